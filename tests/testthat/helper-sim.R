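## Shared in-code fixtures for the test suite. Everything is generated at
## test time from seeds; no data files.

## small annotated genome reused across stats tests
tiny_genome <- function(seed = 101L, len = 60000L) {
  make_genome(c(chrA = len), gc = 0.41,
              polyA_runs = list(n = 6L, length = 12L),
              seed = seed)
}

## a break set constructed directly from positions (bypassing the pipeline)
manual_breakset <- function(chrom, start, strand, read_count = NULL,
                            sample_id = "test") {
  df <- data.frame(chrom = chrom, start = as.integer(start), strand = strand,
                   stringsAsFactors = FALSE)
  if (!is.null(read_count)) df$read_count <- as.integer(read_count)
  break_set(df, sample_id = sample_id)
}

## uniform random breaks over [margin, L - margin)
random_breakset <- function(n, len = 100000L, seed = 1L, chrom = "chrA") {
  set.seed(seed)
  manual_breakset(chrom, sample.int(len - 200L, n, replace = FALSE) + 100L,
                  sample(c("+", "-"), n, replace = TRUE))
}

## brute-force oracle: is each single-base position inside any interval?
oracle_in_intervals <- function(chrom, pos, intervals) {
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start <= pos[i] & pos[i] < intervals$end)
  }, logical(1))
}

## brute-force oracle: T fraction of a character window
oracle_t_fraction <- function(window) {
  ch <- strsplit(window, "")[[1]]
  sum(ch == "T") / length(ch)
}

## local reverse complement, independent of the package implementation
oracle_rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## independent string-slicing oracle for the ILM read-2 chemistry:
## 12 T's + revcomp of the broken-strand window ending at (incl.) the break.
## For a '-' break the broken-strand window covers genomic [pos, pos+k),
## whose revcomp-of-revcomp is the sense sequence.
oracle_ilm_read2 <- function(genome, chrom, pos, strand, read_length) {
  k <- read_length - 12L
  seqc <- genome$sequences[[chrom]]
  genomic <- if (strand == "+") {
    oracle_rc(substr(seqc, pos - k + 2L, pos + 1L))  # 1-based [pos-k+1..pos+1]
  } else {
    substr(seqc, pos + 1L, pos + k)
  }
  paste0(strrep("T", 12L), genomic)
}

## independent oracle for the SMS chemistry: revcomp of the broken-strand
## window ending one base 5' of the break (break base itself skipped)
oracle_sms_read <- function(genome, chrom, pos, strand, read_length) {
  seqc <- genome$sequences[[chrom]]
  if (strand == "+") {
    oracle_rc(substr(seqc, pos - read_length + 1L, pos))   # [pos-L..pos-1] 0b
  } else {
    substr(seqc, pos + 2L, pos + 1L + read_length)         # [pos+1..pos+L] 0b
  }
}
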