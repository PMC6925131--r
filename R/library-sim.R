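#' Library simulation configuration
#'
#' Parameters of a simulated tailed sequencing library. Defaults reflect the
#' study conditions: MNase fragments of 150-500 bp, paired 50-base reads for
#' the Illumina-style chemistry, 25-60 base reads for the SMS-style
#' chemistry, error-free by default.
#'
#' @param chemistry "ILM" (paired-end, 10G/12T prefixes) or "SMS"
#'   (single-end, 1-base fill-and-lock skip).
#' @param read_length ILM read length in bases (both mates).
#' @param sms_length_range SMS read-length range, drawn uniformly.
#' @param fragment_range MNase fragment size range in bases.
#' @param error_rate per-base substitution probability.
#' @param artifact_rate expected internal-priming artifact reads per true
#'   break; requires planted polyA runs in the genome.
#' @param n_artifacts explicit artifact read count, overriding
#'   \code{artifact_rate}.
#' @param background_rate expected structureless junk reads per true break.
#' @param tailed if FALSE (untailed control), no break-derived reads are
#'   emitted; artifact and background channels are unaffected.
#' @param reads_per_break tailed reads emitted per planted break.
#' @param quality flat Phred score for emitted bases.
#' @param corrupt_fraction fraction of break-derived reads (pairs) given one
#'   base at Phred 20, to exercise the strict quality filter.
#' @param seed integer seed.
#' @return list of class \code{ssb_libconfig}.
#' @export
library_config <- function(chemistry = c("ILM", "SMS"), read_length = 50L,
                           sms_length_range = c(25L, 60L),
                           fragment_range = c(150L, 500L),
                           error_rate = 0, artifact_rate = 0,
                           n_artifacts = NULL, background_rate = 0,
                           tailed = TRUE, reads_per_break = 1L,
                           quality = 30L, corrupt_fraction = 0, seed = 1L) {
  chemistry <- match.arg(chemistry)
  stopifnot_scalar_prob(error_rate, "error_rate")
  stopifnot_scalar_prob(corrupt_fraction, "corrupt_fraction")
  if (artifact_rate < 0 || background_rate < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (chemistry == "ILM" && fragment_range[1] < read_length - 10L)
    stop("fragments must be able to carry one trimmed read", call. = FALSE)
  structure(list(chemistry = chemistry, read_length = as.integer(read_length),
                 sms_length_range = as.integer(sms_length_range),
                 fragment_range = as.integer(fragment_range),
                 error_rate = error_rate, artifact_rate = artifact_rate,
                 n_artifacts = n_artifacts, background_rate = background_rate,
                 tailed = isTRUE(tailed),
                 reads_per_break = as.integer(reads_per_break),
                 quality = as.integer(quality),
                 corrupt_fraction = corrupt_fraction,
                 seed = as.integer(seed)),
            class = "ssb_libconfig")
}

slice <- function(genome, chrom, start, end) {
  substr(genome$sequences[[chrom]], start + 1L, end)  # 0-based half-open
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

flat_qual <- function(seqs, q) {
  vapply(nchar(seqs), function(n) strrep(intToUtf8(q + 33L), n), character(1))
}

corrupt_one_base <- function(qual, q = 20L) {
  n <- nchar(qual)
  i <- sample.int(n, 1L)
  substr(qual, i, i) <- intToUtf8(q + 33L)
  qual
}

## number of artifact reads to emit
n_artifact_reads <- function(cfg, n_breaks) {
  if (!is.null(cfg$n_artifacts)) return(as.integer(cfg$n_artifacts))
  as.integer(round(cfg$artifact_rate * n_breaks))
}

#' Simulate a paired-end Illumina-style tailed library
#'
#' For every planted break the emitted pair encodes the tailing chemistry:
#' read 2 carries 12 T's (the oligo-dT primer annealed to the polyA tag)
#' followed by the reverse complement of the broken-strand sequence ending
#' at, and including, the 3'-OH terminal base; read 1 carries 10 G's
#' followed by sense sequence from the fragment's MNase end toward the
#' break. MNase fragment ends themselves never seed reads (3'-P is not a
#' terminal-transferase substrate). Internal-priming artifact pairs are
#' primed at the genome's planted polyA runs, so their alignment-strand
#' upstream 20-mer is T-rich and they are removable by the >40% T-fraction
#' filter. With \code{tailed = FALSE} (untailed control) only artifact and
#' background reads are emitted.
#'
#' @param genome an \code{ssb_genome} (artifacts require planted polyA runs).
#' @param truth an \code{ssb_truth} from \code{\link{simulate_breaks}}.
#' @param cfg an ILM \code{\link{library_config}}.
#' @return list with \code{read1}, \code{read2} (data.frames
#'   \code{id,seq,qual}), \code{origin} (named character: read id ->
#'   break|artifact|background), \code{truth} (input truth with
#'   \code{artifact_sites} and \code{per_read_origin} filled),
#'   \code{fragments_resampled} count.
#' @export
build_ilm_library <- function(genome, truth, cfg) {
  stopifnot(inherits(cfg, "ssb_libconfig"))
  if (cfg$chemistry != "ILM") stop("cfg$chemistry must be 'ILM'", call. = FALSE)
  set.seed(cfg$seed)
  L1g <- cfg$read_length - 10L
  L2g <- cfg$read_length - 12L
  minseg <- max(L1g, L2g)
  lens <- genome_lengths(genome)

  ids <- character(0); s1 <- character(0); s2 <- character(0)
  origin <- character(0)
  resampled <- 0L

  emit_pair_plus <- function(chrom, Z) {
    repeat {
      Fl <- draw_int(cfg$fragment_range[1], cfg$fragment_range[2])
      if (Fl < minseg) { resampled <<- resampled + 1L; next }
      seg <- draw_int(minseg, Fl)
      f1 <- Z - seg + 1L
      if (f1 < 0L || f1 + Fl > lens[[chrom]]) { resampled <<- resampled + 1L; next }
      r1 <- paste0(strrep("G", 10L), slice(genome, chrom, f1, f1 + L1g))
      r2 <- paste0(strrep("T", 12L), revcomp(slice(genome, chrom, Z - L2g + 1L, Z + 1L)))
      return(c(r1, r2))
    }
  }
  emit_pair_minus <- function(chrom, Z) {
    repeat {
      Fl <- draw_int(cfg$fragment_range[1], cfg$fragment_range[2])
      if (Fl < minseg) { resampled <<- resampled + 1L; next }
      seg <- draw_int(minseg, Fl)
      f2 <- Z + seg
      if (f2 > lens[[chrom]] || f2 - Fl < 0L) { resampled <<- resampled + 1L; next }
      r1 <- paste0(strrep("G", 10L), revcomp(slice(genome, chrom, f2 - L1g, f2)))
      r2 <- paste0(strrep("T", 12L), slice(genome, chrom, Z, Z + L2g))
      return(c(r1, r2))
    }
  }

  if (cfg$tailed && nrow(truth$breaks) > 0) {
    for (i in seq_len(nrow(truth$breaks))) {
      b <- truth$breaks[i, ]
      for (k in seq_len(cfg$reads_per_break)) {
        pr <- if (b$strand == "+") emit_pair_plus(b$chrom, b$pos)
              else emit_pair_minus(b$chrom, b$pos)
        ids <- c(ids, sprintf("break_%06d_%d", i, k))
        s1 <- c(s1, pr[1]); s2 <- c(s2, pr[2])
        origin <- c(origin, "break")
      }
    }
  }

  ## internal-priming artifacts at planted polyA runs ('+'-strand A runs)
  na <- n_artifact_reads(cfg, nrow(truth$breaks))
  art_sites <- truth$artifact_sites
  if (na > 0) {
    runs <- genome$polyA_runs
    if (nrow(runs) == 0)
      stop("artifact reads requested but genome has no planted polyA runs",
           call. = FALSE)
    pick <- sample.int(nrow(runs), na, replace = TRUE)
    for (j in seq_len(na)) {
      a <- runs$start[pick[j]]; chrom <- runs$chrom[pick[j]]
      Z <- a - 1L  # apparent break base just 5' of the run
      pr <- {
        repeat {
          Fl <- draw_int(cfg$fragment_range[1], cfg$fragment_range[2])
          if (Fl < minseg) { resampled <- resampled + 1L; next }
          seg <- draw_int(minseg, Fl)
          f1 <- Z - seg + 1L
          if (f1 < 0L || f1 + Fl > lens[[chrom]]) { resampled <- resampled + 1L; next }
          r1 <- paste0(strrep("G", 10L), slice(genome, chrom, f1, f1 + L1g))
          r2 <- paste0(strrep("T", 12L),
                       revcomp(slice(genome, chrom, Z - L2g + 1L, Z + 1L)))
          break
        }
        c(r1, r2)
      }
      ids <- c(ids, sprintf("artifact_%06d", j))
      s1 <- c(s1, pr[1]); s2 <- c(s2, pr[2])
      origin <- c(origin, "artifact")
      art_sites <- rbind(art_sites,
                         data.frame(chrom = chrom, pos = Z, strand = "+"))
    }
  }

  ## structureless background junk (exercises the prefix filters)
  nb <- as.integer(round(cfg$background_rate * nrow(truth$breaks)))
  if (nb > 0) {
    for (j in seq_len(nb)) {
      chrom <- sample(names(lens), 1L)
      st <- sample.int(lens[[chrom]] - cfg$read_length, 1L)
      ids <- c(ids, sprintf("background_%06d", j))
      s1 <- c(s1, slice(genome, chrom, st, st + cfg$read_length))
      s2 <- c(s2, slice(genome, chrom, st, st + cfg$read_length))
      origin <- c(origin, "background")
    }
  }

  s1 <- apply_errors(s1, cfg$error_rate)
  s2 <- apply_errors(s2, cfg$error_rate)
  q1 <- flat_qual(s1, cfg$quality)
  q2 <- flat_qual(s2, cfg$quality)
  if (cfg$corrupt_fraction > 0 && length(ids) > 0) {
    hit <- which(runif(length(ids)) < cfg$corrupt_fraction)
    for (i in hit) q2[i] <- corrupt_one_base(q2[i])
  }

  names(origin) <- ids
  truth$artifact_sites <- art_sites
  truth$per_read_origin <- origin
  list(read1 = data.frame(id = ids, seq = s1, qual = q1, stringsAsFactors = FALSE),
       read2 = data.frame(id = ids, seq = s2, qual = q2, stringsAsFactors = FALSE),
       origin = origin, truth = truth, fragments_resampled = resampled)
}

#' Simulate a single-end SMS-style tailed library
#'
#' Each break-derived read is the reverse complement of the broken-strand
#' window ending one base 5' of the 3'-OH terminal base: the first template
#' base after the polyA tail is consumed by the fill-and-lock step and never
#' sequenced, which downstream calling compensates with a 1-base 5'
#' extension. Read lengths are drawn uniformly from
#' \code{cfg$sms_length_range}. Artifact and untailed channels behave as in
#' \code{\link{build_ilm_library}}.
#'
#' @inheritParams build_ilm_library
#' @return list with \code{reads} (data.frame \code{id,seq,qual}),
#'   \code{origin}, \code{truth}.
#' @export
build_sms_library <- function(genome, truth, cfg) {
  stopifnot(inherits(cfg, "ssb_libconfig"))
  if (cfg$chemistry != "SMS") stop("cfg$chemistry must be 'SMS'", call. = FALSE)
  set.seed(cfg$seed)
  lens <- genome_lengths(genome)
  lo <- cfg$sms_length_range[1]; hi <- cfg$sms_length_range[2]

  ids <- character(0); ss <- character(0); origin <- character(0)

  if (cfg$tailed && nrow(truth$breaks) > 0) {
    for (i in seq_len(nrow(truth$breaks))) {
      b <- truth$breaks[i, ]
      for (k in seq_len(cfg$reads_per_break)) {
        L <- draw_int(lo, hi)
        s <- if (b$strand == "+") {
          revcomp(slice(genome, b$chrom, b$pos - L, b$pos))      # skips pos
        } else {
          slice(genome, b$chrom, b$pos + 1L, b$pos + 1L + L)     # skips pos
        }
        ids <- c(ids, sprintf("break_%06d_%d", i, k))
        ss <- c(ss, s)
        origin <- c(origin, "break")
      }
    }
  }

  na <- n_artifact_reads(cfg, nrow(truth$breaks))
  art_sites <- truth$artifact_sites
  if (na > 0) {
    runs <- genome$polyA_runs
    if (nrow(runs) == 0)
      stop("artifact reads requested but genome has no planted polyA runs",
           call. = FALSE)
    pick <- sample.int(nrow(runs), na, replace = TRUE)
    for (j in seq_len(na)) {
      a <- runs$start[pick[j]]; chrom <- runs$chrom[pick[j]]
      Z <- a - 1L
      L <- draw_int(lo, hi)
      ids <- c(ids, sprintf("artifact_%06d", j))
      ss <- c(ss, revcomp(slice(genome, chrom, Z - L, Z)))
      origin <- c(origin, "artifact")
      art_sites <- rbind(art_sites,
                         data.frame(chrom = chrom, pos = Z, strand = "+"))
    }
  }

  nb <- as.integer(round(cfg$background_rate * nrow(truth$breaks)))
  if (nb > 0) {
    for (j in seq_len(nb)) {
      chrom <- sample(names(lens), 1L)
      L <- draw_int(10L, 20L)  # short junk, fails the >=25 length filter
      st <- sample.int(lens[[chrom]] - L, 1L)
      ids <- c(ids, sprintf("background_%06d", j))
      ss <- c(ss, slice(genome, chrom, st, st + L))
      origin <- c(origin, "background")
    }
  }

  ss <- apply_errors(ss, cfg$error_rate)
  qq <- flat_qual(ss, cfg$quality)
  names(origin) <- ids
  truth$artifact_sites <- art_sites
  truth$per_read_origin <- origin
  list(reads = data.frame(id = ids, seq = ss, qual = qq, stringsAsFactors = FALSE),
       origin = origin, truth = truth)
}

#' Write reads to FASTQ
#' @param reads data.frame \code{id,seq,qual}.
#' @param path output path (".gz" for gzip).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path.
#' @return data.frame \code{id,seq,qual}.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
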