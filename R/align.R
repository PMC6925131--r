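#' Exact-match fixture aligner
#'
#' Finds all exact occurrences of each read, or of its reverse complement,
#' in a genome. A forward hit is reported on '+', a reverse-complement hit
#' on '-'. \code{mode = "unique_only"} keeps reads with exactly one
#' occurrence genome-wide; \code{mode = "random_best"} picks one occurrence
#' uniformly at random (seeded), emulating the treatment of multi-mapping
#' reads in repeat-class analyses. This is a test fixture standing in for a
#' production aligner, usable only on error-free reads.
#'
#' @param reads data.frame \code{id,seq} (qualities ignored).
#' @param genome an \code{ssb_genome}.
#' @param mode "unique_only" or "random_best".
#' @param seed seed for \code{random_best}.
#' @return list with \code{alignments} (data.frame
#'   \code{read_id,chrom,start,end,strand,mapq,n_hits}; 0-based half-open;
#'   mapq 60 for unique hits, 0 for randomly chosen multi-hits) and
#'   \code{stats} (\code{unaligned} and \code{multi} counts).
#' @export
exact_align <- function(reads, genome, mode = c("unique_only", "random_best"),
                        seed = 1L) {
  mode <- match.arg(mode)
  subjects <- lapply(genome$sequences, Biostrings::DNAString)
  out <- vector("list", nrow(reads))
  unaligned <- 0L; multi <- 0L
  if (mode == "random_best") set.seed(as.integer(seed))
  for (i in seq_len(nrow(reads))) {
    sq <- reads$seq[i]
    hits <- list()
    for (chrom in names(subjects)) {
      fwd <- Biostrings::matchPattern(sq, subjects[[chrom]])
      if (length(fwd) > 0)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = Biostrings::start(fwd) - 1L,
          end = Biostrings::end(fwd), strand = "+", stringsAsFactors = FALSE)
      rev <- Biostrings::matchPattern(revcomp(sq), subjects[[chrom]])
      if (length(rev) > 0)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = Biostrings::start(rev) - 1L,
          end = Biostrings::end(rev), strand = "-", stringsAsFactors = FALSE)
    }
    h <- if (length(hits)) do.call(rbind, hits) else NULL
    if (is.null(h) || nrow(h) == 0) { unaligned <- unaligned + 1L; next }
    nh <- nrow(h)
    if (nh > 1) {
      multi <- multi + 1L
      if (mode == "unique_only") next
      h <- h[sample.int(nh, 1L), , drop = FALSE]
    }
    h$read_id <- reads$id[i]
    h$mapq <- if (nh == 1) 60L else 0L
    h$n_hits <- nh
    out[[i]] <- h
  }
  aln <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(aln))
    aln <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      n_hits = integer(0))
  aln <- aln[, c("read_id", "chrom", "start", "end", "strand", "mapq", "n_hits")]
  rownames(aln) <- NULL
  list(alignments = aln, stats = list(unaligned = unaligned, multi = multi))
}

#' Pair mate alignments into face-to-face fragments
#'
#' Joins read-1 and read-2 alignments by read id and keeps pairs that are on
#' the same chromosome, on opposite strands, face-to-face (FR: each mate's
#' 5' end points toward the other) and within \code{max_insert}.
#'
#' @param aln1,aln2 alignment data.frames from \code{\link{exact_align}} or
#'   \code{\link{load_alignments}}.
#' @param max_insert maximal outer fragment span in bases.
#' @return data.frame of aligned pairs: read id, read-2 (break-proximal)
#'   coordinates, read-1 coordinates, insert size.
#' @export
pair_alignments <- function(aln1, aln2, max_insert = 1000L) {
  m <- merge(aln2, aln1, by = "read_id", suffixes = c("_r2", "_r1"))
  same <- m$chrom_r2 == m$chrom_r1
  opp <- m$strand_r2 != m$strand_r1
  ## FR: the '+' mate must start left of the '-' mate's end
  plus_start <- ifelse(m$strand_r2 == "+", m$start_r2, m$start_r1)
  minus_end <- ifelse(m$strand_r2 == "-", m$end_r2, m$end_r1)
  insert <- minus_end - plus_start
  ok <- same & opp & insert > 0 & insert <= max_insert
  res <- m[ok, , drop = FALSE]
  res$insert <- insert[ok]
  res <- res[, c("read_id", "chrom_r2", "start_r2", "end_r2", "strand_r2",
                 "start_r1", "end_r1", "strand_r1", "insert")]
  names(res)[2] <- "chrom"
  rownames(res) <- NULL
  res
}

flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Load alignments from SAM/BAM with uniqueness and pairing filters
#'
#' Ingests a SAM or BAM file, keeping primary, non-supplementary records
#' with MAPQ at or above \code{min_mapq} ("uniquely mapped" is
#' operationalised as this triple; the threshold is a parameter). In
#' \code{mode = "ilm"} records are additionally paired by query name and
#' must form proper face-to-face pairs within \code{max_insert}; read 2 (the
#' break-proximal mate) is identified by the second-in-pair flag. SAM input
#' is converted through Rsamtools. All returned coordinates are 0-based
#' half-open.
#'
#' @param path SAM or BAM file.
#' @param mode "ilm" (paired) or "sms" (single-end).
#' @param min_mapq MAPQ threshold, default 20.
#' @param max_insert maximal fragment span for pairing, default 1000.
#' @return \code{mode="sms"}: list(\code{alignments}, \code{stats});
#'   \code{mode="ilm"}: list(\code{pairs} (as
#'   \code{\link{pair_alignments}}), \code{stats}).
#' @export
load_alignments <- function(path, mode = c("ilm", "sms"), min_mapq = 20L,
                            max_insert = 1000L) {
  mode <- match.arg(mode)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "mapq", "cigar")))[[1]]
  df <- data.frame(read_id = b$qname, flag = b$flag,
                   chrom = as.character(b$rname), pos = b$pos,
                   qwidth = b$qwidth, mapq = b$mapq, cigar = b$cigar,
                   stringsAsFactors = FALSE)
  n_in <- nrow(df)
  unmapped <- flag_bit(df$flag, 4L) | is.na(df$pos)
  secondary <- flag_bit(df$flag, 256L)
  suppl <- flag_bit(df$flag, 2048L)
  lowq <- !unmapped & !secondary & !suppl &
    (is.na(df$mapq) | df$mapq < min_mapq)
  keep <- !(unmapped | secondary | suppl | lowq)
  df <- df[keep, , drop = FALSE]
  ## aligned span on the reference from the CIGAR (fixture emits pure matches)
  ref_width <- cigar_ref_width(df$cigar, df$qwidth)
  df$start <- df$pos - 1L
  df$end <- df$start + ref_width
  df$strand <- ifelse(flag_bit(df$flag, 16L), "-", "+")
  drops <- list(unmapped = sum(unmapped), secondary = sum(secondary),
                supplementary = sum(suppl), mapq = sum(lowq))

  if (mode == "sms") {
    aln <- df[, c("read_id", "chrom", "start", "end", "strand", "mapq")]
    rownames(aln) <- NULL
    st <- filter_stats(n_in, nrow(aln), drops)
    return(list(alignments = aln, stats = st))
  }
  is_r2 <- flag_bit(df$flag, 128L)
  aln2 <- df[is_r2, c("read_id", "chrom", "start", "end", "strand", "mapq")]
  aln1 <- df[!is_r2, c("read_id", "chrom", "start", "end", "strand", "mapq")]
  pairs <- pair_alignments(aln1, aln2, max_insert = max_insert)
  unpaired <- n_in - sum(unlist(drops)) - 2L * nrow(pairs)
  st <- filter_stats(n_in, 2L * nrow(pairs),
                     c(drops, list(pairing = unpaired)))
  list(pairs = pairs, stats = st)
}

## reference span from CIGAR: sum of M/D/N/=/X lengths; fallback to qwidth
cigar_ref_width <- function(cigar, qwidth) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg) || cg == "*") return(qwidth[i])
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Write alignments as SAM
#'
#' Minimal SAM writer for fixture round-trips: emits a valid header and one
#' record per alignment (per mate for pairs) with full-match CIGARs.
#'
#' @param x alignment data.frame (single-end; columns
#'   \code{read_id,chrom,start,end,strand,mapq}) or a pairs data.frame from
#'   \code{\link{pair_alignments}}.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param path output SAM path.
#' @param paired treat \code{x} as a pairs data.frame.
#' @export
write_sam <- function(x, chrom_lengths, path, paired = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, chrom_lengths[[nm]]), con)
  rec <- function(id, flag, chrom, start, end, mapq) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            id, flag, chrom, start + 1L, mapq, end - start,
            strrep("N", end - start))
  }
  if (!paired) {
    for (i in seq_len(nrow(x))) {
      flag <- if (x$strand[i] == "-") 16L else 0L
      writeLines(rec(x$read_id[i], flag, x$chrom[i], x$start[i], x$end[i],
                     x$mapq[i] %||% 60L), con)
    }
  } else {
    for (i in seq_len(nrow(x))) {
      f1 <- 1L + 2L + 64L; f2 <- 1L + 2L + 128L
      if (x$strand_r1[i] == "-") { f1 <- f1 + 16L; f2 <- f2 + 32L }
      if (x$strand_r2[i] == "-") { f2 <- f2 + 16L; f1 <- f1 + 32L }
      writeLines(rec(x$read_id[i], f1, x$chrom[i], x$start_r1[i], x$end_r1[i], 60L), con)
      writeLines(rec(x$read_id[i], f2, x$chrom[i], x$start_r2[i], x$end_r2[i], 60L), con)
    }
  }
  invisible(path)
}
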