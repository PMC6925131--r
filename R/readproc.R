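#' Filter and trim Illumina-style read pairs
#'
#' Applies the paired-end structure and quality rules: read 1 must begin
#' with at least 10 G's, read 2 with at least 12 T's, and every base of both
#' (untrimmed) reads must have Phred quality strictly greater than
#' \code{min_phred - 1} (default: > 20). Kept pairs are trimmed: exactly the
#' first 10 bases of read 1 are removed (base 11 may be a genomic G), and
#' the maximal leading T-run of read 2 is removed (on clean data the 13th
#' base is templated and non-T, so maximal-run and fixed-12 trimming
#' coincide). Drop reasons are assigned in the order \code{structure1},
#' \code{structure2}, \code{quality}.
#'
#' @param read1,read2 data.frames \code{id,seq,qual} (mates matched by row).
#' @param min_phred minimal acceptable Phred score (strict: bases must be
#'   > \code{min_phred - 1}; default 21 reproduces the "> 20" rule).
#' @return list with \code{read1} and \code{read2} (trimmed kept pairs,
#'   with \code{t_run_length} on read2), \code{stats} (a
#'   \code{\link{filter_stats}}), \code{reasons} (per dropped pair).
#' @export
filter_ilm_pairs <- function(read1, read2, min_phred = 21L) {
  if (nrow(read1) != nrow(read2))
    stop("read1 and read2 must have the same number of records", call. = FALSE)
  bad_len <- nchar(read1$seq) != nchar(read1$qual) |
    nchar(read2$seq) != nchar(read2$qual)
  if (any(bad_len))
    stop("sequence/quality length mismatch in input reads", call. = FALSE)

  ok1 <- startsWith(read1$seq, strrep("G", 10L))
  ok2 <- startsWith(read2$seq, strrep("T", 12L))
  q1 <- phred_min(read1$qual) >= min_phred
  q2 <- phred_min(read2$qual) >= min_phred
  okq <- q1 & q2

  reason <- rep(NA_character_, nrow(read1))
  reason[!ok1] <- "structure1"
  reason[ok1 & !ok2] <- "structure2"
  reason[ok1 & ok2 & !okq] <- "quality"
  keep <- is.na(reason)

  r1 <- read1[keep, , drop = FALSE]
  r2 <- read2[keep, , drop = FALSE]
  if (nrow(r2) > 0) {
    trun <- attr(regexpr("^T+", r2$seq), "match.length")
    r1$seq <- substring(r1$seq, 11L)
    r1$qual <- substring(r1$qual, 11L)
    r2$t_run_length <- trun
    r2$seq <- substring(r2$seq, trun + 1L)
    r2$qual <- substring(r2$qual, trun + 1L)
    if (any(!nzchar(r2$seq)))
      stop("read 2 empty after T-run trimming", call. = FALSE)
  } else {
    r2$t_run_length <- integer(0)
  }
  drops <- table(factor(reason[!keep],
                        levels = c("structure1", "structure2", "quality")))
  st <- filter_stats(input = nrow(read1), passed = sum(keep),
                     drops = as.list(drops))
  list(read1 = r1, read2 = r2, stats = st, reasons = reason[!keep])
}

#' Filter SMS-style reads by length
#'
#' Keeps reads of at least \code{min_len} bases (boundary inclusive); base
#' qualities are a configurable pass-through hook, unused by default (the
#' platform's own quality filtration is not reproduced).
#'
#' @param reads data.frame \code{id,seq,qual}.
#' @param min_len minimal read length, default 25.
#' @return list with \code{reads} (kept, unchanged), \code{stats}.
#' @export
filter_sms_reads <- function(reads, min_len = 25L) {
  keep <- nchar(reads$seq) >= min_len
  st <- filter_stats(input = nrow(reads), passed = sum(keep),
                     drops = list(length = sum(!keep)))
  list(reads = reads[keep, , drop = FALSE], stats = st)
}

#' Filter accounting
#'
#' Bookkeeping for every filtering stage; the conservation invariant
#' input = passed + sum(drops) is enforced at construction.
#'
#' @param input,passed counts.
#' @param drops named list of per-rule drop counts.
#' @return object of class \code{ssb_filterstats}.
#' @export
filter_stats <- function(input, passed, drops = list()) {
  drops <- lapply(drops, as.integer)
  if (as.integer(input) != as.integer(passed) + sum(unlist(drops)))
    stop("filter stats do not conserve: input != passed + drops", call. = FALSE)
  structure(list(input = as.integer(input), passed = as.integer(passed),
                 drops = drops),
            class = "ssb_filterstats")
}

#' @export
print.ssb_filterstats <- function(x, ...) {
  cat(sprintf("reads in: %d  passed: %d\n", x$input, x$passed))
  for (nm in names(x$drops))
    if (x$drops[[nm]] > 0) cat(sprintf("  dropped (%s): %d\n", nm, x$drops[[nm]]))
  invisible(x)
}

#' Write a filtering stats report as TSV
#' @param stats an \code{ssb_filterstats}.
#' @param path output path.
#' @export
write_filter_stats <- function(stats, path) {
  df <- data.frame(rule = c("input", "passed", names(stats$drops)),
                   count = c(stats$input, stats$passed,
                             unlist(stats$drops, use.names = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
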