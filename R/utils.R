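#' @import methods
#' @importFrom stats binom.test wilcox.test phyper p.adjust prcomp glm lm
#'   binomial logLik coef predict pnorm setNames cor rbinom runif
#'   rnorm quantile median pf fitted
#' @importFrom utils head write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over character vectors of A/C/G/T (and N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Phred+33 helpers; qualities are carried as ASCII strings end to end.
phred_to_string <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

phred_min <- function(s) {
  vapply(s, function(x) if (nzchar(x)) min(utf8ToInt(x)) - 33L else NA_integer_,
         integer(1))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
}

## data.frame of intervals -> GRanges (0-based half-open in, 1-based in GRanges)
intervals_to_gr <- function(df, strand = NULL) {
  if (is.null(df) || nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  s <- if (!is.null(strand)) strand else
    if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = s
  )
}

## single-base positions -> GRanges
positions_to_gr <- function(chrom, pos, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L),
    strand = strand
  )
}

empty_calls_df <- function() {
  data.frame(chrom = character(0), start = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

## sum of interval lengths (0-based half-open data.frame)
interval_total_length <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(0)
  sum(as.numeric(df$end - df$start))
}

## deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) * 69069L + as.integer(k)) %% 2147483647L
}

## uniform integer draw on [lo, hi], immune to sample()'s scalar expansion
draw_int <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}
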