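## Eligibility of genomic positions to carry a planted 3'-OH break.
##
## A break planted on '+' at 0-based position Z is sequenced through a polyA
## tail appended at Z; the resulting alignment's 5'-upstream 20-mer (on the
## alignment strand) covers the genomic bases immediately 3' of Z. Default
## placement therefore requires, per strand:
##   * terminal base not A (on the broken strand) — the anchored oligo-dT
##     would otherwise shift the first genomic base past the terminal A-run;
##   * at most 8 of the 20 tail-side bases complementary to T on the
##     alignment strand, so a clean break cannot trip the >40% T-fraction
##     internal-priming filter;
##   * outside annotated repeat intervals (repeat masking runs downstream);
##   * a margin from the contig ends large enough for fragments and windows.
break_eligibility <- function(genome, margin = 600L, honor_repeats = TRUE,
                              require_non_a = TRUE, avoid_priming = TRUE) {
  lapply(names(genome$sequences), function(chrom) {
    L <- nchar(genome$sequences[[chrom]])
    idx <- seq_len(L)
    if (!require_non_a && !avoid_priming) {
      ## fast path: only margins and repeats constrain placement
      plus <- idx > margin & idx <= L - margin
      minus <- plus
      if (honor_repeats && nrow(genome$repeats) > 0) {
        rp <- genome$repeats[genome$repeats$chrom == chrom, , drop = FALSE]
        for (i in seq_len(nrow(rp))) {
          span <- (rp$start[i] + 1L):rp$end[i]
          plus[span] <- FALSE; minus[span] <- FALSE
        }
      }
      return(list(plus = plus, minus = minus))
    }
    seqc <- strsplit(genome$sequences[[chrom]], "")[[1]]
    isA <- seqc == "A"; isT <- seqc == "T"
    ## rolling 20-base counts: downstream A's (for '+'), upstream T's (for '-')
    csA <- cumsum(isA); csT <- cumsum(isT)
    winA <- rep(NA_integer_, L)  # A count in (Z, Z+20]
    winT <- rep(NA_integer_, L)  # T count in [Z-20, Z)
    idx <- seq_len(L)
    ok <- idx + 20L <= L
    winA[ok] <- csA[idx[ok] + 20L] - csA[idx[ok]]
    ok2 <- idx - 21L >= 1L
    winT[ok2] <- csT[idx[ok2] - 1L] - csT[idx[ok2] - 21L]
    winT[idx == 21L] <- csT[20L]

    plus <- rep(TRUE, L); minus <- rep(TRUE, L)
    if (require_non_a) { plus <- plus & !isA; minus <- minus & !isT }
    if (avoid_priming) {
      plus <- plus & !is.na(winA) & winA <= 8L
      minus <- minus & !is.na(winT) & winT <= 8L
    }
    edge <- idx <= margin | idx > L - margin
    plus[edge] <- FALSE; minus[edge] <- FALSE
    if (honor_repeats && nrow(genome$repeats) > 0) {
      rp <- genome$repeats[genome$repeats$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(rp))) {
        span <- (rp$start[i] + 1L):rp$end[i]
        plus[span] <- FALSE; minus[span] <- FALSE
      }
    }
    list(plus = plus, minus = minus)
  }) |> stats::setNames(names(genome$sequences))
}

#' Plant single-strand breaks in a synthetic genome
#'
#' Either reproduces an explicit list of break records verbatim, or places
#' \code{n} breaks at random. Random placement is i.i.d. over eligible
#' positions (so the same coordinate may recur, modelling recurrent breaks
#' in a cell population), optionally with per-element relative rates (a
#' break is \code{rate}-fold more likely per eligible base inside the
#' element than outside). By default eligible positions have a non-A 3'-terminal base on
#' the broken strand, a tail-side base context that cannot trip the
#' internal-priming filter, lie outside annotated repeats and keep a margin
#' from contig ends; these defaults make planted breaks recoverable by the
#' full pipeline, which is what the truth channel is for. Flags relax each
#' constraint to create known-bias test cases.
#'
#' @param genome an \code{ssb_genome}.
#' @param breaks optional data.frame \code{chrom,pos,strand} (0-based) taken
#'   verbatim; overrides random placement.
#' @param n number of random breaks.
#' @param element_rates optional named list: element label (present in
#'   \code{genome$elements}) -> relative rate (>= 0) vs background rate 1.
#' @param seed integer seed.
#' @param require_non_a,avoid_priming,honor_repeats eligibility flags (see
#'   Details).
#' @param margin bases kept free at each contig end (default 600, enough for
#'   the largest default fragment plus filter windows).
#' @return object of class \code{ssb_truth}: list with \code{breaks}
#'   (data.frame \code{chrom,pos,strand}), \code{artifact_sites} (filled by
#'   the library builders), \code{per_read_origin} (idem).
#' @export
simulate_breaks <- function(genome, breaks = NULL, n = NULL,
                            element_rates = NULL, seed = 1L,
                            require_non_a = TRUE, avoid_priming = TRUE,
                            honor_repeats = TRUE, margin = 600L) {
  lens <- genome_lengths(genome)
  if (!is.null(breaks)) {
    bad <- breaks$pos < 0 | breaks$pos >= lens[breaks$chrom]
    if (any(bad)) stop("explicit break positions out of bounds", call. = FALSE)
    bdf <- data.frame(chrom = breaks$chrom, pos = as.integer(breaks$pos),
                      strand = breaks$strand, stringsAsFactors = FALSE)
    return(new_truth(bdf))
  }
  if (is.null(n)) stop("either 'breaks' or 'n' must be given", call. = FALSE)
  set.seed(as.integer(seed))
  elig <- break_eligibility(genome, margin = margin,
                            honor_repeats = honor_repeats,
                            require_non_a = require_non_a,
                            avoid_priming = avoid_priming)
  ## flatten eligible (chrom, pos, strand) with weights
  tabs <- lapply(names(elig), function(chrom) {
    pl <- which(elig[[chrom]]$plus) - 1L
    mi <- which(elig[[chrom]]$minus) - 1L
    data.frame(chrom = chrom, pos = c(pl, mi),
               strand = rep(c("+", "-"), c(length(pl), length(mi))),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (nrow(tab) < n)
    stop(sprintf("requested %d breaks but only %d eligible positions", n,
                 nrow(tab)), call. = FALSE)
  w <- rep(1, nrow(tab))
  if (!is.null(element_rates)) {
    for (lab in names(element_rates)) {
      rate <- element_rates[[lab]]
      if (rate < 0) stop("element rates must be >= 0", call. = FALSE)
      el <- genome$elements[[lab]]
      if (is.null(el)) stop(sprintf("unknown element '%s'", lab), call. = FALSE)
      inside <- rep(FALSE, nrow(tab))
      for (i in seq_len(nrow(el))) {
        inside <- inside | (tab$chrom == el$chrom[i] &
                              tab$pos >= el$start[i] & tab$pos < el$end[i])
      }
      w[inside] <- w[inside] * rate
    }
  }
  ## i.i.d. placement: the same coordinate may recur (a recurrent break)
  pick <- sample.int(nrow(tab), n, replace = TRUE, prob = w)
  bdf <- tab[sort(pick), , drop = FALSE]
  rownames(bdf) <- NULL
  new_truth(bdf)
}

new_truth <- function(breaks) {
  structure(list(breaks = breaks,
                 artifact_sites = data.frame(chrom = character(0),
                                             pos = integer(0),
                                             strand = character(0)),
                 per_read_origin = character(0)),
            class = "ssb_truth")
}

#' @export
print.ssb_truth <- function(x, ...) {
  cat("Planted truth:", nrow(x$breaks), "breaks,",
      nrow(x$artifact_sites), "artifact sites,",
      length(x$per_read_origin), "reads tracked\n")
  invisible(x)
}

#' Write planted breaks as BED6
#'
#' One line per break: chrom, start, start+1, name = origin label, score 1,
#' strand = broken strand.
#' @param truth an \code{ssb_truth}.
#' @param path output path.
#' @export
write_truth_bed <- function(truth, path) {
  b <- truth$breaks
  df <- data.frame(chrom = b$chrom, start = b$pos, end = b$pos + 1L,
                   name = "break", score = 1L, strand = b$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
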