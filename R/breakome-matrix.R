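#' Per-gene-strand break-density matrix
#'
#' One row per sample, one column per (gene, strand). Density of breaks in
#' gene g on strand s for a sample with T total breaks is
#' count / (gene length in kb * T) * 1e6 — breaks per kb per million
#' sample breaks, so densities are invariant under uniform read-depth
#' scaling of a sample. A break contributes to a cell iff it lies in the
#' gene interval and matches the cell's strand.
#'
#' @param samples named list of \code{ssb_breakset}.
#' @param genes data.frame \code{gene,chrom,start,end} (0-based half-open;
#'   zero-length genes excluded with a warning).
#' @param metadata optional data.frame with one row per sample (cell type,
#'   treatment, age, ...), carried along.
#' @return object of class \code{ssb_breakome}: list with \code{matrix}
#'   (samples x features, feature names "gene|strand"), \code{metadata}.
#' @export
gene_density_matrix <- function(samples, genes, metadata = NULL) {
  zl <- genes$end <= genes$start
  if (any(zl)) {
    warning(sprintf("%d zero-length gene(s) excluded", sum(zl)))
    genes <- genes[!zl, , drop = FALSE]
  }
  feat <- as.vector(t(outer(genes$gene, c("+", "-"), paste, sep = "|")))
  gr_g <- intervals_to_gr(genes[, c("chrom", "start", "end")])
  len_kb <- (genes$end - genes$start) / 1000
  m <- matrix(0, nrow = length(samples), ncol = length(feat),
              dimnames = list(names(samples), feat))
  for (si in seq_along(samples)) {
    bs <- samples[[si]]
    total <- nrow(bs$calls)  # unique coordinates
    if (total == 0) stop("sample ", names(samples)[si], " is empty", call. = FALSE)
    gr_b <- positions_to_gr(bs$calls$chrom, bs$calls$start)
    hits <- IRanges::findOverlaps(gr_b, gr_g, ignore.strand = TRUE)
    if (length(hits) > 0) {
      gi <- S4Vectors::subjectHits(hits)
      bstr <- bs$calls$strand[S4Vectors::queryHits(hits)]
      key <- paste(genes$gene[gi], bstr, sep = "|")
      cnt <- table(key)
      kb <- len_kb[gi[match(names(cnt), key)]]
      j <- match(names(cnt), feat)
      m[si, j] <- as.integer(cnt) / (kb * total) * 1e6
    }
  }
  structure(list(matrix = m, metadata = metadata, genes = genes),
            class = "ssb_breakome")
}

#' @export
print.ssb_breakome <- function(x, ...) {
  cat(sprintf("Breakome matrix: %d samples x %d (gene, strand) features\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' PCA embedding of a breakome matrix
#'
#' Centers features (and optionally scales them to unit variance) before
#' the eigendecomposition; components are ordered by decreasing explained
#' variance.
#'
#' @param bm an \code{ssb_breakome} (or plain matrix).
#' @param n_components components to return; truncated with a warning if
#'   more than samples allow.
#' @param scale. scale features to unit variance (default FALSE: densities
#'   share units).
#' @return list with \code{coordinates} (samples x components),
#'   \code{explained_variance} (fractions), \code{prcomp} (the full fit).
#' @export
pca_embed <- function(bm, n_components = 2L, scale. = FALSE) {
  m <- if (inherits(bm, "ssb_breakome")) bm$matrix else bm
  if (nrow(m) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  keep <- apply(m, 2, function(v) stats::var(v) > 0)
  if (isTRUE(scale.)) m <- m[, keep, drop = FALSE]
  p <- prcomp(m, center = TRUE, scale. = scale.)
  avail <- ncol(p$x)
  if (n_components > avail) {
    warning(sprintf("only %d component(s) available; truncating", avail))
    n_components <- avail
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)], prcomp = p)
}
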