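#' Select genes carrying breaks in promoters or exons
#'
#' Promoter mode first assigns each promoter interval to a gene: a
#' promoter belongs to a gene iff it lies within \code{max_dist} bases of
#' the gene's annotated 5' end (transcription start, strand-aware); if
#' several genes qualify the nearest 5' end wins, ties broken by gene
#' order (deterministic). Genes whose assigned promoters carry at least
#' \code{min_breaks} breaks are selected; the gene universe is the set of
#' promoter-assigned genes. Exon mode counts breaks in the genes' exon
#' intervals directly, with the universe either all genes or the
#' promoter-assigned set.
#'
#' @param bs an \code{ssb_breakset}.
#' @param genes data.frame \code{gene,chrom,start,end,strand} (0-based
#'   half-open; the 5' end is \code{start} for '+', \code{end - 1} for '-').
#' @param promoters data.frame \code{chrom,start,end} (promoter mode).
#' @param exons data.frame \code{gene,chrom,start,end} (exon mode).
#' @param region "promoter" or "exon".
#' @param min_breaks selection threshold, default 3.
#' @param max_dist promoter-to-5'-end assignment distance, default 5000.
#' @param exon_universe "assigned" (promoter-assigned genes) or "all".
#' @return list(\code{selected} gene vector, \code{universe} gene vector,
#'   \code{assignment} promoter->gene table in promoter mode).
#' @export
select_break_genes <- function(bs, genes, promoters = NULL, exons = NULL,
                               region = c("promoter", "exon"),
                               min_breaks = 3L, max_dist = 5000L,
                               exon_universe = c("all", "assigned")) {
  region <- match.arg(region)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)

  assign_promoters <- function() {
    stopifnot(!is.null(promoters))
    gene_idx <- integer(nrow(promoters))
    for (i in seq_len(nrow(promoters))) {
      same <- which(genes$chrom == promoters$chrom[i])
      if (length(same) == 0) { gene_idx[i] <- NA_integer_; next }
      ## distance from the promoter interval to the 5' end
      d <- pmax(0L, pmax(promoters$start[i] - tss[same],
                         tss[same] - (promoters$end[i] - 1L)))
      ok <- which(d <= max_dist)
      gene_idx[i] <- if (length(ok) == 0) NA_integer_ else
        same[ok[which.min(d[ok])]]
    }
    data.frame(promoter = seq_len(nrow(promoters)),
               gene = ifelse(is.na(gene_idx), NA_character_,
                             genes$gene[gene_idx]),
               stringsAsFactors = FALSE)
  }

  if (region == "promoter") {
    asg <- assign_promoters()
    keep <- !is.na(asg$gene)
    universe <- sort(unique(asg$gene[keep]))
    gr_b <- breaks_gr(bs)
    gr_p <- intervals_to_gr(promoters[keep, c("chrom", "start", "end")])
    hits <- IRanges::findOverlaps(gr_b, gr_p, ignore.strand = TRUE)
    gene_of_break <- asg$gene[keep][S4Vectors::subjectHits(hits)]
    ## count distinct break positions per gene
    brk <- S4Vectors::queryHits(hits)
    cnt <- table(gene_of_break[!duplicated(paste(brk, gene_of_break))])
    selected <- sort(names(cnt)[cnt >= min_breaks])
    return(list(selected = selected, universe = universe, assignment = asg))
  }

  exon_universe <- match.arg(exon_universe)
  stopifnot(!is.null(exons))
  universe <- if (exon_universe == "all") sort(unique(genes$gene)) else {
    asg <- assign_promoters()
    sort(unique(asg$gene[!is.na(asg$gene)]))
  }
  gr_b <- breaks_gr(bs)
  gr_e <- intervals_to_gr(exons[, c("chrom", "start", "end")])
  hits <- IRanges::findOverlaps(gr_b, gr_e, ignore.strand = TRUE)
  gene_of_break <- exons$gene[S4Vectors::subjectHits(hits)]
  brk <- S4Vectors::queryHits(hits)
  cnt <- table(gene_of_break[!duplicated(paste(brk, gene_of_break))])
  selected <- sort(intersect(names(cnt)[cnt >= min_breaks], universe))
  list(selected = selected, universe = universe, assignment = NULL)
}

#' Gene-set over-representation
#'
#' One-sided hypergeometric test of each named gene set's overlap with the
#' selected genes, drawn from the universe; odds ratios from the 2x2 table
#' and Benjamini-Hochberg adjustment across sets.
#'
#' @param selected character vector of selected genes (subset of
#'   \code{universe}).
#' @param universe character vector of background genes.
#' @param sets named list of character vectors (gene sets; intersected
#'   with the universe, empty intersections skipped with a warning).
#' @return data.frame \code{set,set_size,overlap,odds_ratio,p_value,
#'   p_adjusted}, ordered by p-value.
#' @export
geneset_enrichment <- function(selected, universe, sets) {
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe", call. = FALSE)
  n_sel <- length(selected)
  N <- length(universe)
  rows <- list()
  for (nm in names(sets)) {
    set <- intersect(sets[[nm]], universe)
    if (length(set) == 0) {
      warning(sprintf("gene set '%s' has no genes in the universe; skipped", nm))
      next
    }
    K <- length(set)
    k <- length(intersect(set, selected))
    p <- phyper(k - 1L, K, N - K, n_sel, lower.tail = FALSE)
    a <- k; b <- n_sel - k; cc <- K - k; dd <- N - K - b
    or <- if (b == 0 || cc == 0) Inf else (a * dd) / (b * cc)
    if (a == 0) or <- 0
    rows[[nm]] <- data.frame(set = nm, set_size = K, overlap = k,
                             odds_ratio = or, p_value = p,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame())
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
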