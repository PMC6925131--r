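breaks_gr <- function(bs) {
  positions_to_gr(bs$calls$chrom, bs$calls$start, bs$calls$strand)
}

#' Break enrichment in a genomic element class
#'
#' Tests whether breaks overlap an element class more often than expected
#' from its share of the background. With k of n breaks in an element of
#' total length L_e on a background of length L_bg, the null hit
#' probability is p0 = L_e / L_bg, the p-value is the two-sided exact
#' binomial test of k out of n at p0, and the odds ratio is
#' (k/(n-k)) / (L_e/(L_bg-L_e)) (+Inf when k = n). The 95% CI is the
#' Clopper-Pearson interval on k/n transformed to the odds-ratio scale.
#' Overlap is by the break's single base, half-open, strand-blind.
#'
#' @param bs an \code{ssb_breakset}.
#' @param element data.frame \code{chrom,start,end} of element intervals;
#'   intersected with the background first.
#' @param background data.frame \code{chrom,start,end}; default background
#'   should be the same region set the breaks were filtered against
#'   (e.g. genome minus repeats).
#' @return object of class \code{ssb_enrichment}: list with \code{k, n,
#'   element_length, background_length, odds_ratio, p_value, ci95, test}.
#' @export
element_enrichment <- function(bs, element, background) {
  gr_bg <- GenomicRanges::reduce(intervals_to_gr(background), ignore.strand = TRUE)
  gr_el <- GenomicRanges::reduce(intervals_to_gr(element), ignore.strand = TRUE)
  gr_el <- GenomicRanges::intersect(gr_el, gr_bg, ignore.strand = TRUE)
  L_bg <- sum(as.numeric(GenomicRanges::width(gr_bg)))
  L_e <- sum(as.numeric(GenomicRanges::width(gr_el)))
  if (L_e == 0 || L_e == L_bg)
    stop("element length must be strictly between 0 and the background length",
         call. = FALSE)
  gr_b <- breaks_gr(bs)
  n <- length(gr_b)
  if (n < 1) stop("break set is empty", call. = FALSE)
  k <- sum(IRanges::overlapsAny(gr_b, gr_el, ignore.strand = TRUE))
  p0 <- L_e / L_bg
  bt <- binom.test(k, n, p = p0, alternative = "two.sided")
  or_scale <- L_e / (L_bg - L_e)
  or <- if (k == n) Inf else (k / (n - k)) / or_scale
  ci_p <- bt$conf.int
  ci <- c(lo = unname(ci_p[1] / (1 - ci_p[1])) / or_scale,
          hi = if (ci_p[2] >= 1) Inf else
            unname(ci_p[2] / (1 - ci_p[2])) / or_scale)
  structure(list(k = k, n = n, element_length = L_e,
                 background_length = L_bg, odds_ratio = or,
                 p_value = bt$p.value, ci95 = ci,
                 test = "two-sided exact binomial"),
            class = "ssb_enrichment")
}

#' @export
print.ssb_enrichment <- function(x, ...) {
  cat(sprintf("%d of %d breaks in element (%.3g of background); OR = %.3g [%.3g, %.3g], p = %.3g (%s)\n",
              x$k, x$n, x$element_length / x$background_length,
              x$odds_ratio, x$ci95[1], x$ci95[2], x$p_value, x$test))
  invisible(x)
}

#' Template/non-template strand asymmetry of breaks in gene regions
#'
#' For each region class (e.g. exon, intron) counts breaks on the template
#' strand (the strand complementary to the gene's sense strand: a break in
#' a '+' gene is template iff its strand is '-') versus the non-template
#' strand, and reports the template/non-template ratio. Regions lying in
#' genes annotated on both strands are excluded by default (their template
#' assignment is ambiguous); \code{ambiguous = "both"} instead counts such
#' breaks once per overlapping gene strand.
#'
#' @param bs an \code{ssb_breakset}.
#' @param regions data.frame \code{chrom,start,end,gene_strand,class}
#'   (0-based half-open; \code{class} e.g. "exon"/"intron").
#' @param ambiguous "exclude" (default) or "both".
#' @return data.frame per class: \code{class, template, nontemplate,
#'   ratio} (ratio NA when nontemplate = 0).
#' @export
strand_asymmetry <- function(bs, regions, ambiguous = c("exclude", "both")) {
  ambiguous <- match.arg(ambiguous)
  gr_b <- breaks_gr(bs)
  gr_r <- intervals_to_gr(regions[, c("chrom", "start", "end")])
  if (ambiguous == "exclude") {
    ## a region is ambiguous if it overlaps a region of the same class
    ## annotated on the other gene strand
    drop <- rep(FALSE, nrow(regions))
    for (cl in unique(regions$class)) {
      i <- which(regions$class == cl)
      sub <- gr_r[i]
      other <- regions$gene_strand[i]
      hits <- IRanges::findOverlaps(sub, sub)
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      amb <- unique(qh[other[qh] != other[sh]])
      drop[i[amb]] <- TRUE
    }
    regions <- regions[!drop, , drop = FALSE]
    gr_r <- intervals_to_gr(regions[, c("chrom", "start", "end")])
  }
  hits <- IRanges::findOverlaps(gr_b, gr_r, ignore.strand = TRUE)
  bqs <- bs$calls$strand[S4Vectors::queryHits(hits)]
  gstr <- regions$gene_strand[S4Vectors::subjectHits(hits)]
  cls <- regions$class[S4Vectors::subjectHits(hits)]
  is_template <- bqs != gstr
  out <- do.call(rbind, lapply(unique(regions$class), function(cl) {
    t_n <- sum(is_template & cls == cl)
    nt_n <- sum(!is_template & cls == cl)
    data.frame(class = cl, template = t_n, nontemplate = nt_n,
               ratio = if (nt_n > 0) t_n / nt_n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Break overlap with sequence variants at several windows
#'
#' A break hits a variant if their positions differ by at most w bases
#' (strand-blind), for each window half-width w. The expected hit
#' probability under uniform variant density rho on the background is
#' 1 - (1 - rho)^(2w+1); enrichment is the two-sided exact binomial test of
#' the observed hit count against that expectation, with the odds ratio on
#' the same probability scale.
#'
#' @param bs an \code{ssb_breakset}.
#' @param variants data.frame \code{chrom,pos} (0-based), optionally
#'   \code{type} (SNP/indel) and \code{af}; when \code{type}/class columns
#'   are present results are stratified.
#' @param windows integer half-widths, default c(0, 2, 5, 10).
#' @param background_length total background length in bases (for rho).
#' @return data.frame, one row per (type, class, window): hit count, n,
#'   expected probability, odds ratio, p-value.
#' @export
variant_overlap <- function(bs, variants, windows = c(0L, 2L, 5L, 10L),
                            background_length) {
  if (is.null(variants$type)) variants$type <- "variant"
  if (!is.null(variants$af) && is.null(variants$class))
    variants$class <- variant_af_class(variants$af)
  if (is.null(variants$class)) variants$class <- "all"
  gr_b <- breaks_gr(bs)
  n <- length(gr_b)
  combos <- unique(variants[, c("type", "class")])
  out <- list()
  for (r in seq_len(nrow(combos))) {
    vv <- variants[variants$type == combos$type[r] &
                     variants$class == combos$class[r], , drop = FALSE]
    rho <- nrow(vv) / background_length
    gr_v <- positions_to_gr(vv$chrom, vv$pos)
    for (w in windows) {
      hit <- IRanges::overlapsAny(gr_b, gr_v + w, ignore.strand = TRUE)
      k <- sum(hit)
      p_exp <- 1 - (1 - rho)^(2 * w + 1)
      bt <- binom.test(k, n, p = p_exp, alternative = "two.sided")
      or <- if (k == n) Inf else (k / (n - k)) / (p_exp / (1 - p_exp))
      out[[length(out) + 1L]] <- data.frame(
        type = combos$type[r], class = combos$class[r], window = w,
        k = k, n = n, expected_p = p_exp, odds_ratio = or,
        p_value = bt$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify variants by allele frequency
#'
#' 1000 Genomes-style classes: common (AF >= 0.05), low_frequency
#' (0.005 <= AF < 0.05), rare (AF < 0.005).
#' @param af numeric allele frequencies in [0,1].
#' @return character vector of classes.
#' @export
variant_af_class <- function(af) {
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequencies must be in [0, 1]", call. = FALSE)
  ifelse(af >= 0.05, "common", ifelse(af >= 0.005, "low_frequency", "rare"))
}

#' Read variants from VCF
#'
#' Thin reader returning positions, type (SNP vs indel by allele lengths)
#' and allele frequency from the AF INFO field.
#' @param path VCF file (uncompressed or bgzipped).
#' @return data.frame \code{chrom,pos,type,af,class} (pos 0-based).
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  type <- ifelse(nchar(fix$REF) == 1 &
                   !grepl(",", fix$ALT) & nchar(fix$ALT) == 1, "SNP", "indel")
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
             type = type, af = af, class = variant_af_class(af),
             stringsAsFactors = FALSE)
}

#' Overlap significance between two break/position sets
#'
#' One-sided hypergeometric test for the overlap of two position sets over
#' a discrete universe of background positions at 1-bp resolution (used
#' e.g. to compare candidate DSB positions against an independent DSB map).
#'
#' @param set_a,set_b data.frames \code{chrom,pos}.
#' @param universe_size number of positions in the background universe.
#' @return list(\code{overlap}, \code{p_value}).
#' @export
position_overlap_test <- function(set_a, set_b, universe_size) {
  key <- function(df) paste(df$chrom, df$pos)
  ov <- length(intersect(key(set_a), key(set_b)))
  p <- phyper(ov - 1L, nrow(set_b), universe_size - nrow(set_b),
              nrow(set_a), lower.tail = FALSE)
  list(overlap = ov, p_value = p)
}
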