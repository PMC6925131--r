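#' Piecewise-constant signal track
#'
#' Container for bedGraph / fixedStep-wig style signal (replication timing,
#' nucleosome occupancy, conservation scores): non-overlapping intervals per
#' chromosome with one value each.
#'
#' @param intervals data.frame \code{chrom,start,end,value} (0-based
#'   half-open).
#' @param label track label.
#' @return object of class \code{ssb_track}.
#' @export
signal_track <- function(intervals, label = "signal") {
  gr <- intervals_to_gr(intervals[, c("chrom", "start", "end")])
  ov <- IRanges::findOverlaps(gr, gr)  # self-hits only iff non-overlapping
  if (length(ov) > length(gr))
    stop("track intervals overlap within a chromosome", call. = FALSE)
  structure(list(intervals = intervals, label = label), class = "ssb_track")
}

#' @export
print.ssb_track <- function(x, ...) {
  cat(sprintf("Signal track '%s': %d intervals, %.0f bp covered\n",
              x$label, nrow(x$intervals),
              interval_total_length(x$intervals)))
  invisible(x)
}

#' Read a signal track from bedGraph or wig
#' @param path bedGraph/wig file (rtracklayer formats).
#' @param label track label.
#' @return an \code{ssb_track}.
#' @export
read_signal_track <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path)
  signal_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr),
                          value = gr$score, stringsAsFactors = FALSE),
               label = label)
}

## track value at single 0-based positions; NA where uncovered
track_values_at <- function(track, chrom, pos) {
  gr_p <- positions_to_gr(chrom, pos)
  gr_t <- intervals_to_gr(track$intervals[, c("chrom", "start", "end")])
  hits <- IRanges::findOverlaps(gr_p, gr_t, ignore.strand = TRUE)
  out <- rep(NA_real_, length(gr_p))
  out[S4Vectors::queryHits(hits)] <- track$intervals$value[S4Vectors::subjectHits(hits)]
  out
}

## length-weighted mean of a track over its covered span
track_background_mean <- function(track) {
  w <- track$intervals$end - track$intervals$start
  sum(track$intervals$value * w) / sum(w)
}

#' Replication-timing ratios at break positions
#'
#' For each cell-cycle fraction track, the ratio of the mean signal at
#' break positions to the length-weighted mean signal over the background:
#' > 1 indicates break enrichment where that fraction replicates, < 1
#' depletion.
#'
#' @param bs an \code{ssb_breakset}.
#' @param fraction_tracks named list of \code{ssb_track}, one per fraction
#'   (e.g. G1, S1..S4, G2).
#' @return data.frame \code{fraction, mean_at_breaks, background_mean,
#'   ratio}.
#' @export
replication_ratio <- function(bs, fraction_tracks) {
  out <- lapply(names(fraction_tracks), function(nm) {
    tr <- fraction_tracks[[nm]]
    v <- track_values_at(tr, bs$calls$chrom, bs$calls$start)
    bg <- track_background_mean(tr)
    if (bg == 0) stop("background mean is zero for fraction ", nm, call. = FALSE)
    data.frame(fraction = nm, mean_at_breaks = mean(v, na.rm = TRUE),
               background_mean = bg,
               ratio = mean(v, na.rm = TRUE) / bg, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare a signal track at breaks against background positions
#'
#' Two-sided Wilcoxon rank-sum test of the track values at break positions
#' versus values at uniformly sampled background positions (seeded), e.g.
#' to ask whether breaks fall in regions of lower nucleosome occupancy.
#'
#' @param bs an \code{ssb_breakset}.
#' @param track an \code{ssb_track}.
#' @param background data.frame \code{chrom,start,end} to sample from.
#' @param n_background background positions to draw (default 1e5).
#' @param seed sampling seed.
#' @return list: medians, \code{p_value}, the two value vectors.
#' @export
track_compare <- function(bs, track, background, n_background = 1e5L,
                          seed = 1L) {
  v_b <- track_values_at(track, bs$calls$chrom, bs$calls$start)
  v_b <- v_b[!is.na(v_b)]
  if (length(v_b) == 0) stop("no break positions covered by track", call. = FALSE)
  set.seed(as.integer(seed))
  bgp <- sample_background_positions(background, n_background)
  v_bg <- track_values_at(track, bgp$chrom, bgp$pos)
  v_bg <- v_bg[!is.na(v_bg)]
  wt <- wilcox.test(v_b, v_bg, alternative = "two.sided", exact = NULL)
  list(median_breaks = median(v_b), median_background = median(v_bg),
       p_value = wt$p.value, values_breaks = v_b, values_background = v_bg)
}

#' Sample uniform positions from a background interval set
#' @param background data.frame \code{chrom,start,end}.
#' @param n positions to draw (with replacement over the base universe).
#' @return data.frame \code{chrom,pos}.
#' @export
sample_background_positions <- function(background, n) {
  w <- background$end - background$start
  i <- sample.int(nrow(background), n, replace = TRUE, prob = w)
  off <- floor(runif(n) * w[i])
  data.frame(chrom = background$chrom[i],
             pos = as.integer(background$start[i] + off))
}

#' Conservation-score profile around breaks
#'
#' For each break and window half-width w, averages the positive scores
#' (over positions with score > 0) and the absolute negative scores (over
#' positions with score < 0) within +/- w bases of the break, then averages
#' over breaks. Also reports the ratio of the mean score over nearby
#' positions (the window excluding the break base) to the mean score at
#' break bases themselves. Breaks with no covered position in the window
#' are excluded and counted.
#'
#' @param bs an \code{ssb_breakset}.
#' @param track an \code{ssb_track} of per-base scores (e.g. PhyloP).
#' @param windows half-widths, default c(5, 10, 20).
#' @return list with \code{profile} (data.frame \code{window,
#'   mean_positive, mean_negative_abs, nearby_over_break}) and
#'   \code{excluded} counts per window.
#' @export
conservation_profile <- function(bs, track, windows = c(5L, 10L, 20L)) {
  cc <- bs$calls
  out <- list(); excluded <- integer(0)
  for (w in windows) {
    pos_means <- numeric(0); neg_means <- numeric(0)
    nearby_vals <- numeric(0); at_vals <- numeric(0)
    excl <- 0L
    for (i in seq_len(nrow(cc))) {
      offs <- (-w):w
      v <- track_values_at(track, rep(cc$chrom[i], length(offs)),
                           cc$start[i] + offs)
      if (all(is.na(v))) { excl <- excl + 1L; next }
      pv <- v[!is.na(v) & v > 0]; nv <- v[!is.na(v) & v < 0]
      pos_means <- c(pos_means, if (length(pv)) mean(pv) else 0)
      neg_means <- c(neg_means, if (length(nv)) mean(abs(nv)) else 0)
      at <- v[offs == 0]
      near <- v[offs != 0]
      if (!is.na(at)) at_vals <- c(at_vals, at)
      nearby_vals <- c(nearby_vals, near[!is.na(near)])
    }
    ratio <- if (length(at_vals) && mean(at_vals) != 0)
      mean(nearby_vals) / mean(at_vals) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      window = w, mean_positive = mean(pos_means),
      mean_negative_abs = mean(neg_means), nearby_over_break = ratio)
    excluded <- c(excluded, excl)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  list(profile = res, excluded = stats::setNames(excluded, windows))
}
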