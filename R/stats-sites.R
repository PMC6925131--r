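#' Per-base break profile around motif sites
#'
#' For a set of motif occurrences (e.g. nickase recognition sites) with
#' strand, computes the fraction of all breaks in the sample that map to
#' each site-relative offset and strand within site +/- flank. Occurrences
#' on '-' are coordinate-flipped so offsets are motif-relative (offset 0 is
#' the first motif base) and strands are reported site-relative ("top" =
#' the strand the motif is written on).
#'
#' @param bs an \code{ssb_breakset}.
#' @param sites data.frame \code{chrom,start,end,strand} of motif
#'   occurrences (0-based half-open).
#' @param flank flanking bases on each side.
#' @return data.frame \code{offset,strand,fraction} ("top"/"bottom"
#'   strands); fractions are relative to all breaks in the sample, so they
#'   sum to <= 1 (= 1 when every break falls in a window).
#' @export
site_profile <- function(bs, sites, flank = 10L) {
  cc <- bs$calls
  width <- sites$end - sites$start  # assumed constant motif width
  offs <- (-flank):(max(width) - 1L + flank)
  counts <- matrix(0, nrow = length(offs), ncol = 2,
                   dimnames = list(NULL, c("top", "bottom")))
  gr_b <- positions_to_gr(cc$chrom, cc$start)
  gr_s <- intervals_to_gr(sites[, c("chrom", "start", "end")]) + flank
  hits <- IRanges::findOverlaps(gr_b, gr_s, ignore.strand = TRUE)
  for (h in seq_along(hits)) {
    bi <- S4Vectors::queryHits(hits)[h]
    si <- S4Vectors::subjectHits(hits)[h]
    if (sites$strand[si] == "+") {
      off <- cc$start[bi] - sites$start[si]
      srel <- if (cc$strand[bi] == "+") "top" else "bottom"
    } else {
      off <- (sites$end[si] - 1L) - cc$start[bi]
      srel <- if (cc$strand[bi] == "-") "top" else "bottom"
    }
    j <- match(off, offs)
    if (!is.na(j)) counts[j, srel] <- counts[j, srel] + 1
  }
  total <- nrow(cc)
  data.frame(offset = rep(offs, 2),
             strand = rep(c("top", "bottom"), each = length(offs)),
             fraction = c(counts[, "top"], counts[, "bottom"]) / total)
}

#' Normalized per-position break score
#'
#' score(position) = breaks detected at the position * 1e9 / total breaks
#' in the sample. Over all positions of the genome the scores sum to 1e9
#' exactly.
#'
#' @param bs an \code{ssb_breakset}.
#' @param positions optional data.frame \code{chrom,pos} restricting output
#'   (e.g. site +/- 10); default: every position carrying a break.
#' @param use_read_counts score read-level counts (default) rather than
#'   unique positions.
#' @return data.frame \code{chrom,pos,strand,score}.
#' @export
normalized_site_score <- function(bs, positions = NULL,
                                  use_read_counts = TRUE) {
  cc <- bs$calls
  total <- if (use_read_counts) sum(cc$read_count) else nrow(cc)
  if (total <= 0) stop("break set is empty", call. = FALSE)
  count <- if (use_read_counts) cc$read_count else rep(1L, nrow(cc))
  out <- data.frame(chrom = cc$chrom, pos = cc$start, strand = cc$strand,
                    score = count * 1e9 / total, stringsAsFactors = FALSE)
  if (!is.null(positions)) {
    key <- paste(out$chrom, out$pos)
    out <- out[key %in% paste(positions$chrom, positions$pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Site detection sensitivity under subsampling
#'
#' Subsamples read-level calls without replacement at each depth (seeded)
#' and reports the fraction of sites detected, a site counting as detected
#' if at least one surviving call lies within its detection window
#' (site interval +/- \code{window}).
#'
#' @param read_calls read-level call data.frame \code{chrom,start} (one row
#'   per read).
#' @param sites data.frame \code{chrom,start,end}.
#' @param depths integer vector of subsampling depths (<= rows of
#'   \code{read_calls}).
#' @param window detection half-width around the site interval, default 1.
#' @param seed subsampling seed.
#' @return data.frame \code{depth,detected_fraction}.
#' @export
detection_sensitivity <- function(read_calls, sites, depths, window = 1L,
                                  seed = 1L) {
  n <- nrow(read_calls)
  if (any(depths > n)) stop("depth exceeds available reads", call. = FALSE)
  set.seed(as.integer(seed))
  gr_s <- intervals_to_gr(sites[, c("chrom", "start", "end")]) + window
  out <- vapply(depths, function(d) {
    idx <- sample.int(n, d)
    gr_b <- positions_to_gr(read_calls$chrom[idx], read_calls$start[idx])
    det <- IRanges::overlapsAny(gr_s, gr_b, ignore.strand = TRUE)
    mean(det)
  }, numeric(1))
  data.frame(depth = depths, detected_fraction = out)
}

#' Partition breaks into hotspots and singletons
#'
#' Hotspots are unique break positions supported by at least
#' \code{min_reads} reads (read-level counts are the stated exception to
#' unique-coordinate collapsing).
#'
#' @param bs an \code{ssb_breakset} with read counts.
#' @param min_reads hotspot threshold, default 4.
#' @return list(\code{hotspots}, \code{rest}): two \code{ssb_breakset}s
#'   partitioning the unique positions.
#' @export
hotspots <- function(bs, min_reads = 4L) {
  hot <- bs$calls$read_count >= min_reads
  mk <- function(df, tag) {
    out <- bs
    out$calls <- df
    rownames(out$calls) <- NULL
    out$total_filtered_reads <- sum(df$read_count)
    add_provenance(out, tag)
  }
  list(hotspots = mk(bs$calls[hot, , drop = FALSE],
                     sprintf("hotspots_min%d", min_reads)),
       rest = mk(bs$calls[!hot, , drop = FALSE], "singletons"))
}

#' Library-complexity curve under subsampling
#'
#' Subsamples read-level calls without replacement at each depth (seeded)
#' and reports the ratio of unique (chrom, pos, strand) coordinates to the
#' depth — the "breakome" complexity, which decreases with depth as
#' positions recur.
#'
#' @param read_calls read-level call data.frame \code{chrom,start,strand}.
#' @param depths subsampling depths.
#' @param seed subsampling seed.
#' @return data.frame \code{depth,unique_positions,ratio}.
#' @export
complexity_curve <- function(read_calls, depths, seed = 1L) {
  n <- nrow(read_calls)
  if (any(depths > n)) stop("depth exceeds available reads", call. = FALSE)
  set.seed(as.integer(seed))
  key <- paste(read_calls$chrom, read_calls$start, read_calls$strand)
  out <- t(vapply(depths, function(d) {
    u <- length(unique(key[sample.int(n, d)]))
    c(u, u / d)
  }, numeric(2)))
  data.frame(depth = depths, unique_positions = as.integer(out[, 1]),
             ratio = out[, 2])
}
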