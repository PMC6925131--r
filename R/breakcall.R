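#' Break-set container
#'
#' A collection of strand-aware single-base SSB calls with per-position
#' read counts, keyed by (chrom, start, strand). All coordinates are
#' 0-based half-open; a break at base b is the interval [b, b+1) on the
#' broken strand. Provenance records the ordered list of filters applied.
#'
#' @param calls data.frame \code{chrom,start,strand} (one row per read-level
#'   call; collapsed by key here) or \code{chrom,start,strand,read_count}
#'   (taken as already collapsed).
#' @param sample_id optional sample label.
#' @param provenance character vector of applied processing steps.
#' @return object of class \code{ssb_breakset}.
#' @export
break_set <- function(calls, sample_id = NA_character_, provenance = character(0)) {
  if (nrow(calls) == 0) {
    cc <- data.frame(chrom = character(0), start = integer(0),
                     strand = character(0), read_count = integer(0))
    total <- 0L
  } else if ("read_count" %in% names(calls)) {
    cc <- calls[, c("chrom", "start", "strand", "read_count")]
    total <- sum(cc$read_count)
  } else {
    key <- paste(calls$chrom, calls$start, calls$strand, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    cc <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                     start = as.integer(vapply(parts, `[`, "", 2L)),
                     strand = vapply(parts, `[`, "", 3L),
                     read_count = as.integer(tab),
                     stringsAsFactors = FALSE)
    total <- nrow(calls)
  }
  cc <- cc[order(cc$chrom, cc$start, cc$strand), , drop = FALSE]
  rownames(cc) <- NULL
  structure(list(calls = cc, total_filtered_reads = as.integer(total),
                 sample_id = sample_id, provenance = provenance),
            class = "ssb_breakset")
}

#' @export
print.ssb_breakset <- function(x, ...) {
  cat(sprintf("Break set%s: %d unique positions, %d reads\n",
              if (!is.na(x$sample_id)) paste0(" '", x$sample_id, "'") else "",
              nrow(x$calls), x$total_filtered_reads))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.ssb_breakset <- function(object, ...) {
  cc <- object$calls
  cat(sprintf("%d unique break positions (%d '+', %d '-'), %d reads\n",
              nrow(cc), sum(cc$strand == "+"), sum(cc$strand == "-"),
              object$total_filtered_reads))
  if (nrow(cc)) {
    cat("reads per position:\n")
    print(summary(cc$read_count))
  }
  invisible(object)
}

#' @export
as.data.frame.ssb_breakset <- function(x, ...) x$calls

add_provenance <- function(bs, step) {
  bs$provenance <- c(bs$provenance, step)
  bs
}

#' Write / read a break set as BED6
#'
#' Columns: chrom, start, start+1, name, score = read count, strand =
#' broken strand.
#' @param bs an \code{ssb_breakset}.
#' @param path file path.
#' @export
write_breakset_bed <- function(bs, path) {
  cc <- bs$calls
  df <- data.frame(chrom = cc$chrom, start = cc$start, end = cc$start + 1L,
                   name = "ssb", score = cc$read_count, strand = cc$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_breakset_bed
#' @param sample_id sample label for the loaded set.
#' @export
read_breakset_bed <- function(path, sample_id = NA_character_) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  calls <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                      strand = df[[6]], read_count = as.integer(df[[5]]),
                      stringsAsFactors = FALSE)
  break_set(calls, sample_id = sample_id, provenance = "imported")
}

#' Call SSBs from Illumina-style aligned pairs
#'
#' The break is the first genomic base of read 2 (its 5' terminus after
#' T-run trimming), on the strand opposite to the read-2 alignment: a '+'
#' read-2 alignment at [s,e) yields the SSB [s, s+1) on '-'; a '-'
#' alignment at [s,e) yields [e-1, e) on '+'.
#'
#' @param pairs data.frame from \code{\link{pair_alignments}} or
#'   \code{\link{load_alignments}} (ilm mode).
#' @return read-level call data.frame \code{read_id,chrom,start,strand}
#'   plus the source read-2 alignment coordinates (needed by
#'   \code{\link{internal_priming_filter}}).
#' @export
call_ssb_ilm <- function(pairs) {
  plus <- pairs$strand_r2 == "+"
  data.frame(read_id = pairs$read_id, chrom = pairs$chrom,
             start = ifelse(plus, pairs$start_r2, pairs$end_r2 - 1L),
             strand = ifelse(plus, "-", "+"),
             aln_start = pairs$start_r2, aln_end = pairs$end_r2,
             aln_strand = pairs$strand_r2, stringsAsFactors = FALSE)
}

#' Call SSBs from SMS-style alignments
#'
#' The fill-and-lock step consumes one unsequenced template base, so the 5'
#' coordinate of the alignment is extended by one base and the SSB is that
#' extended base on the opposite strand: a '+' alignment at [s,e) yields
#' [s-1, s) on '-'; a '-' alignment yields [e, e+1) on '+'. Calls whose
#' extension would leave the chromosome are dropped with a count.
#'
#' @param alignments data.frame \code{read_id,chrom,start,end,strand}.
#' @param chrom_lengths named vector of chromosome lengths (for the
#'   boundary check).
#' @return list(\code{calls} read-level data.frame as
#'   \code{\link{call_ssb_ilm}}, \code{dropped_boundary} count).
#' @export
call_ssb_sms <- function(alignments, chrom_lengths = NULL) {
  plus <- alignments$strand == "+"
  start <- ifelse(plus, alignments$start - 1L, alignments$end)
  oob <- start < 0L
  if (!is.null(chrom_lengths))
    oob <- oob | start >= chrom_lengths[alignments$chrom]
  calls <- data.frame(read_id = alignments$read_id, chrom = alignments$chrom,
                      start = as.integer(start),
                      strand = ifelse(plus, "-", "+"),
                      aln_start = alignments$start, aln_end = alignments$end,
                      aln_strand = alignments$strand, stringsAsFactors = FALSE)
  list(calls = calls[!oob, , drop = FALSE],
       dropped_boundary = sum(oob))
}

#' Remove likely internal-priming calls
#'
#' The polyA tag is read as a leading T-run, so oligo-dT priming at genomic
#' A-rich sequence mimics a break. For each source alignment the 20-base 5'
#' upstream sequence on the alignment strand is examined ('+' alignment at
#' [s,e): genomic '+' bases [s-20, s); '-' alignment: reverse complement of
#' [e, e+20)); the call is removed iff the T fraction of that window is
#' strictly greater than \code{max_t_fraction}. Windows truncated by a
#' contig end either use the available bases (default) or drop the call
#' (\code{truncated = "drop"}).
#'
#' @param calls read-level call data.frame with source alignment columns.
#' @param genome an \code{ssb_genome}.
#' @param max_t_fraction threshold, default 0.40 (strict inequality).
#' @param truncated "use" or "drop" for windows truncated at contig ends.
#' @return list(\code{calls} kept read-level calls, \code{dropped} count).
#' @export
internal_priming_filter <- function(calls, genome, max_t_fraction = 0.40,
                                    truncated = c("use", "drop")) {
  truncated <- match.arg(truncated)
  if (nrow(calls) == 0) return(list(calls = calls, dropped = 0L))
  lens <- genome_lengths(genome)
  tfrac <- numeric(nrow(calls))
  short <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    chrom <- calls$chrom[i]
    if (calls$aln_strand[i] == "+") {
      w0 <- max(0L, calls$aln_start[i] - 20L)
      win <- slice(genome, chrom, w0, calls$aln_start[i])
    } else {
      w1 <- min(lens[[chrom]], calls$aln_end[i] + 20L)
      win <- revcomp(slice(genome, chrom, calls$aln_end[i], w1))
    }
    short[i] <- nchar(win) < 20L
    tfrac[i] <- if (nchar(win) == 0) 0 else
      lengths(regmatches(win, gregexpr("T", win))) / nchar(win)
  }
  drop <- tfrac > max_t_fraction
  if (truncated == "drop") drop <- drop | short
  list(calls = calls[!drop, , drop = FALSE], dropped = sum(drop))
}

#' Subtract untailed-control breaks
#'
#' Removes every call whose (chrom, start, strand) key appears in the
#' untailed control set; matching is base- and strand-exact.
#'
#' @param bs an \code{ssb_breakset}.
#' @param control an \code{ssb_breakset} from the untailed library.
#' @return list(\code{breaks} filtered \code{ssb_breakset},
#'   \code{removed} unique positions removed).
#' @export
subtract_control <- function(bs, control) {
  key <- function(df) paste(df$chrom, df$start, df$strand)
  hit <- key(bs$calls) %in% key(control$calls)
  out <- bs
  out$calls <- bs$calls[!hit, , drop = FALSE]
  rownames(out$calls) <- NULL
  out$total_filtered_reads <- sum(out$calls$read_count)
  out <- add_provenance(out, "control_subtracted")
  list(breaks = out, removed = sum(hit))
}

#' Mask breaks in repeat intervals
#'
#' Removes calls whose single base lies in any repeat interval (half-open,
#' strand-blind), mirroring RepeatMasker-based masking.
#'
#' @param bs an \code{ssb_breakset}.
#' @param repeats data.frame \code{chrom,start,end} (0-based half-open).
#' @return list(\code{breaks}, \code{removed}).
#' @export
mask_repeats <- function(bs, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0) {
    return(list(breaks = add_provenance(bs, "repeats_masked"), removed = 0L))
  }
  gr_b <- positions_to_gr(bs$calls$chrom, bs$calls$start)
  gr_r <- intervals_to_gr(repeats)
  hit <- IRanges::overlapsAny(gr_b, gr_r, ignore.strand = TRUE)
  out <- bs
  out$calls <- bs$calls[!hit, , drop = FALSE]
  rownames(out$calls) <- NULL
  out$total_filtered_reads <- sum(out$calls$read_count)
  out <- add_provenance(out, "repeats_masked")
  list(breaks = out, removed = sum(hit))
}

#' Pair opposite-strand SSBs into candidate DSBs
#'
#' Emits one candidate double-strand break per ('+','-') pair of calls on
#' the same chromosome whose positions differ by at most \code{max_gap}
#' bases. By default every qualifying pair is reported (an SSB may
#' participate in several); \code{mode = "nearest"} greedily assigns each
#' '+' call to its nearest unassigned '-' partner.
#'
#' @param bs an \code{ssb_breakset}.
#' @param max_gap maximal position difference, default 2.
#' @param mode "all" or "nearest".
#' @return data.frame \code{chrom,plus_pos,minus_pos,gap}.
#' @export
pair_dsb <- function(bs, max_gap = 2L, mode = c("all", "nearest")) {
  mode <- match.arg(mode)
  cc <- bs$calls
  plus <- cc[cc$strand == "+", , drop = FALSE]
  minus <- cc[cc$strand == "-", , drop = FALSE]
  out <- list()
  for (chrom in intersect(unique(plus$chrom), unique(minus$chrom))) {
    p <- plus$start[plus$chrom == chrom]
    m <- minus$start[minus$chrom == chrom]
    if (mode == "all") {
      ## window join via findOverlaps with maxgap
      hits <- IRanges::findOverlaps(IRanges::IRanges(p, width = 1L),
                                    IRanges::IRanges(m, width = 1L),
                                    maxgap = max_gap)
      if (length(hits) > 0)
        out[[chrom]] <- data.frame(
          chrom = chrom,
          plus_pos = p[S4Vectors::queryHits(hits)],
          minus_pos = m[S4Vectors::subjectHits(hits)])
    } else {
      m_free <- sort(m)
      rows <- list()
      for (pp in sort(p)) {
        if (length(m_free) == 0) break
        d <- abs(m_free - pp)
        j <- which.min(d)
        if (d[j] <= max_gap) {
          rows[[length(rows) + 1L]] <- data.frame(chrom = chrom,
                                                  plus_pos = pp,
                                                  minus_pos = m_free[j])
          m_free <- m_free[-j]
        }
      }
      if (length(rows)) out[[chrom]] <- do.call(rbind, rows)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), plus_pos = integer(0),
               minus_pos = integer(0))
  res$gap <- abs(res$plus_pos - res$minus_pos)
  res <- res[res$gap <= max_gap, , drop = FALSE]
  rownames(res) <- NULL
  res
}
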