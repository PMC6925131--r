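#' Run the full break-calling pipeline on simulated or real reads
#'
#' Convenience wrapper chaining, for the Illumina-style chemistry:
#' structure/quality filtering, exact-fixture alignment of both mates
#' (unique hits only), face-to-face pairing, SSB calling, the
#' internal-priming filter, untailed-control subtraction and repeat
#' masking — in that order, matching the processing sequence of the
#' protocol. For the SMS-style chemistry the paired steps are replaced by
#' single-end filtering, alignment and the 1-base-extension calling rule.
#'
#' @param library a library list from \code{\link{build_ilm_library}} /
#'   \code{\link{build_sms_library}}, or equivalently shaped read
#'   data.frames.
#' @param genome an \code{ssb_genome}.
#' @param chemistry "ILM" or "SMS".
#' @param control optional untailed-control \code{ssb_breakset} (or a
#'   library list to be processed identically first).
#' @param repeats optional repeat intervals; defaults to the genome's
#'   annotated repeats.
#' @param sample_id sample label.
#' @param min_phred,min_len,max_insert,max_t_fraction filter parameters
#'   passed through to the stage functions.
#' @return list with \code{breaks} (final \code{ssb_breakset}),
#'   \code{stage_stats} (named list of per-stage counts), and
#'   \code{read_calls} (read-level calls surviving the priming filter, for
#'   read-level analyses such as sensitivity/complexity curves).
#' @export
run_break_pipeline <- function(library, genome, chemistry = c("ILM", "SMS"),
                               control = NULL, repeats = genome$repeats,
                               sample_id = NA_character_, min_phred = 21L,
                               min_len = 25L, max_insert = 1000L,
                               max_t_fraction = 0.40) {
  chemistry <- match.arg(chemistry)
  stage_stats <- list()

  if (chemistry == "ILM") {
    fl <- filter_ilm_pairs(library$read1, library$read2, min_phred = min_phred)
    stage_stats$read_filter <- fl$stats
    a1 <- exact_align(fl$read1, genome, mode = "unique_only")
    a2 <- exact_align(fl$read2, genome, mode = "unique_only")
    stage_stats$align <- list(read1 = a1$stats, read2 = a2$stats)
    pairs <- pair_alignments(a1$alignments, a2$alignments,
                             max_insert = max_insert)
    stage_stats$paired <- nrow(pairs)
    calls <- call_ssb_ilm(pairs)
  } else {
    fl <- filter_sms_reads(library$reads, min_len = min_len)
    stage_stats$read_filter <- fl$stats
    al <- exact_align(fl$reads, genome, mode = "unique_only")
    stage_stats$align <- al$stats
    cs <- call_ssb_sms(al$alignments, genome_lengths(genome))
    stage_stats$boundary_dropped <- cs$dropped_boundary
    calls <- cs$calls
  }

  pf <- internal_priming_filter(calls, genome, max_t_fraction = max_t_fraction)
  stage_stats$priming_dropped <- pf$dropped
  bs <- break_set(pf$calls[, c("chrom", "start", "strand")],
                  sample_id = sample_id,
                  provenance = c(paste0("called_", tolower(chemistry)),
                                 "priming_filtered"))

  if (!is.null(control)) {
    if (!inherits(control, "ssb_breakset")) {
      ctl <- run_break_pipeline(control, genome, chemistry = chemistry,
                                control = NULL, repeats = NULL,
                                sample_id = "untailed_control",
                                min_phred = min_phred, min_len = min_len,
                                max_insert = max_insert,
                                max_t_fraction = max_t_fraction)
      control <- ctl$breaks
    }
    sc <- subtract_control(bs, control)
    stage_stats$control_removed <- sc$removed
    bs <- sc$breaks
  }

  mr <- mask_repeats(bs, repeats)
  stage_stats$repeat_removed <- mr$removed
  bs <- mr$breaks

  list(breaks = bs, stage_stats = stage_stats, read_calls = pf$calls)
}
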