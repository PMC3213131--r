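#' Compare pipeline calls against a planted truth set
#'
#' A truth CNV is recovered when the same sample has a QC-passing call of
#' matching type (deletion family vs duplication) with reciprocal overlap
#' at least `fraction` in both directions. Calls matching no truth CNV
#' are false calls. Breakpoint error is the mean of the absolute start
#' and end offsets of each recovered event's best-matching call.
#'
#' @param calls pipeline call data.frame (QC-passing rows are used)
#' @param truth truth-set data.frame (`sample`, `chrom`, `start`, `end`,
#'   `type`)
#' @param design optional `probe_design`; when given, the local
#'   inter-probe gap at each truth CNV is reported alongside the error
#' @param fraction reciprocal-overlap fraction for matching
#' @return list: `sensitivity`, `n_truth`, `n_recovered`, `n_false`,
#'   `per_event` (data.frame with `recovered`, `bp_error`, `probe_gap`)
#' @export
evaluate_recovery <- function(calls, truth, design = NULL, fraction = 0.5) {
  if ("qc_pass" %in% names(calls)) calls <- calls[calls$qc_pass, , drop = FALSE]
  rownames(calls) <- NULL
  n_truth <- nrow(truth)
  recovered <- rep(FALSE, n_truth)
  bp_error <- rep(NA_real_, n_truth)
  probe_gap <- rep(NA_real_, n_truth)
  matched_calls <- rep(FALSE, nrow(calls))
  if (n_truth > 0 && nrow(calls) > 0) {
    hits <- overlap_pairs(truth, calls)
    ok <- hits$frac_q >= fraction & hits$frac_s >= fraction &
      truth$sample[hits$query] == calls$sample[hits$subject] &
      type_matches(truth$type[hits$query], calls$type[hits$subject])
    hits <- hits[ok, , drop = FALSE]
    if (nrow(hits)) {
      matched_calls[unique(hits$subject)] <- TRUE
      hits <- hits[order(hits$query, -hits$width), , drop = FALSE]
      best <- hits[!duplicated(hits$query), , drop = FALSE]
      recovered[best$query] <- TRUE
      bp_error[best$query] <-
        (abs(calls$start[best$subject] - truth$start[best$query]) +
         abs(calls$end[best$subject] - truth$end[best$query])) / 2
    }
  }
  if (!is.null(design) && n_truth > 0) {
    for (i in seq_len(n_truth)) {
      idx <- which(design$chrom == truth$chrom[i])
      if (length(idx) > 1) {
        near <- idx[design$start[idx] >= truth$start[i] - 2e5 &
                    design$start[idx] <= truth$end[i] + 2e5]
        if (length(near) > 1) probe_gap[i] <- max(diff(design$start[near]))
      }
    }
  }
  list(sensitivity = if (n_truth) mean(recovered) else NA_real_,
       n_truth = n_truth, n_recovered = sum(recovered),
       n_false = sum(!matched_calls),
       per_event = data.frame(recovered = recovered, bp_error = bp_error,
                              probe_gap = probe_gap))
}
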