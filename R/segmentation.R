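#' Chromosome-wise z-score transform of a log2-ratio track
#'
#' Normalized log2 ratios are converted to z-scores using
#' chromosome-specific means and standard deviations (sample SD over all
#' probes of the chromosome, CNV probes included; a median/MAD fit is
#' available via `robust`). This removes per-chromosome baseline offsets
#' before HMM decoding.
#'
#' @param values numeric log2 ratios aligned to `design` (NA allowed;
#'   NA probes get NA z and are excluded from the fit)
#' @param design a `probe_design`
#' @param robust use median/MAD instead of mean/SD
#' @return a `ztrack` list: `z` (per-probe z-scores), `stats`
#'   (data.frame `chrom`, `mu`, `sigma`, `n`)
#' @export
zscore_transform <- function(values, design, robust = FALSE) {
  stopifnot(length(values) == nrow(design))
  z <- rep(NA_real_, length(values))
  st <- list()
  for (chrom in unique(design$chrom)) {
    idx <- which(design$chrom == chrom)
    x <- values[idx]
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("chromosome ", chrom, " has fewer than 2 usable probes")
    mu <- if (robust) stats::median(x[ok]) else mean(x[ok])
    sigma <- if (robust) stats::mad(x[ok]) else stats::sd(x[ok])
    if (!is.finite(sigma) || sigma == 0)
      stop("degenerate chromosome ", chrom, ": zero variance in log2 ratios")
    z[idx] <- (x - mu) / sigma
    st[[length(st) + 1]] <- data.frame(chrom = chrom, mu = mu, sigma = sigma,
                                       n = sum(ok), stringsAsFactors = FALSE)
  }
  structure(list(z = z, stats = do.call(rbind, st)), class = "ztrack")
}

#' Merge per-probe HMM states into segments
#'
#' Consecutive probes of the same state join one segment only when the
#' inter-probe gap (next probe start minus previous probe end) is strictly
#' less than `gap_limit`. Normal-state segments are retained because the
#' bridging step needs them. NA-state probes (missing intensities) break
#' segments.
#'
#' @param states character state vector aligned to `design`
#' @param z numeric z-scores aligned to `design`
#' @param design a `probe_design`
#' @param gap_limit merge distance bound in bp (strict `<`)
#' @return data.frame of segments: `chrom`, `state`, `first`, `last`
#'   (probe indices into the design), `start`, `end`, `n_probes`, `mean_z`
#' @export
assemble_segments <- function(states, z, design, gap_limit = 50000) {
  stopifnot(length(states) == nrow(design), length(z) == nrow(design))
  segs <- list()
  for (chrom in unique(design$chrom)) {
    idx <- which(design$chrom == chrom)
    st <- states[idx]
    gap_before <- c(Inf, design$start[idx][-1] - design$end[idx][-length(idx)])
    changed <- st[-1] != st[-length(st)]
    changed[is.na(changed)] <- TRUE
    new_seg <- c(TRUE, changed) | gap_before >= gap_limit | is.na(st)
    grp <- cumsum(new_seg)
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (is.na(states[members[1]])) next
      segs[[length(segs) + 1]] <- data.frame(
        chrom = chrom, state = states[members[1]],
        first = members[1], last = members[length(members)],
        start = design$start[members[1]], end = design$end[members[length(members)]],
        n_probes = length(members), mean_z = mean(z[members]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) {
    return(data.frame(chrom = character(), state = character(), first = integer(),
                      last = integer(), start = numeric(), end = numeric(),
                      n_probes = integer(), mean_z = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Bridge same-state segments across short intervening sequence
#'
#' Two non-normal segments of the same state merge, together with the
#' intervening probes, into a single variant when the intervening
#' sequence contains at most `max_probes` probes AND spans at most
#' `max_gap` bp. Applied left-to-right until a fixed point; probe counts
#' include the intervening probes and mean z is recomputed over the full
#' span. Returns only the non-normal variants.
#'
#' @param segments output of [assemble_segments()]
#' @param z z-scores aligned to the design
#' @param design a `probe_design`
#' @param max_probes intervening probe bound (`<=`)
#' @param max_gap intervening span bound in bp (`<=`)
#' @return data.frame of variants with the segment columns
#' @export
bridge_segments <- function(segments, z, design, max_probes = 5, max_gap = 10000) {
  vars <- segments[segments$state != "normal", , drop = FALSE]
  if (nrow(vars) < 2) {
    rownames(vars) <- NULL
    return(vars)
  }
  vars <- vars[order(vars$chrom, vars$first), , drop = FALSE]
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < nrow(vars)) {
      a <- vars[i, ]; b <- vars[i + 1, ]
      if (a$chrom == b$chrom && a$state == b$state) {
        inter_probes <- b$first - a$last - 1
        inter_span <- design$start[b$first] - design$end[a$last]
        if (inter_probes <= max_probes && inter_span <= max_gap) {
          members <- a$first:b$last
          vars[i, c("last", "end", "n_probes", "mean_z")] <- list(
            b$last, b$end, length(members), mean(z[members], na.rm = TRUE))
          vars <- vars[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
          next
        }
      }
      i <- i + 1
    }
    if (!merged_any) break
  }
  rownames(vars) <- NULL
  vars
}

#' Apply post-HMM QC thresholds to variants
#'
#' A variant passes iff `|mean z| >` the z threshold, its probe count is
#' strictly greater than the probe threshold, its size strictly exceeds
#' the hotspot-class size floor, and — when classified non-hotspot — also
#' the non-hotspot floor. Rejected variants are retained with
#' `qc_pass = FALSE` and a reason code. Deletion segments whose mean z
#' falls below the homozygous threshold are labelled
#' `homozygous_deletion`.
#'
#' @param variants output of [bridge_segments()]
#' @param sample sample id to stamp on the calls
#' @param config an [analysis_config()]
#' @param layout a `genome_layout` (for hotspot classification)
#' @return CNV call data.frame: `sample`, `chrom`, `start`, `end`, `size`,
#'   `type`, `n_probes`, `mean_z`, `hotspot_class`, `qc_pass`,
#'   `reject_reason`
#' @export
qc_filter_calls <- function(variants, sample, config = analysis_config(),
                            layout = NULL) {
  if (nrow(variants) == 0) {
    return(data.frame(sample = character(), chrom = character(), start = numeric(),
                      end = numeric(), size = numeric(), type = character(),
                      n_probes = integer(), mean_z = numeric(),
                      hotspot_class = character(), qc_pass = logical(),
                      reject_reason = character(), stringsAsFactors = FALSE))
  }
  type <- ifelse(variants$state == "increased", "duplication",
                 ifelse(variants$mean_z < config$homdel_z_threshold,
                        "homozygous_deletion", "deletion"))
  calls <- data.frame(sample = sample, chrom = variants$chrom,
                      start = variants$start, end = variants$end,
                      size = variants$end - variants$start, type = type,
                      n_probes = variants$n_probes, mean_z = variants$mean_z,
                      stringsAsFactors = FALSE)
  calls$hotspot_class <- if (is.null(layout)) NA_character_ else
    classify_hotspot(calls, layout, config$reciprocal_overlap)
  reasons <- character(nrow(calls))
  fail <- function(cond, code) {
    reasons[cond] <<- ifelse(nzchar(reasons[cond]), paste0(reasons[cond], ";", code), code)
  }
  fail(!(abs(calls$mean_z) > config$z_threshold), "low_z")
  fail(!(calls$n_probes > config$min_probes), "few_probes")
  fail(!(calls$size > config$min_size_hotspot), "small")
  fail(!is.na(calls$hotspot_class) & calls$hotspot_class == "non_HS" &
         !(calls$size > config$min_size_nonhotspot), "small_nonhotspot")
  calls$qc_pass <- !nzchar(reasons)
  calls$reject_reason <- ifelse(calls$qc_pass, NA_character_, reasons)
  calls
}

#' Per-sample quality control
#'
#' A sample fails when the autosomal log2-ratio SD exceeds the configured
#' ceiling (strictly) or its raw variant count exceeds the configured
#' multiple of the cohort median raw count (floored at 1 so sparse
#' cohorts do not flag every carrier). The rule is an explicit, tunable
#' stand-in: array QC criteria are platform-specific.
#'
#' @param values log2 ratios aligned to `design`
#' @param design a `probe_design`
#' @param n_raw_calls raw (pre-QC) variant count for the sample
#' @param cohort_median_calls cohort median raw variant count
#' @param config an [analysis_config()]
#' @return list `status` (`"pass"`/`"fail"`), `reason` (NA when passing),
#'   `sd` (observed autosomal SD)
#' @export
sample_qc <- function(values, design, n_raw_calls = 0,
                      cohort_median_calls = NA, config = analysis_config()) {
  autosomal <- !design$chrom %in% c("chrX", "chrY")
  s <- stats::sd(values[autosomal], na.rm = TRUE)
  reason <- NA_character_
  if (s > config$sample_sd_ceiling) {
    reason <- "high_sd"
  } else if (!is.na(cohort_median_calls) &&
             n_raw_calls > config$sample_call_multiple * max(cohort_median_calls, 1)) {
    reason <- "excess_calls"
  }
  list(status = if (is.na(reason)) "pass" else "fail", reason = reason, sd = s)
}

#' Call CNVs for one sample from a log2-ratio track
#'
#' The full segmentation pipeline: chromosome-wise z-scoring, three-state
#' Viterbi decoding, segment assembly (< 50 kbp same-state merging),
#' bridging (<= 5 probes and <= 10 kbp) and QC filtering.
#'
#' @param values log2 ratios aligned to `design`
#' @param design a `probe_design`
#' @param sample sample id
#' @param config an [analysis_config()]
#' @param layout optional `genome_layout` for hotspot classification
#' @param params an `hmm_params`
#' @return CNV call data.frame (see [qc_filter_calls()])
#' @export
call_sample <- function(values, design, sample = "sample", config = analysis_config(),
                        layout = NULL, params = hmm_params()) {
  zt <- zscore_transform(values, design, robust = config$robust_zscore)
  states <- decode_track(zt, design, params)
  segs <- assemble_segments(states, zt$z, design, config$segment_gap_limit)
  vars <- bridge_segments(segs, zt$z, design, config$bridge_max_probes,
                          config$bridge_max_gap)
  qc_filter_calls(vars, sample, config, layout)
}

#' Call CNVs for every sample of a log2-ratio matrix
#'
#' @param mat probes x samples matrix (rownames = probe ids)
#' @param design a `probe_design`
#' @param config an [analysis_config()]
#' @param layout optional `genome_layout`
#' @param params an `hmm_params`
#' @return combined CNV call data.frame over all samples
#' @export
call_matrix <- function(mat, design, config = analysis_config(), layout = NULL,
                        params = hmm_params()) {
  if (!identical(rownames(mat), design$probe_id))
    stop("matrix rows are not aligned to the probe design")
  out <- lapply(colnames(mat), function(s)
    call_sample(mat[, s], design, s, config, layout, params))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
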