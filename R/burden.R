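#' Fisher exact test with the sample (cross-product) odds ratio
#'
#' The odds ratio is the unconditional cross-product `a*d / (b*c)`
#' (reported as `Inf` when `b*c = 0` and `a*d > 0`, NA when both products
#' vanish), not the conditional MLE, because that is the quantity printed
#' by case-control CNV burden studies. The two-sided p-value follows the
#' point-probability rule: the sum of hypergeometric probabilities of all
#' tables (with the observed margins) whose point probability does not
#' exceed the observed one. A one-sided (greater) p and a
#' Haldane-Anscombe-corrected OR are available via flags.
#'
#' @param table 2x2 matrix or length-4 vector `c(a, b, c, d)` laid out as
#'   rows = groups, columns = outcome yes/no
#' @param label comparison label carried into the result
#' @param alternative `"two.sided"` (default) or `"greater"`
#' @param haldane add 0.5 to every cell for the OR (zero-cell tables)
#' @return a `burden_result` list: `label`, `table`, `odds_ratio`,
#'   `p_value`, `test`
#' @export
fisher_or <- function(table, label = "", alternative = c("two.sided", "greater"),
                      haldane = FALSE) {
  alternative <- match.arg(alternative)
  x <- as.numeric(table)
  if (length(x) != 4) stop("need a 2x2 table")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("table margins must be positive")
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else if (b * c > 0) {
    (a * d) / (b * c)
  } else if (a * d > 0) Inf else NA_real_
  # conditional on margins, a ~ hypergeometric
  lo <- max(0, a - d)
  hi <- min(a + b, a + c)
  support <- lo:hi
  probs <- stats::dhyper(support, a + b, c + d, a + c)
  p_obs <- stats::dhyper(a, a + b, c + d, a + c)
  p <- if (alternative == "two.sided") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    sum(probs[support >= a])
  }
  structure(list(label = label,
                 table = matrix(x, 2, 2, byrow = TRUE,
                                dimnames = list(group = c("g1", "g2"),
                                                outcome = c("yes", "no"))),
                 odds_ratio = or, p_value = min(1, p),
                 test = paste0("fisher_exact_", alternative)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("%s: OR = %s, p = %.4g (%s)\n",
              if (nzchar(x$label)) x$label else "comparison",
              format(x$odds_ratio, digits = 4), x$p_value, x$test))
  print(x$table)
  invisible(x)
}

#' Largest CNV per sample
#'
#' One value per pass-QC proband, zero for samples without calls — the
#' per-individual statistic behind largest-CNV survivor functions.
#'
#' @param calls QC-passed call data.frame
#' @param meta sample metadata; samples with `qc_status == "fail"` are
#'   dropped, parents (role != proband) excluded
#' @param types CNV types to consider
#' @return data.frame `sample`, `cohort`, `max_size`
#' @export
largest_cnv_per_sample <- function(calls, meta,
                                   types = c("deletion", "duplication",
                                             "homozygous_deletion")) {
  keep <- meta
  if ("role" %in% names(keep)) keep <- keep[keep$role == "proband", , drop = FALSE]
  if ("qc_status" %in% names(keep)) keep <- keep[keep$qc_status != "fail", , drop = FALSE]
  calls <- calls[calls$type %in% types, , drop = FALSE]
  if ("qc_pass" %in% names(calls)) calls <- calls[calls$qc_pass, , drop = FALSE]
  mx <- tapply(calls$size, calls$sample, max)
  out <- data.frame(sample = keep$sample, cohort = keep$cohort,
                    max_size = as.numeric(mx[keep$sample]),
                    stringsAsFactors = FALSE)
  out$max_size[is.na(out$max_size)] <- 0
  rownames(out) <- NULL
  out
}

#' Survivor function of the largest CNV per individual
#'
#' For each grid size, the fraction of the cohort whose largest CNV is at
#' least that size; individuals without any call never count as carriers,
#' so the value at size 0 is the fraction of individuals with at least
#' one call. Non-increasing in size by construction.
#'
#' @param maxima data.frame from [largest_cnv_per_sample()] (or with
#'   columns `cohort`, `max_size`)
#' @param grid ascending size grid (bp)
#' @return data.frame `cohort`, `size`, `fraction`
#' @export
survivor_curve <- function(maxima, grid) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  by_cohort <- split(maxima$max_size, maxima$cohort)
  rows <- lapply(names(by_cohort), function(co) {
    m <- by_cohort[[co]]
    if (!length(m)) stop("empty cohort: ", co)
    data.frame(cohort = co, size = grid,
               fraction = vapply(grid, function(s) mean(m >= s & m > 0), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Large-CNV burden comparison between two cohorts
#'
#' Builds the 2x2 table of carriers (largest CNV strictly greater than
#' `threshold`) versus non-carriers and applies [fisher_or()]. A CNV of
#' exactly the threshold size does not make a carrier.
#'
#' @param maxima_a,maxima_b numeric vectors of per-sample largest sizes
#' @param threshold carrier size threshold in bp (strict `>`)
#' @param label comparison label
#' @return a `burden_result`
#' @export
large_cnv_burden_test <- function(maxima_a, maxima_b, threshold = 1e6,
                                  label = "large_cnv") {
  if (!length(maxima_a) || !length(maxima_b)) stop("both cohorts must be non-empty")
  a <- sum(maxima_a > threshold); b <- length(maxima_a) - a
  c <- sum(maxima_b > threshold); d <- length(maxima_b) - c
  fisher_or(c(a, b, c, d), label = label)
}

cohort_units <- function(meta, cohort) {
  keep <- meta
  if ("role" %in% names(keep)) keep <- keep[keep$role == "proband", , drop = FALSE]
  if ("qc_status" %in% names(keep)) keep <- keep[keep$qc_status != "fail", , drop = FALSE]
  keep$sample[keep$cohort == cohort]
}

#' Rare-CNV carrier, de novo and two-hit cohort comparisons
#'
#' Each builds a 2x2 contingency table and delegates to [fisher_or()]:
#' \itemize{
#'   \item `rare_carrier_test`: unit = individual; outcome = carries at
#'     least one strict-rare call.
#'   \item `de_novo_test`: unit = strict-rare CNV with resolved
#'     inheritance (calls with NA inheritance are excluded); outcome =
#'     arose de novo.
#'   \item `two_hit_test`: unit = strict-rare-carrying individual;
#'     outcome = carries two or more strict-rare calls.
#' }
#'
#' @param annotated annotated call data.frame (see [annotate_calls()])
#' @param meta sample metadata
#' @param cohort_a,cohort_b cohort labels to compare (group a vs b)
#' @return a `burden_result`
#' @export
rare_carrier_test <- function(annotated, meta, cohort_a, cohort_b) {
  rare <- annotated[annotated$rare_strict, , drop = FALSE]
  tab <- vapply(c(cohort_a, cohort_b), function(co) {
    units <- cohort_units(meta, co)
    if (!length(units)) stop("no eligible individuals in cohort ", co)
    carriers <- sum(units %in% rare$sample)
    c(carriers, length(units) - carriers)
  }, numeric(2))
  fisher_or(c(tab[, 1], tab[, 2]),
            label = sprintf("rare_carrier %s vs %s", cohort_a, cohort_b))
}

#' @rdname rare_carrier_test
#' @export
de_novo_test <- function(annotated, meta, cohort_a, cohort_b) {
  rare <- annotated[annotated$rare_strict & !is.na(annotated$inheritance), , drop = FALSE]
  tab <- vapply(c(cohort_a, cohort_b), function(co) {
    units <- cohort_units(meta, co)
    ev <- rare[rare$sample %in% units, , drop = FALSE]
    if (!nrow(ev)) stop("no rare CNVs with resolved inheritance in cohort ", co)
    dn <- sum(ev$inheritance == "de_novo")
    c(dn, nrow(ev) - dn)
  }, numeric(2))
  fisher_or(c(tab[, 1], tab[, 2]),
            label = sprintf("de_novo %s vs %s", cohort_a, cohort_b))
}

#' @rdname rare_carrier_test
#' @export
two_hit_test <- function(annotated, meta, cohort_a, cohort_b) {
  rare <- annotated[annotated$rare_strict, , drop = FALSE]
  tab <- vapply(c(cohort_a, cohort_b), function(co) {
    units <- cohort_units(meta, co)
    counts <- table(rare$sample[rare$sample %in% units])
    if (!length(counts)) stop("no rare-CNV carriers in cohort ", co)
    two <- sum(counts >= 2)
    c(two, length(counts) - two)
  }, numeric(2))
  fisher_or(c(tab[, 1], tab[, 2]),
            label = sprintf("two_hit %s vs %s", cohort_a, cohort_b))
}

#' Per-cohort CNV summary
#'
#' CNV count, mean size, deletion proportion (homozygous deletions count
#' as deletions), proportion of gene-breaking CNVs and mean gene density
#' per CNV, per cohort.
#'
#' @param calls annotated call data.frame (needs `breaks_gene` and
#'   `gene_count` for the gene columns; NA otherwise)
#' @param meta sample metadata
#' @return one data.frame row per cohort present
#' @export
cohort_summary <- function(calls, meta) {
  probands <- if ("role" %in% names(meta)) meta[meta$role == "proband", ] else meta
  calls <- calls[calls$sample %in% probands$sample, , drop = FALSE]
  calls$cohort <- probands$cohort[match(calls$sample, probands$sample)]
  rows <- lapply(split(calls, calls$cohort), function(d) {
    data.frame(cohort = d$cohort[1], n_cnvs = nrow(d),
               mean_size = mean(d$size),
               deletion_prop = mean(d$type %in% c("deletion", "homozygous_deletion")),
               breaks_gene_prop = if ("breaks_gene" %in% names(d))
                 mean(d$breaks_gene) else NA_real_,
               mean_gene_density = if ("gene_count" %in% names(d))
                 mean(d$gene_count) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-individual CNV counts by size bin
#'
#' Left-closed right-open bins; deletions and duplications reported
#' separately; counts normalized by the number of individuals.
#'
#' @param calls call data.frame
#' @param meta sample metadata (defines the individual denominator)
#' @param breaks ascending bin edges in bp
#' @return data.frame `type`, `bin_start`, `bin_end`, `per_individual`
#' @export
size_histogram <- function(calls, meta, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly ascending")
  probands <- if ("role" %in% names(meta)) meta[meta$role == "proband", ] else meta
  if ("qc_status" %in% names(probands))
    probands <- probands[probands$qc_status != "fail", , drop = FALSE]
  n_ind <- nrow(probands)
  calls <- calls[calls$sample %in% probands$sample, , drop = FALSE]
  grp <- list(deletion = c("deletion", "homozygous_deletion"),
              duplication = "duplication")
  rows <- lapply(names(grp), function(ty) {
    sz <- calls$size[calls$type %in% grp[[ty]]]
    cnt <- vapply(seq_len(length(breaks) - 1), function(i)
      sum(sz >= breaks[i] & sz < breaks[i + 1]), numeric(1))
    data.frame(type = ty, bin_start = breaks[-length(breaks)],
               bin_end = breaks[-1], per_individual = cnt / n_ind,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median size of rare CNVs
#'
#' @param sizes numeric vector of rare-CNV sizes (bp); even counts
#'   average the two middle values
#' @return median size in bp
#' @export
median_rare_size <- function(sizes) {
  if (!length(sizes)) stop("no rare CNVs to take a median over")
  stats::median(sizes)
}

#' Power of a two-sided two-proportion test (normal approximation)
#'
#' Unpooled-variance normal approximation; at `delta = 0` the power
#' equals `alpha`, as it should for a two-sided test at the null.
#'
#' @param p0 baseline proportion
#' @param delta difference to detect (`p1 = p0 + delta`)
#' @param n1,n2 group sizes
#' @param alpha two-sided significance level
#' @return approximate power in (0, 1)
#' @export
two_proportion_power <- function(p0, delta, n1, n2, alpha = 0.05) {
  p1 <- p0 + delta
  stopifnot(p0 > 0, p0 < 1, p1 > 0, p1 < 1, n1 > 0, n2 > 0)
  se <- sqrt(p0 * (1 - p0) / n1 + p1 * (1 - p1) / n2)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-zc + abs(delta) / se) + stats::pnorm(-zc - abs(delta) / se)
}

#' Bonferroni correction helper for a set of burden results
#'
#' Off by default in every pipeline output (burden studies of this design
#' report raw p-values); provided for users who want familywise control.
#'
#' @param results list of `burden_result` objects
#' @return the list with an added `p_adjusted` element per result
#' @export
adjust_burden_results <- function(results) {
  p <- vapply(results, function(r) r$p_value, numeric(1))
  adj <- stats::p.adjust(p, method = "bonferroni")
  Map(function(r, pa) { r$p_adjusted <- pa; r }, results, adj)
}
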