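#' Cohort specification for the synthetic-data generator
#'
#' One spec per cohort: how many individuals, how often they carry a rare
#' planted CNV, the size distribution of planted events (log-uniform),
#' the deletion:duplication balance, the de novo fraction among planted
#' events and the probability that a carrier bears a second event
#' (two-hit). Defaults for the six study cohorts are provided by
#' [default_cohort_specs()].
#'
#' @param cohort cohort label (see [cohort_levels()])
#' @param n number of probands
#' @param carrier_prob probability an individual carries >= 1 planted rare CNV
#' @param size_range min/max planted CNV size (bp), sampled log-uniformly
#' @param deletion_prob probability a planted CNV is a deletion
#' @param de_novo_frac fraction of planted CNVs that are de novo
#' @param two_hit_prob probability a carrier bears a second planted CNV
#' @param trios whether probands come with father/mother samples
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(cohort, n, carrier_prob, size_range,
                        deletion_prob = 0.5, de_novo_frac = 0,
                        two_hit_prob = 0, trios = TRUE) {
  stopifnot(cohort %in% cohort_levels(), n >= 0,
            carrier_prob >= 0, carrier_prob <= 1,
            size_range[1] > 0, size_range[1] <= size_range[2],
            de_novo_frac >= 0, de_novo_frac <= 1,
            two_hit_prob >= 0, two_hit_prob <= 1)
  structure(list(cohort = cohort, n = n, carrier_prob = carrier_prob,
                 size_range = size_range, deletion_prob = deletion_prob,
                 de_novo_frac = de_novo_frac, two_hit_prob = two_hit_prob,
                 trios = trios), class = "cohort_spec")
}

#' Default cohort specs mirroring the study's carrier and de novo profiles
#'
#' Carrier probabilities follow the observed rare-CNV carrier rates
#' (control/dyslexia ~2%, autism ~10-12%, ID ~17-18%), de novo fractions
#' the observed rates (dyslexia 0, autism 0.40, ID 0.64), two-hit
#' probabilities the observed two-hit shares, and the size ranges are
#' log-uniform windows whose medians track the cohort median sizes
#' (hundreds of kbp for dyslexia up to multi-Mbp for ID/MCA). Sample
#' sizes default to a desk-scale fraction of the study's cohorts.
#'
#' @param scale multiplier on the per-cohort sample sizes
#' @return named list of `cohort_spec` objects
#' @export
default_cohort_specs <- function(scale = 0.1) {
  n <- function(x) max(2L, as.integer(round(x * scale)))
  list(
    control = cohort_spec("control", n(306), 0.02, c(60e3, 1.2e6),
                          deletion_prob = 0.4, de_novo_frac = 0, trios = FALSE),
    dyslexia = cohort_spec("dyslexia", n(322), 0.019, c(60e3, 1.2e6),
                           deletion_prob = 0.6, de_novo_frac = 0),
    autism_no_ID = cohort_spec("autism_no_ID", n(246), 0.102, c(100e3, 4e6),
                               deletion_prob = 0.45, de_novo_frac = 0.40),
    autism_ID = cohort_spec("autism_ID", n(90), 0.111, c(150e3, 12e6),
                            deletion_prob = 0.5, de_novo_frac = 0.40,
                            two_hit_prob = 0.10),
    ID = cohort_spec("ID", n(358), 0.168, c(150e3, 15e6),
                     deletion_prob = 0.5, de_novo_frac = 0.64,
                     two_hit_prob = 0.067),
    ID_MCA = cohort_spec("ID_MCA", n(73), 0.123, c(300e3, 20e6),
                         deletion_prob = 0.5, de_novo_frac = 0.64,
                         two_hit_prob = 0.44)
  )
}

#' Probe-level noise model for simulated log2 ratios
#'
#' Single-copy expectations on the log2 scale: a heterozygous deletion at
#' log2(1/2) = -1, a duplication at log2(3/2) = +0.585, homozygous
#' deletions floored at -3. Probe noise is Gaussian with SD `sigma`; each
#' chromosome of each sample receives a fixed baseline offset drawn with
#' SD `tau`, which is what the chromosome-wise z-scoring removes.
#'
#' @param sigma probe-level SD of log2 ratios
#' @param tau SD of per-chromosome baseline offsets
#' @param m_del,m_dup,m_homdel state means (log2 scale)
#' @return a `noise_model` list
#' @export
noise_model <- function(sigma = 0.15, tau = 0.1,
                        m_del = -1.0, m_dup = 0.585, m_homdel = -3.0) {
  stopifnot(sigma > 0, tau >= 0, m_del < 0, m_dup > 0, m_homdel < m_del)
  structure(list(sigma = sigma, tau = tau, m_del = m_del, m_dup = m_dup,
                 m_homdel = m_homdel), class = "noise_model")
}

## Draw one planted CNV interval: log-uniform size; located in a hotspot
## with probability hotspot_weight (start near the hotspot start), else
## uniformly on the genome.
draw_cnv_interval <- function(layout, size_range, hotspot_weight) {
  size <- round(exp(stats::runif(1, log(size_range[1]), log(size_range[2]))))
  use_hs <- nrow(layout$hotspots) > 0 && stats::runif(1) < hotspot_weight
  if (use_hs) {
    h <- layout$hotspots[sample.int(nrow(layout$hotspots), 1), ]
    chrom <- h$chrom
    start <- h$start + round(stats::runif(1, 0, max(1, (h$end - h$start) * 0.2)))
  } else {
    ci <- sample.int(nrow(layout$chromosomes), 1)
    chrom <- layout$chromosomes$chrom[ci]
    start <- round(stats::runif(1, 0, layout$chromosomes$length[ci] - size - 1))
  }
  len <- layout$chromosomes$length[match(chrom, layout$chromosomes$chrom)]
  start <- max(0, min(start, len - size - 1))
  data.frame(chrom = chrom, start = start, end = start + size, stringsAsFactors = FALSE)
}

#' Simulate cohorts, trios and the planted-CNV truth set
#'
#' Carrier status is Bernoulli per individual; carriers receive one
#' planted CNV (two with the spec's two-hit probability), de novo with the
#' spec's fraction. Inherited CNVs are copied into one randomly chosen
#' parent's truth; de novo CNVs appear in the proband only. Cohorts with
#' `trios = TRUE` get father and mother samples (role `father`/`mother`).
#'
#' @param layout a `genome_layout`
#' @param specs list of `cohort_spec` objects
#' @param seed integer seed
#' @param hotspot_weight probability a planted CNV sits at a hotspot locus
#' @return list with `meta` (sample metadata incl. `role`) and `truth`
#'   (`sample`, `chrom`, `start`, `end`, `type`, `inheritance`)
#' @export
simulate_cohorts <- function(layout, specs, seed, hotspot_weight = 0.5) {
  if (!length(specs)) stop("need at least one cohort spec")
  set.seed(derive_seed(seed, 3))
  meta <- list(); truth <- list()
  for (sp in specs) {
    if (sp$n == 0) next
    ids <- sprintf("%s_%03d", sp$cohort, seq_len(sp$n))
    fa <- if (sp$trios) paste0(ids, "_fa") else rep(NA_character_, sp$n)
    mo <- if (sp$trios) paste0(ids, "_mo") else rep(NA_character_, sp$n)
    meta[[length(meta) + 1]] <- data.frame(
      sample = ids, cohort = sp$cohort, father = fa, mother = mo,
      qc_status = "untested", role = "proband", stringsAsFactors = FALSE)
    if (sp$trios) {
      meta[[length(meta) + 1]] <- data.frame(
        sample = c(fa, mo), cohort = sp$cohort,
        father = NA_character_, mother = NA_character_,
        qc_status = "untested", role = rep(c("father", "mother"), each = sp$n),
        stringsAsFactors = FALSE)
    }
    carrier <- stats::runif(sp$n) < sp$carrier_prob
    for (i in which(carrier)) {
      n_events <- 1 + (stats::runif(1) < sp$two_hit_prob)
      placed <- NULL
      for (k in seq_len(n_events)) {
        for (try in 1:20) {
          iv <- draw_cnv_interval(layout, sp$size_range, hotspot_weight)
          clash <- !is.null(placed) && nrow(overlap_pairs(iv, placed)) > 0
          if (!clash) break
        }
        placed <- rbind(placed, iv)
        type <- if (stats::runif(1) < sp$deletion_prob) "deletion" else "duplication"
        de_novo <- sp$trios && stats::runif(1) < sp$de_novo_frac
        truth[[length(truth) + 1]] <- data.frame(
          sample = ids[i], chrom = iv$chrom, start = iv$start, end = iv$end,
          type = type, inheritance = if (!sp$trios) NA_character_ else
            if (de_novo) "de_novo" else "inherited",
          stringsAsFactors = FALSE)
        if (sp$trios && !de_novo) {
          parent <- if (stats::runif(1) < 0.5) fa[i] else mo[i]
          truth[[length(truth) + 1]] <- data.frame(
            sample = parent, chrom = iv$chrom, start = iv$start, end = iv$end,
            type = type, inheritance = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  meta <- do.call(rbind, meta)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), type = character(), inheritance = character(),
               stringsAsFactors = FALSE)
  rownames(meta) <- rownames(truth) <- NULL
  validate_sample_meta(meta)
  list(meta = meta, truth = truth)
}

#' Simulate probe log2-ratio tracks from a truth set
#'
#' Each probe value is `N(m_state + delta_c, sigma)` where `m_state` is 0
#' outside planted CNVs and the noise model's deletion/duplication mean
#' inside them (a probe belongs to a CNV when its midpoint falls inside),
#' and `delta_c ~ N(0, tau)` is fixed per chromosome per sample.
#'
#' @param design a `probe_design`
#' @param truth truth-set data.frame (see [simulate_cohorts()])
#' @param samples sample ids to simulate (default: all appearing in `truth`
#'   plus any in `meta` if given)
#' @param noise a `noise_model`
#' @param seed integer seed
#' @return numeric matrix probes x samples (rownames = probe ids)
#' @export
simulate_intensities <- function(design, truth, samples, noise = noise_model(),
                                 seed = 1) {
  set.seed(derive_seed(seed, 4))
  n_probes <- nrow(design)
  chroms <- unique(design$chrom)
  mid <- (design$start + design$end) / 2
  mat <- matrix(NA_real_, nrow = n_probes, ncol = length(samples),
                dimnames = list(design$probe_id, samples))
  for (j in seq_along(samples)) {
    delta <- stats::rnorm(length(chroms), 0, noise$tau)
    names(delta) <- chroms
    mu <- delta[design$chrom]
    tr <- truth[truth$sample == samples[j], , drop = FALSE]
    for (k in seq_len(nrow(tr))) {
      inside <- design$chrom == tr$chrom[k] & mid >= tr$start[k] & mid < tr$end[k]
      m <- switch(tr$type[k],
                  deletion = noise$m_del,
                  duplication = noise$m_dup,
                  homozygous_deletion = noise$m_homdel,
                  stop("unknown CNV type in truth: ", tr$type[k]))
      mu[inside] <- mu[inside] + m
    }
    mat[, j] <- mu + stats::rnorm(n_probes, 0, noise$sigma)
  }
  mat
}

#' Simulate a frequency-annotated control CNV map
#'
#' Places polymorphic CNV loci (preferentially inside hotspot regions) and
#' assigns each a control carrier count drawn from `count_pool`, emulating
#' a population CNV frequency map: a mixture of common polymorphisms
#' (counts in the tens to hundreds) and rare-but-present events (counts
#' 1-8, i.e. below 0.1% of the default 8,635 controls).
#'
#' @param layout a `genome_layout`
#' @param n_controls control individuals behind the map
#' @param n_loci number of polymorphic loci
#' @param count_pool integer counts sampled (with replacement) per locus
#' @param hotspot_fraction fraction of loci placed inside hotspots
#' @param size_range locus size range (bp), log-uniform
#' @param seed integer seed
#' @return control-map data.frame (`chrom`, `start`, `end`, `type`,
#'   `count`) with attribute `n_controls`
#' @export
simulate_control_map <- function(layout, n_controls = 8635, n_loci = 40,
                                 count_pool = c(1:8, 15, 25, 60, 150, 400),
                                 hotspot_fraction = 0.7,
                                 size_range = c(50e3, 500e3), seed = 1) {
  stopifnot(n_controls > 0)
  set.seed(derive_seed(seed, 5))
  rows <- list()
  for (i in seq_len(n_loci)) {
    iv <- draw_cnv_interval(layout, size_range, hotspot_fraction)
    rows[[i]] <- data.frame(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      type = sample(c("deletion", "duplication"), 1),
      count = sample(count_pool, 1), stringsAsFactors = FALSE)
  }
  map <- if (length(rows)) normalize_intervals(do.call(rbind, rows)) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               type = character(), count = numeric(), stringsAsFactors = FALSE)
  map <- map[map$count > 0, , drop = FALSE]
  rownames(map) <- NULL
  attr(map, "n_controls") <- n_controls
  map
}
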