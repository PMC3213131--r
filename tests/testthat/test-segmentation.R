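test_that("z-transform uses chromosome-specific mean and sample SD", {
  d <- grid_design(4)
  zt <- zscore_transform(c(0, 0, 0, 2), d)
  expect_equal(zt$z, c(-0.5, -0.5, -0.5, 1.5))
  expect_equal(zt$stats$mu, 0.5)
  expect_equal(zt$stats$sigma, 1)
  # location invariance: shifting one chromosome leaves its z unchanged
  d2 <- rbind(grid_design(4), grid_design(4, chrom = "chr2"))
  class(d2) <- c("probe_design", "data.frame")
  z_a <- zscore_transform(c(0, 0, 0, 2, 1, 2, 3, 4), d2)
  z_b <- zscore_transform(c(0, 0, 0, 2, 1, 2, 3, 4) + rep(c(0, 10), each = 4), d2)
  expect_equal(z_a$z, z_b$z)
  expect_error(zscore_transform(rep(1, 4), d), "degenerate chromosome chr1")
})

test_that("viterbi decodes flat tracks as normal and matches brute force", {
  p <- hmm_params()
  expect_equal(viterbi_decode(rep(0, 20), p), rep("normal", 20))
  set.seed(7)
  for (k in 1:40) {
    n <- sample(2:8, 1)
    z <- rnorm(n, 0, 2.5)
    expect_equal(viterbi_decode(z, p), brute_force_viterbi(z, p))
  }
})

test_that("a deep run is decoded exactly over its probes", {
  set.seed(3)
  z <- rnorm(100, 0, 1)
  z[41:70] <- -4
  states <- viterbi_decode(z, hmm_params())
  expect_equal(which(states == "decreased"), 41:70)
})

test_that("segment assembly merges strictly below the 50 kbp gap", {
  mk <- function(gap) {
    starts <- c(0, 100 + gap)   # two probes of 100 bp
    d <- data.frame(chrom = "chr1", start = starts, end = starts + 100,
                    probe_id = c("a", "b"), class = "backbone",
                    stringsAsFactors = FALSE)
    class(d) <- c("probe_design", "data.frame")
    assemble_segments(c("decreased", "decreased"), c(-3, -3), d, gap_limit = 50000)
  }
  expect_equal(nrow(mk(49999)), 1)
  expect_equal(nrow(mk(50000)), 2)
  # alternating states give one segment per probe
  d <- grid_design(6)
  segs <- assemble_segments(rep(c("decreased", "increased"), 3),
                            rep(c(-3, 3), 3), d, 50000)
  expect_equal(nrow(segs), 6)
  expect_equal(segs$n_probes, rep(1L, 6))
})

test_that("bridging obeys both the probe and the span bound", {
  # 12 DEL probes + 4 normal probes, intervening span ~9 kbp -> one variant
  starts <- c(seq(0, by = 3000, length.out = 12),
              seq(34000, by = 2000, length.out = 4),
              seq(42000, by = 3000, length.out = 15))
  d <- data.frame(chrom = "chr1", start = starts, end = starts + 50,
                  probe_id = sprintf("p%02d", seq_along(starts)), class = "hotspot",
                  stringsAsFactors = FALSE)
  class(d) <- c("probe_design", "data.frame")
  st <- c(rep("decreased", 12), rep("normal", 4), rep("decreased", 15))
  z <- ifelse(st == "decreased", -3, 0)
  segs <- assemble_segments(st, z, d, 50000)
  out <- bridge_segments(segs, z, d, 5, 10000)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_probes, 31L)
  expect_equal(out$state, "decreased")
  expect_equal(out$mean_z, mean(z))

  # 6 intervening probes: probe bound fails
  starts6 <- c(seq(0, by = 3000, length.out = 12),
               seq(34000, by = 1000, length.out = 6),
               seq(41000, by = 3000, length.out = 15))
  d6 <- d; d6 <- data.frame(chrom = "chr1", start = starts6, end = starts6 + 50,
                            probe_id = sprintf("p%02d", seq_along(starts6)),
                            class = "hotspot", stringsAsFactors = FALSE)
  class(d6) <- c("probe_design", "data.frame")
  st6 <- c(rep("decreased", 12), rep("normal", 6), rep("decreased", 15))
  z6 <- ifelse(st6 == "decreased", -3, 0)
  out6 <- bridge_segments(assemble_segments(st6, z6, d6, 50000), z6, d6, 5, 10000)
  expect_equal(nrow(out6), 2)

  # 3 intervening probes spanning 12 kbp: span bound fails
  starts3 <- c(seq(0, by = 3000, length.out = 12),
               seq(36000, by = 3000, length.out = 3),
               seq(45200, by = 3000, length.out = 15))
  d3 <- data.frame(chrom = "chr1", start = starts3, end = starts3 + 50,
                   probe_id = sprintf("p%02d", seq_along(starts3)),
                   class = "hotspot", stringsAsFactors = FALSE)
  class(d3) <- c("probe_design", "data.frame")
  st3 <- c(rep("decreased", 12), rep("normal", 3), rep("decreased", 15))
  z3 <- ifelse(st3 == "decreased", -3, 0)
  out3 <- bridge_segments(assemble_segments(st3, z3, d3, 50000), z3, d3, 5, 10000)
  expect_equal(nrow(out3), 2)
})

test_that("QC thresholds are strict at their boundaries", {
  mk_var <- function(n_probes, mean_z, size) {
    data.frame(chrom = "chr1", state = if (mean_z < 0) "decreased" else "increased",
               first = 1L, last = n_probes, start = 0, end = size,
               n_probes = n_probes, mean_z = mean_z, stringsAsFactors = FALSE)
  }
  cfg <- analysis_config()
  r10 <- qc_filter_calls(mk_var(10, -3, 60000), "s", cfg)
  expect_false(r10$qc_pass)
  expect_match(r10$reject_reason, "few_probes")
  r15 <- qc_filter_calls(mk_var(20, 1.5, 60000), "s", cfg)
  expect_false(r15$qc_pass)
  expect_match(r15$reject_reason, "low_z")
  ok <- qc_filter_calls(mk_var(20, -3, 60000), "s", cfg)
  expect_true(ok$qc_pass)
  expect_equal(ok$type, "deletion")
  deep <- qc_filter_calls(mk_var(20, -8, 60000), "s", cfg)
  expect_equal(deep$type, "homozygous_deletion")
  exact_size <- qc_filter_calls(mk_var(20, -3, 50000), "s", cfg)
  expect_false(exact_size$qc_pass)
})

test_that("non-hotspot calls face the larger size floor", {
  layout <- tiny_layout()
  h <- layout$hotspots[1, ]
  mk <- function(chrom, start, size) {
    data.frame(chrom = chrom, state = "decreased", first = 1L, last = 20L,
               start = start, end = start + size, n_probes = 20L, mean_z = -3,
               stringsAsFactors = FALSE)
  }
  in_hs <- qc_filter_calls(mk(h$chrom, h$start, 100e3), "s", layout = layout)
  expect_true(in_hs$qc_pass)
  # far from any hotspot: 100 kbp fails, 400 kbp passes
  far <- layout$chromosomes$length[1] - 2e6
  out_small <- qc_filter_calls(mk("chr1", far, 100e3), "s", layout = layout)
  expect_false(out_small$qc_pass)
  expect_match(out_small$reject_reason, "small_nonhotspot")
  out_big <- qc_filter_calls(mk("chr1", far, 400e3), "s", layout = layout)
  expect_true(out_big$qc_pass)
})

test_that("lowering thresholds never removes a passing call", {
  layout <- tiny_layout()
  design <- tiny_design(layout)
  sim <- simulate_cohorts(layout, list(cohort_spec("ID", 6, 1, c(2e5, 2e6),
                                                   trios = FALSE)), seed = 21)
  mat <- simulate_intensities(design, sim$truth, sim$meta$sample, seed = 21)
  strictc <- analysis_config()
  loose <- analysis_config(z_threshold = 1.0, min_probes = 5)
  for (s in colnames(mat)) {
    a <- call_sample(mat[, s], design, s, strictc, layout)
    b <- call_sample(mat[, s], design, s, loose, layout)
    pass_a <- a[a$qc_pass, c("chrom", "start", "end")]
    pass_b <- b[b$qc_pass, c("chrom", "start", "end")]
    expect_true(nrow(merge(pass_a, pass_b)) == nrow(pass_a))
  }
})

test_that("planted CNVs of >= 20 probes are recovered with probe-level breakpoints", {
  layout <- std_layout()
  design <- std_design()
  sim <- simulate_cohorts(layout, list(cohort_spec("ID", 10, 1, c(8e5, 3e6),
                                                   trios = FALSE)), seed = 31)
  mat <- simulate_intensities(design, sim$truth, sim$meta$sample,
                              noise_model(sigma = 0.15), seed = 31)
  calls <- call_matrix(mat, design, layout = layout)
  ev <- evaluate_recovery(calls, sim$truth, design)
  expect_gte(ev$sensitivity, 0.95)
  rec <- ev$per_event[ev$per_event$recovered, ]
  expect_true(all(rec$bp_error <= rec$probe_gap))
})

test_that("sample QC fails noisy samples and passes the boundary", {
  d <- grid_design(500)
  set.seed(5)
  clean <- rnorm(500, 0, 0.1)
  noisy <- rnorm(500, 0, 0.6)
  expect_equal(sample_qc(clean, d)$status, "pass")
  qn <- sample_qc(noisy, d)
  expect_equal(qn$status, "fail")
  expect_equal(qn$reason, "high_sd")
  # exactly at the ceiling passes (strict inequality)
  at <- clean / sd(clean) * 0.35
  expect_equal(sample_qc(at, d)$status, "pass")
  # call-count rule
  expect_equal(sample_qc(clean, d, n_raw_calls = 10, cohort_median_calls = 3)$status,
               "fail")
  expect_equal(sample_qc(clean, d, n_raw_calls = 9, cohort_median_calls = 3)$status,
               "pass")
})

test_that("the calling pipeline is deterministic", {
  layout <- tiny_layout()
  design <- tiny_design(layout)
  sim <- simulate_cohorts(layout, list(cohort_spec("ID", 3, 1, c(5e5, 2e6),
                                                   trios = FALSE)), seed = 8)
  mat <- simulate_intensities(design, sim$truth, sim$meta$sample, seed = 8)
  c1 <- call_matrix(mat, design, layout = layout)
  c2 <- call_matrix(mat, design, layout = layout)
  expect_identical(c1, c2)
})
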