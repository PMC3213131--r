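test_that("fisher_or reproduces published odds ratios and p-values", {
  r <- fisher_or(c(4, 5, 4, 56))
  expect_equal(r$odds_ratio, 11.2)
  expect_equal(r$p_value, 0.008, tolerance = 0.02)
  inf <- fisher_or(c(30, 17, 0, 8))
  expect_identical(inf$odds_ratio, Inf)
  expect_equal(inf$p_value, 0.0009, tolerance = 0.02)
  sym <- fisher_or(c(5, 5, 5, 5))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  expect_equal(fisher_or(c(30, 17, 14, 21))$p_value,
               brute_force_fisher_p(30, 17, 14, 21))
  expect_error(fisher_or(c(-1, 2, 3, 4)), "non-negative")
  expect_error(fisher_or(c(0, 0, 3, 4)), "margins")
})

test_that("two-sided p equals exhaustive enumeration and stats::fisher.test", {
  set.seed(9)
  for (k in 1:60) {
    tab <- as.vector(stats::rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
    margins <- c(tab[1] + tab[2], tab[3] + tab[4], tab[1] + tab[3], tab[2] + tab[4])
    if (any(margins == 0)) next
    got <- fisher_or(tab)$p_value
    expect_equal(got, brute_force_fisher_p(tab[1], tab[2], tab[3], tab[4]))
    expect_equal(got, stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("odds-ratio invariances hold", {
  set.seed(10)
  for (k in 1:20) {
    t <- sample(1:30, 4)
    or <- fisher_or(t)$odds_ratio
    swapped_both <- fisher_or(c(t[4], t[3], t[2], t[1]))$odds_ratio
    expect_equal(swapped_both, or)
    rows_swapped <- fisher_or(c(t[3], t[4], t[1], t[2]))$odds_ratio
    expect_equal(rows_swapped, 1 / or)
  }
})

test_that("largest CNV per sample covers zero-call individuals", {
  meta <- data.frame(sample = c("a", "b", "c"), cohort = "ID",
                     qc_status = c("pass", "pass", "fail"),
                     stringsAsFactors = FALSE)
  calls <- data.frame(sample = c("a", "a"), chrom = "chr1",
                      start = c(0, 1e6), end = c(120e3, 2.6e6),
                      size = c(120e3, 1.6e6), type = "deletion",
                      stringsAsFactors = FALSE)
  mx <- largest_cnv_per_sample(calls, meta)
  expect_equal(mx$max_size[mx$sample == "a"], 1.6e6)
  expect_equal(mx$max_size[mx$sample == "b"], 0)
  expect_false("c" %in% mx$sample)
  # order invariance
  mx2 <- largest_cnv_per_sample(calls[2:1, ], meta)
  expect_equal(mx, mx2)
})

test_that("survivor curves equal direct counting and are non-increasing", {
  m <- data.frame(cohort = "ID", max_size = c(1e6, 0, 0), stringsAsFactors = FALSE)
  sc <- survivor_curve(m[1, ], grid = c(0.5e6, 1e6, 2e6))
  expect_equal(sc$fraction, c(1, 1, 0))
  set.seed(13)
  maxima <- data.frame(cohort = "x",
                       max_size = sample(c(0, 1e5, 5e5, 2e6), 100, replace = TRUE),
                       stringsAsFactors = FALSE)
  grid <- c(0, 1e5, 3e5, 1e6, 3e6)
  sc2 <- survivor_curve(maxima, grid)
  direct <- vapply(grid, function(s)
    sum(maxima$max_size >= s & maxima$max_size > 0) / 100, numeric(1))
  expect_equal(sc2$fraction, direct)
  expect_true(all(diff(sc2$fraction) <= 0))
  expect_equal(sc2$fraction[1], mean(maxima$max_size > 0))
  allzero <- survivor_curve(data.frame(cohort = "z", max_size = rep(0, 5)), grid)
  expect_true(all(allzero$fraction == 0))
})

test_that("large-CNV burden uses a strict size threshold", {
  res <- large_cnv_burden_test(c(1e6, 2e6), c(5e5, 5e5), threshold = 1e6)
  expect_equal(as.vector(res$table), c(1, 0, 1, 2))  # the exact-1-Mbp call is no carrier
  ident <- large_cnv_burden_test(c(2e6, 5e5, 0), c(2e6, 5e5, 0))
  expect_equal(ident$odds_ratio, 1)
  # planted effect detected on simulated carrier rates
  set.seed(14)
  a <- ifelse(runif(400) < 0.25, 2e6, 0)
  b <- ifelse(runif(400) < 0.02, 2e6, 0)
  eff <- large_cnv_burden_test(a, b)
  expect_gt(eff$odds_ratio, 1)
  expect_lt(eff$p_value, 0.001)
})

test_that("carrier, de novo and two-hit tests rebuild the published tables", {
  # cohort-level units constructed to the printed contingency counts
  mk_meta <- function(cohort, n) {
    data.frame(sample = sprintf("%s_%d", cohort, 1:n), cohort = cohort,
               stringsAsFactors = FALSE)
  }
  meta <- rbind(mk_meta("ID", 431), mk_meta("dyslexia", 322))
  rare_carriers <- c(sprintf("ID_%d", 1:69), sprintf("dyslexia_%d", 1:6))
  ann <- data.frame(sample = rare_carriers, chrom = "chr1", start = 0, end = 1e6,
                    size = 1e6, type = "deletion", rare_strict = TRUE,
                    inheritance = NA_character_, stringsAsFactors = FALSE)
  rc <- rare_carrier_test(ann, meta, "ID", "dyslexia")
  expect_equal(as.vector(t(rc$table)), c(69, 362, 6, 316))
  expect_equal(round(rc$odds_ratio), 10)

  # de novo: ID 30/47 vs autism_no_ID 14/35
  meta2 <- rbind(mk_meta("ID", 47), mk_meta("autism_no_ID", 35))
  inh <- c(rep("de_novo", 30), rep("maternal", 17), rep("de_novo", 14),
           rep("paternal", 21))
  ann2 <- data.frame(sample = meta2$sample, chrom = "chr1", start = 0, end = 1e6,
                     size = 1e6, type = "deletion", rare_strict = TRUE,
                     inheritance = inh, stringsAsFactors = FALSE)
  dn <- de_novo_test(ann2, meta2, "ID", "autism_no_ID")
  expect_equal(dn$odds_ratio, 2.6, tolerance = 0.02)

  # two-hit: ID_MCA 4/9 carriers vs ID 4/60
  meta3 <- rbind(mk_meta("ID_MCA", 73), mk_meta("ID", 358))
  two_hits <- c(rep(sprintf("ID_MCA_%d", 1:4), 2), sprintf("ID_MCA_%d", 5:9),
                rep(sprintf("ID_%d", 1:4), 2), sprintf("ID_%d", 5:60))
  ann3 <- data.frame(sample = two_hits, chrom = "chr1",
                     start = seq(0, by = 2e6, length.out = length(two_hits)),
                     end = seq(1e6, by = 2e6, length.out = length(two_hits)),
                     size = 1e6, type = "deletion", rare_strict = TRUE,
                     inheritance = NA_character_, stringsAsFactors = FALSE)
  th <- two_hit_test(ann3, meta3, "ID_MCA", "ID")
  expect_equal(th$odds_ratio, 11.2)
  expect_equal(th$p_value, 0.008, tolerance = 0.02)
})

test_that("cohort summaries aggregate size, type and gene columns", {
  meta <- data.frame(sample = c("a", "b"), cohort = "ID", stringsAsFactors = FALSE)
  calls <- data.frame(sample = c("a", "b"), chrom = "chr1", start = 0,
                      end = c(1e5, 3e5), size = c(1e5, 3e5),
                      type = c("deletion", "homozygous_deletion"),
                      breaks_gene = c(TRUE, FALSE), gene_count = c(4, 2),
                      stringsAsFactors = FALSE)
  s <- cohort_summary(calls, meta)
  expect_equal(s$mean_size, 2e5)
  expect_equal(s$deletion_prop, 1)
  expect_equal(s$breaks_gene_prop, 0.5)
  expect_equal(s$mean_gene_density, 3)
})

test_that("size histograms are per-individual, left-closed and type-split", {
  meta <- data.frame(sample = c("a", "b"), cohort = "ID", stringsAsFactors = FALSE)
  calls <- data.frame(sample = "a", chrom = "chr1", start = 0, end = 560e3,
                      size = 560e3, type = "deletion", stringsAsFactors = FALSE)
  h <- size_histogram(calls, meta, breaks = c(0, 5e5, 1e6))
  del <- h[h$type == "deletion", ]
  expect_equal(del$per_individual, c(0, 0.5))
  expect_true(all(h$per_individual[h$type == "duplication"] == 0))
  # boundary call goes to the left-closed bin on the right
  calls$size <- 5e5; calls$end <- 5e5
  h2 <- size_histogram(calls, meta, breaks = c(0, 5e5, 1e6))
  expect_equal(h2$per_individual[h2$type == "deletion"], c(0, 0.5))
  empty <- size_histogram(calls[0, ], meta, breaks = c(0, 5e5, 1e6))
  expect_true(all(empty$per_individual == 0))
})

test_that("the dyslexia strict-rare median reproduces the published 302 kbp", {
  strict <- rarity_filter(dyslexia_fixture(), mode = "strict")
  expect_equal(median_rare_size(strict$size), 302914)
  expect_equal(median_rare_size(61828), 61828)
  set.seed(15)
  sort_and_pick <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (k in 1:20) {
    x <- sample(1e4:1e6, sample(1:9, 1))
    expect_equal(median_rare_size(x), sort_and_pick(x))
  }
  expect_error(median_rare_size(numeric()), "no rare CNVs")
})

test_that("two-proportion power matches its null case, simulation and monotonicity", {
  expect_equal(two_proportion_power(0.03, 0, 322, 306), 0.05)
  p0 <- 0.03; delta <- 0.042; n1 <- 322; n2 <- 306
  set.seed(16)
  reps <- 20000
  x1 <- rbinom(reps, n1, p0) / n1
  x2 <- rbinom(reps, n2, p0 + delta) / n2
  se <- sqrt(x1 * (1 - x1) / n1 + x2 * (1 - x2) / n2)
  zstat <- abs(x2 - x1) / se
  mc <- mean(zstat > qnorm(0.975), na.rm = TRUE)
  expect_equal(two_proportion_power(p0, delta, n1, n2), mc, tolerance = 0.02)
  pows <- sapply(c(0.01, 0.02, 0.04, 0.08), function(d)
    two_proportion_power(0.03, d, 322, 306))
  expect_true(all(diff(pows) > 0))
  expect_gt(two_proportion_power(0.03, 0.042, 1000, 1000),
            two_proportion_power(0.03, 0.042, 322, 306))
})
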