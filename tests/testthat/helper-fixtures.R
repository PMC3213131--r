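## Shared in-code fixtures for the test suite.

iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

## Tiny deterministic genome: 2 chromosomes x 20 Mbp, 6 hotspots.
tiny_layout <- function(seed = 11) {
  make_layout(seed, n_chromosomes = 2, chromosome_length = 20e6, n_hotspots = 6,
              hotspot_size_range = c(200e3, 500e3))
}

tiny_design <- function(layout = tiny_layout(), seed = 11) {
  make_probe_design(layout, seed = seed)
}

## Default-scale genome (4 x 50 Mbp, 27 hotspots), memoized: CNV recovery
## tests need chromosomes large relative to the planted events so that a
## single CNV does not dominate its chromosome's own z-score fit.
.std_cache <- new.env(parent = emptyenv())
std_layout <- function() {
  if (is.null(.std_cache$layout)) .std_cache$layout <- make_layout(7)
  .std_cache$layout
}
std_design <- function() {
  if (is.null(.std_cache$design))
    .std_cache$design <- make_probe_design(std_layout(), seed = 7)
  .std_cache$design
}

## Evenly spaced single-chromosome design for hand-constructed tracks.
grid_design <- function(n = 100, spacing = 10000, chrom = "chr1", probe_len = 60,
                        start0 = 0) {
  starts <- start0 + spacing * (seq_len(n) - 1)
  d <- data.frame(chrom = chrom, start = starts, end = starts + probe_len,
                  probe_id = sprintf("P%04d", seq_len(n)), class = "backbone",
                  stringsAsFactors = FALSE)
  class(d) <- c("probe_design", "data.frame")
  d
}

dyslexia_fixture <- function() {
  read_cnv_calls(system.file("extdata", "dyslexia_rare_cnvs.tsv",
                             package = "cnvburden"),
                 dialect = "one_based")
}

## Brute-force Viterbi oracle: enumerate all 3^n state paths.
brute_force_viterbi <- function(z, params) {
  n <- length(z)
  states <- params$states
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  em <- sapply(1:3, function(s) dnorm(z, params$means[s], params$sds[s], log = TRUE))
  em <- matrix(em, nrow = n)
  lp <- log(params$init)[paths[, 1]] + em[cbind(1, paths[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + log(params$transition)[cbind(paths[, t - 1], paths[, t])] +
        em[cbind(t, paths[, t])]
    }
  }
  states[paths[which.max(lp), ]]
}

## Per-base counting oracle for reciprocal overlap on small coordinates.
brute_force_reciprocal <- function(a, b) {
  if (a$chrom != b$chrom) return(c(0, 0))
  ba <- seq(a$start, a$end - 1)
  bb <- seq(b$start, b$end - 1)
  ov <- length(intersect(ba, bb))
  c(ov / length(ba), ov / length(bb))
}

## Exhaustive two-sided Fisher p oracle over all tables with the observed
## margins, using choose() directly (independent of dhyper).
brute_force_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  probs <- vapply(support, prob, numeric(1))
  p_obs <- prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
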