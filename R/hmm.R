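#' Three-state copy-number HMM parameters
#'
#' States are `decreased`, `normal`, `increased` with Gaussian emissions
#' on the z-score scale. Defaults place the decreased mean at -3 (single
#' copy loss sits deep on z once probe noise is chromosome-normalized) and
#' the increased mean at +2.5, with unit emission SDs, sticky
#' self-transitions (0.999) and an initial distribution almost entirely
#' on `normal`.
#'
#' @param means emission means, ordered decreased < normal < increased
#' @param sds emission SDs (> 0)
#' @param transition 3x3 stochastic matrix (rows sum to 1, tol 1e-12)
#' @param init initial state distribution
#' @return an `hmm_params` list
#' @export
hmm_params <- function(means = c(-3, 0, 2.5), sds = c(1, 1, 1),
                       transition = NULL, init = c(0.001, 0.998, 0.001)) {
  states <- c("decreased", "normal", "increased")
  if (is.null(transition)) {
    transition <- matrix(0.0005, 3, 3)
    diag(transition) <- 0.999
  }
  stopifnot(length(means) == 3, length(sds) == 3, all(sds > 0),
            means[1] < means[2], means[2] < means[3],
            all(dim(transition) == c(3, 3)),
            max(abs(rowSums(transition) - 1)) <= 1e-12,
            length(init) == 3, abs(sum(init) - 1) <= 1e-12)
  dimnames(transition) <- list(states, states)
  structure(list(states = states, means = means, sds = sds,
                 transition = transition, init = init),
            class = "hmm_params")
}

#' Viterbi decoding of a z-score sequence
#'
#' Maximum-probability state path under Gaussian emissions, computed in
#' log space on the probe-order sequence. Inter-probe distance is
#' deliberately ignored here: genomic distance enters the pipeline only at
#' segment assembly and bridging.
#'
#' @param z numeric z-score vector for one chromosome (probe order)
#' @param params an `hmm_params`
#' @return character vector of states, one per probe
#' @export
viterbi_decode <- function(z, params = hmm_params()) {
  n <- length(z)
  if (n == 0) return(character())
  log_trans <- log(params$transition)
  # emission log-likelihoods: n x 3
  em <- vapply(1:3, function(s) stats::dnorm(z, params$means[s], params$sds[s], log = TRUE),
               numeric(n))
  em <- matrix(em, nrow = n)
  delta <- matrix(-Inf, n, 3)
  psi <- matrix(0L, n, 3)
  delta[1, ] <- log(params$init) + em[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in 1:3) {
        cand <- delta[t - 1, ] + log_trans[, s]
        psi[t, s] <- which.max(cand)
        delta[t, s] <- cand[psi[t, s]] + em[t, s]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  params$states[path]
}

#' Decode a full z-track chromosome by chromosome
#'
#' @param ztrack result of [zscore_transform()]
#' @param design the `probe_design` the track is aligned to
#' @param params an `hmm_params`
#' @return character state vector aligned to the design
#' @export
decode_track <- function(ztrack, design, params = hmm_params()) {
  states <- character(nrow(design))
  for (chrom in unique(design$chrom)) {
    idx <- which(design$chrom == chrom)
    states[idx] <- viterbi_decode(ztrack$z[idx], params)
  }
  states
}
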