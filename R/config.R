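#' Analysis configuration
#'
#' All thresholds of the calling and annotation pipeline with their
#' comparison strictness:
#' \itemize{
#'   \item `z_threshold` (default 1.5): calls require `|mean z| >` this.
#'   \item `min_probes` (default 10): calls require strictly more probes.
#'   \item `min_size_hotspot` (default 50 kbp, strict >): size floor for
#'     hotspot-class calls (and global floor for every call).
#'   \item `min_size_nonhotspot` (default 300 kbp, strict >): extra size
#'     floor for calls not associated with a hotspot.
#'   \item `segment_gap_limit` (default 50 kbp, strict <): consecutive
#'     same-state probes merge into one segment only when closer than this.
#'   \item `bridge_max_probes` (default 5, <=) and `bridge_max_gap`
#'     (default 10 kbp, <=): two same-state segments and their intervening
#'     probes merge into one variant when both bounds hold.
#'   \item `reciprocal_overlap` (default 0.5, >=): matching fraction for
#'     control-map, parental and disorder-region comparisons.
#'   \item `rare_freq_bound` (default 0.001, strict <): relaxed-rarity
#'     bound on control frequency.
#'   \item `large_cnv_threshold` (default 1 Mbp, strict >): "large CNV"
#'     definition for burden tests.
#'   \item `n_controls` (default 8635): control-map denominator.
#'   \item `homdel_z_threshold` (default -6): segment mean z below this
#'     labels a deletion homozygous.
#'   \item `sample_sd_ceiling` (default 0.35) and `sample_call_multiple`
#'     (default 3): per-sample QC rule.
#'   \item `robust_zscore` (default FALSE): median/MAD chromosome fit
#'     instead of mean/SD.
#'   \item `type_blind_matching` (default FALSE): ignore deletion vs
#'     duplication when matching against the control map.
#' }
#'
#' @param ... overrides of the defaults listed above
#' @return a validated list of class `analysis_config`
#' @export
analysis_config <- function(...) {
  cfg <- list(
    z_threshold = 1.5,
    min_probes = 10,
    min_size_hotspot = 50000,
    min_size_nonhotspot = 300000,
    segment_gap_limit = 50000,
    bridge_max_probes = 5,
    bridge_max_gap = 10000,
    reciprocal_overlap = 0.5,
    rare_freq_bound = 0.001,
    large_cnv_threshold = 1e6,
    n_controls = 8635,
    homdel_z_threshold = -6,
    sample_sd_ceiling = 0.35,
    sample_call_multiple = 3,
    robust_zscore = FALSE,
    type_blind_matching = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  pos <- c("z_threshold", "min_probes", "min_size_hotspot", "min_size_nonhotspot",
           "segment_gap_limit", "bridge_max_probes", "bridge_max_gap",
           "rare_freq_bound", "large_cnv_threshold", "n_controls",
           "sample_sd_ceiling", "sample_call_multiple")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar")
  }
  if (!(cfg$reciprocal_overlap > 0 && cfg$reciprocal_overlap <= 1))
    stop("config field 'reciprocal_overlap' must lie in (0, 1]")
  invisible(cfg)
}

#' Read / write an analysis configuration as YAML
#'
#' The YAML may carry per-stage blocks (`segmentation`, `annotation`,
#' `burden`, ...); scalar fields from every block are flattened onto the
#' config, unknown fields rejected.
#'
#' @param path file path
#' @param cfg an `analysis_config`
#' @return `read_config`: an `analysis_config`; `write_config`: `path`,
#'   invisibly
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (nm in names(raw)) {
    if (is.list(raw[[nm]])) flat <- c(flat, raw[[nm]]) else flat[[nm]] <- raw[[nm]]
  }
  do.call(analysis_config, flat)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## Deterministic 32-bit FNV-1a hash of a config (hex string), used in
## output file headers and manifests.
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg))
  bytes <- utf8ToInt(txt)
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

## Derive a child seed deterministically from a parent seed and stream id;
## stays below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919 + 12345) %% 2147483647)
}
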