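## Stage runners wiring the modules into reproducible on-disk runs. Each
## writes a manifest (config hash, seed, input/output paths) so that every
## artifact can be traced to the run that produced it. Timestamps are
## omitted by default so identical seeds give byte-identical outputs.

write_manifest <- function(out_dir, stage, cfg, seed, paths, timestamp = FALSE) {
  # record paths relative to the run directory so identical seeds give
  # byte-identical manifests regardless of where the run lives
  prefix <- paste0(normalizePath(out_dir, winslash = "/"), "/")
  rel <- lapply(paths, function(p) {
    if (is.na(p) || !is.character(p)) return(p)
    np <- tryCatch(normalizePath(p, winslash = "/", mustWork = FALSE), error = function(e) p)
    sub(prefix, "", np, fixed = TRUE)
  })
  manifest <- list(stage = stage, config_hash = config_hash(cfg), seed = seed,
                   paths = rel, package_version = as.character(utils::packageVersion("cnvburden")))
  if (timestamp) manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(manifest, file.path(out_dir, paste0("manifest_", stage, ".yaml")))
}

#' Simulate a full synthetic study to disk
#'
#' Writes the probe design (BED), the log2-ratio matrix (TSV), the
#' truth set (TSV), the pedigree/sample metadata (TSV) and the control
#' CNV map (BED+count) plus a manifest. Deterministic per seed.
#'
#' @param out_dir output directory (created if needed)
#' @param seed integer seed (mandatory)
#' @param cfg an [analysis_config()]
#' @param specs cohort specs (default [default_cohort_specs()])
#' @param noise a [noise_model()]
#' @param layout_args named list of overrides for [make_layout()]
#' @return named list of output paths, invisibly
#' @export
run_simulate <- function(out_dir, seed, cfg = analysis_config(),
                         specs = default_cohort_specs(), noise = noise_model(),
                         layout_args = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- do.call(make_layout, c(list(seed = seed), layout_args))
  design <- make_probe_design(layout, seed = seed)
  sim <- simulate_cohorts(layout, specs, seed)
  mat <- simulate_intensities(design, sim$truth, sim$meta$sample, noise, seed)
  map <- simulate_control_map(layout, n_controls = cfg$n_controls, seed = seed)
  paths <- list(design = file.path(out_dir, "probe_design.bed"),
                matrix = file.path(out_dir, "log2_ratios.tsv"),
                truth = file.path(out_dir, "truth_set.tsv"),
                pedigree = file.path(out_dir, "pedigree.tsv"),
                control_map = file.path(out_dir, "control_map.bed"),
                layout = file.path(out_dir, "layout.yaml"))
  write_probe_design(design, paths$design, cfg = cfg, seed = seed)
  write_log_ratio_matrix(mat, paths$matrix, cfg = cfg, seed = seed)
  write_cnv_calls(sim$truth, paths$truth, cfg = cfg, seed = seed)
  write_sample_meta(sim$meta, paths$pedigree, cfg = cfg, seed = seed)
  write_control_map(map, paths$control_map, cfg = cfg, seed = seed)
  yaml::write_yaml(list(chromosomes = layout$chromosomes,
                        hotspots = layout$hotspots, flanks = layout$flanks),
                   paths$layout)
  write_manifest(out_dir, "simulate", cfg, seed, paths)
  invisible(paths)
}

#' Read a genome layout written by [run_simulate()]
#' @param path layout YAML path
#' @return a `genome_layout`
#' @export
read_layout <- function(path) {
  raw <- yaml::read_yaml(path)
  layout <- list(chromosomes = as.data.frame(raw$chromosomes, stringsAsFactors = FALSE),
                 hotspots = as.data.frame(raw$hotspots, stringsAsFactors = FALSE),
                 flanks = as.data.frame(raw$flanks, stringsAsFactors = FALSE))
  if (nrow(layout$hotspots) == 0)
    layout$hotspots <- data.frame(chrom = character(), start = numeric(), end = numeric())
  if (nrow(layout$flanks) == 0)
    layout$flanks <- data.frame(chrom = character(), start = numeric(), end = numeric())
  class(layout) <- "genome_layout"
  validate_layout(layout)
  layout
}

#' Segment every sample of a log2-ratio matrix into CNV calls
#'
#' @param design_path probe-design BED path
#' @param matrix_path log2-ratio matrix TSV path
#' @param out_dir output directory
#' @param cfg an [analysis_config()]
#' @param layout_path optional layout YAML for hotspot-aware size filters
#' @param seed seed recorded in the output header
#' @param pedigree_path optional metadata path; when given, per-sample QC
#'   (SD ceiling + call-count rule) marks samples in the written call table
#' @return path of the call table, invisibly
#' @export
run_call <- function(design_path, matrix_path, out_dir, cfg = analysis_config(),
                     layout_path = NULL, seed = NA, pedigree_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- read_probe_design(design_path)
  mat <- read_log_ratio_matrix(matrix_path, design)
  layout <- if (!is.null(layout_path)) read_layout(layout_path) else NULL
  calls <- call_matrix(mat, design, cfg, layout)
  raw_counts <- table(factor(calls$sample, levels = colnames(mat)))
  med <- stats::median(as.numeric(raw_counts))
  qc <- vapply(colnames(mat), function(s)
    sample_qc(mat[, s], design, raw_counts[[s]], med, cfg)$status, character(1))
  calls$sample_qc <- qc[calls$sample]
  path <- file.path(out_dir, "cnv_calls.tsv")
  write_cnv_calls(calls, path, cfg = cfg, seed = seed)
  if (!is.null(pedigree_path)) {
    meta <- read_sample_meta(pedigree_path)
    meta$qc_status <- ifelse(meta$sample %in% names(qc), qc[meta$sample], meta$qc_status)
    write_sample_meta(meta, file.path(out_dir, "pedigree_qc.tsv"), cfg = cfg, seed = seed)
  }
  write_manifest(out_dir, "call", cfg, seed,
                 list(design = design_path, matrix = matrix_path, calls = path))
  invisible(path)
}

#' Annotate a call table on disk
#'
#' @param calls_path call-table TSV
#' @param pedigree_path sample metadata TSV
#' @param control_map_path control-map BED+count (required)
#' @param out_dir output directory
#' @param genes_path,disorders_path optional gene / disorder-region BEDs
#' @param layout_path optional layout YAML
#' @param cfg an [analysis_config()]
#' @param seed seed recorded in the output header
#' @return path of the annotated table, invisibly
#' @export
run_annotate <- function(calls_path, pedigree_path, control_map_path, out_dir,
                         genes_path = NULL, disorders_path = NULL,
                         layout_path = NULL, cfg = analysis_config(), seed = NA) {
  if (is.null(control_map_path) || !file.exists(control_map_path))
    stop("control map is required for annotation")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- read_cnv_calls(calls_path)
  meta <- read_sample_meta(pedigree_path)
  map <- read_control_map(control_map_path, n_controls = cfg$n_controls)
  genes <- if (!is.null(genes_path)) read_gene_table(genes_path) else NULL
  disorders <- if (!is.null(disorders_path))
    read_intervals(disorders_path, col_names = "label") else NULL
  layout <- if (!is.null(layout_path)) read_layout(layout_path) else NULL
  ann <- annotate_calls(calls, meta, map, genes, disorders, layout, cfg)
  path <- file.path(out_dir, "annotated_calls.tsv")
  write_cnv_calls(ann, path, cfg = cfg, seed = seed)
  write_manifest(out_dir, "annotate", cfg, seed,
                 list(calls = calls_path, annotated = path))
  invisible(path)
}

#' Run cohort burden comparisons from an annotated call table
#'
#' @param annotated_path annotated call TSV
#' @param pedigree_path sample metadata TSV
#' @param out_dir output directory
#' @param comparisons data.frame with columns `test` (one of
#'   `large_cnv`, `rare_carrier`, `de_novo`, `two_hit`), `cohort_a`,
#'   `cohort_b`; defaults to large-CNV and rare-carrier contrasts of every
#'   case cohort against controls
#' @param cfg an [analysis_config()]
#' @param grid survivor-curve size grid (bp)
#' @param seed seed recorded in output headers
#' @return named list of output paths, invisibly
#' @export
run_burden <- function(annotated_path, pedigree_path, out_dir,
                       comparisons = NULL, cfg = analysis_config(),
                       grid = c(0, 5e4, 1e5, 2e5, 5e5, 1e6, 2e6, 5e6), seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_cnv_calls(annotated_path)
  for (col in c("rare_strict", "rare_relaxed", "breaks_gene"))
    if (col %in% names(ann)) ann[[col]] <- as.logical(ann[[col]])
  meta <- read_sample_meta(pedigree_path)
  cohorts <- unique(meta$cohort[if ("role" %in% names(meta)) meta$role == "proband" else TRUE])
  if (length(cohorts) < 2) stop("need at least two cohorts for burden comparisons")
  if (is.null(comparisons)) {
    cases <- setdiff(cohorts, "control")
    comparisons <- rbind(
      data.frame(test = "large_cnv", cohort_a = cases, cohort_b = "control"),
      data.frame(test = "rare_carrier", cohort_a = cases, cohort_b = "control"))
  }
  bad <- setdiff(unique(c(comparisons$cohort_a, comparisons$cohort_b)), cohorts)
  if (length(bad)) stop("unknown cohort label(s) in comparisons: ", paste(bad, collapse = ", "))
  maxima <- largest_cnv_per_sample(ann, meta)
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    cm <- comparisons[i, ]
    res <- tryCatch(switch(cm$test,
      large_cnv = large_cnv_burden_test(
        maxima$max_size[maxima$cohort == cm$cohort_a],
        maxima$max_size[maxima$cohort == cm$cohort_b],
        cfg$large_cnv_threshold,
        label = sprintf("large_cnv %s vs %s", cm$cohort_a, cm$cohort_b)),
      rare_carrier = rare_carrier_test(ann, meta, cm$cohort_a, cm$cohort_b),
      de_novo = de_novo_test(ann, meta, cm$cohort_a, cm$cohort_b),
      two_hit = two_hit_test(ann, meta, cm$cohort_a, cm$cohort_b),
      stop("unknown test: ", cm$test)),
      error = function(e) {
        if (grepl("unknown test|unknown cohort", conditionMessage(e))) stop(e)
        # degenerate table (e.g. no carriers in either cohort): report, not die
        structure(list(label = sprintf("%s %s vs %s", cm$test, cm$cohort_a, cm$cohort_b),
                       table = matrix(NA_real_, 2, 2), odds_ratio = NA_real_,
                       p_value = NA_real_,
                       test = paste0("not_testable: ", conditionMessage(e))),
                  class = "burden_result")
      })
    data.frame(label = res$label, a = res$table[1, 1], b = res$table[1, 2],
               c = res$table[2, 1], d = res$table[2, 2],
               odds_ratio = res$odds_ratio, p_value = res$p_value,
               test = res$test, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  paths <- list(report = file.path(out_dir, "burden_report.tsv"),
                survivor = file.path(out_dir, "survivor_curves.tsv"),
                summary = file.path(out_dir, "cohort_summary.tsv"))
  write_lines_with_header(format_tsv(report), paths$report, provenance_comment(cfg, seed))
  write_lines_with_header(format_tsv(survivor_curve(maxima, grid)), paths$survivor,
                          provenance_comment(cfg, seed))
  write_lines_with_header(format_tsv(cohort_summary(ann, meta)), paths$summary,
                          provenance_comment(cfg, seed))
  write_manifest(out_dir, "burden", cfg, seed, paths)
  invisible(paths)
}

#' Run the whole pipeline (simulate, call, annotate, burden) in one go
#'
#' @param out_dir output directory
#' @param seed integer seed (mandatory)
#' @param cfg an [analysis_config()]
#' @param specs cohort specs for the simulation stage
#' @param noise a [noise_model()]
#' @param layout_args overrides for [make_layout()]
#' @return named list of all stage output paths, invisibly
#' @export
run_all <- function(out_dir, seed, cfg = analysis_config(),
                    specs = default_cohort_specs(), noise = noise_model(),
                    layout_args = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  sim <- run_simulate(out_dir, seed, cfg, specs, noise, layout_args)
  calls <- run_call(sim$design, sim$matrix, out_dir, cfg, sim$layout, seed,
                    pedigree_path = sim$pedigree)
  ped <- file.path(out_dir, "pedigree_qc.tsv")
  ann <- run_annotate(calls, ped, sim$control_map, out_dir,
                      layout_path = sim$layout, cfg = cfg, seed = seed)
  burden <- run_burden(ann, ped, out_dir, cfg = cfg, seed = seed)
  invisible(c(sim, list(calls = calls, annotated = ann), burden))
}
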