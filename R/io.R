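## Tabular I/O. BED-like files are headerless tab-separated with three
## leading columns chrom/start/end; TSV files carry a header row. Writers
## can prepend "#"-prefixed comment lines recording config hash and seed;
## readers skip them.

write_lines_with_header <- function(lines, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(lines, con)
  invisible(path)
}

provenance_comment <- function(cfg = NULL, seed = NULL) {
  if (is.null(cfg) && is.null(seed)) return(NULL)
  paste0("cnvburden",
         if (!is.null(cfg)) paste0(" config_hash=", config_hash(cfg)) else "",
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

read_table_skip_comments <- function(path, header) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(NULL)
  utils::read.table(text = lines[keep], header = header, sep = "\t",
                    quote = "", comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' Read a BED-like interval file
#'
#' Three leading columns chrom/start/end (0-based half-open); any further
#' columns are preserved as annotations. Tables printed with 1-based
#' starts (the common convention of published CNV lists, whose `size`
#' column equals `end - start`) are ingested with `dialect = "one_based"`,
#' which shifts the start down by 1 and recomputes the end from the
#' preserved size (`end - 1`), so printed sizes round-trip exactly.
#'
#' @param path file path
#' @param dialect `"bed"` (default, 0-based half-open) or `"one_based"`
#' @param col_names optional names for columns beyond the first three
#' @return sorted interval data.frame
#' @export
read_intervals <- function(path, dialect = c("bed", "one_based"), col_names = NULL) {
  dialect <- match.arg(dialect)
  df <- read_table_skip_comments(path, header = FALSE)
  if (is.null(df)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(df) < 3) stop("BED-like file needs >= 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(col_names)) {
    extra <- seq_len(min(length(col_names), ncol(df) - 3))
    names(df)[3 + extra] <- col_names[extra]
  }
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$start))) |
                 is.na(suppressWarnings(as.numeric(df$end))))
    stop("malformed coordinate(s) at data line(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " of ", path)
  }
  df$chrom <- as.character(df$chrom)
  if (dialect == "one_based") {
    df$start <- df$start - 1
    df$end <- df$end - 1
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop("start >= end at data line(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " of ", path)
  }
  if (df$start[1] < 0 || any(df$start < 0)) stop("negative start coordinate in ", path)
  normalize_intervals(df)
}

#' Write intervals as BED
#'
#' @param iv interval data.frame
#' @param path file path
#' @param cfg,seed optional provenance recorded as a comment header
#' @return `path`, invisibly
#' @export
write_intervals <- function(iv, path, cfg = NULL, seed = NULL) {
  validate_intervals(iv)
  lines <- do.call(paste, c(lapply(iv, as.character), sep = "\t"))
  write_lines_with_header(lines, path, provenance_comment(cfg, seed))
}

format_tsv <- function(df) {
  ff <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "NA"
        else if (is.finite(v) && v == round(v) && abs(v) < 1e15) sprintf("%.0f", v)
        else format(v, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1))
      out
    } else {
      out <- as.character(x)
      out[is.na(out)] <- "NA"
      out
    }
  }
  body <- do.call(paste, c(lapply(df, ff), sep = "\t"))
  c(paste(names(df), collapse = "\t"), body)
}

#' Read / write a probe log2-ratio matrix
#'
#' Headered TSV with a `probe_id` column followed by one column per
#' sample. Probe ids must match the loaded probe design exactly (same
#' set, same order after alignment); missing cells stay `NA`.
#'
#' @param path file path
#' @param design optional probe design to align/validate against
#' @param mat numeric matrix, probes x samples, rownames = probe ids
#' @param cfg,seed optional provenance comment fields
#' @return `read_log_ratio_matrix`: numeric matrix with probe-id rownames
#' @export
read_log_ratio_matrix <- function(path, design = NULL) {
  df <- read_table_skip_comments(path, header = TRUE)
  if (is.null(df) || names(df)[1] != "probe_id")
    stop("log-ratio matrix must start with a 'probe_id' column: ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$probe_id
  if (!is.null(design)) {
    missing <- setdiff(design$probe_id, rownames(mat))
    extra <- setdiff(rownames(mat), design$probe_id)
    if (length(missing) || length(extra)) {
      stop("probe-id mismatch with design; missing: ",
           paste(utils::head(missing, 5), collapse = ", "),
           "; unexpected: ", paste(utils::head(extra, 5), collapse = ", "))
    }
    mat <- mat[design$probe_id, , drop = FALSE]
  }
  mat
}

#' @rdname read_log_ratio_matrix
#' @export
write_log_ratio_matrix <- function(mat, path, cfg = NULL, seed = NULL) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_lines_with_header(format_tsv(df), path, provenance_comment(cfg, seed))
}

#' Read / write CNV call tables
#'
#' Headered TSV with at least `sample`, `chrom`, `start`, `end`, `size`,
#' `type`, `n_probes`, `mean_z`; annotation columns are carried through.
#' On read, a `size` column (when present) must equal `end - start` after
#' dialect handling.
#'
#' @param path file path
#' @param calls call data.frame
#' @param dialect `"bed"` or `"one_based"` (see [read_intervals()])
#' @param cfg,seed optional provenance comment fields
#' @return `read_cnv_calls`: call data.frame
#' @export
read_cnv_calls <- function(path, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  df <- read_table_skip_comments(path, header = TRUE)
  if (is.null(df)) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), size = numeric(),
                      type = character(), stringsAsFactors = FALSE))
  }
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) stop("call table missing columns: ", path)
  if (dialect == "one_based") {
    df$start <- df$start - 1
    df$end <- df$end - 1
  }
  validate_intervals(df)
  if ("size" %in% names(df) && any(df$size != df$end - df$start)) {
    bad <- which(df$size != df$end - df$start)
    stop("size column disagrees with end - start at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  }
  df$size <- df$end - df$start
  df
}

#' @rdname read_cnv_calls
#' @export
write_cnv_calls <- function(calls, path, cfg = NULL, seed = NULL) {
  write_lines_with_header(format_tsv(calls), path, provenance_comment(cfg, seed))
}

#' Read / write sample metadata (pedigree) tables
#'
#' Headered TSV with columns `sample`, `cohort`, `father`, `mother`,
#' `qc_status` (and optionally `role`). Cohort labels come from the closed
#' set used throughout the package; parent ids, when present, must
#' reference rows of the table.
#'
#' @param path file path
#' @param meta metadata data.frame
#' @param cfg,seed optional provenance comment fields
#' @return `read_sample_meta`: validated metadata data.frame
#' @export
read_sample_meta <- function(path) {
  df <- read_table_skip_comments(path, header = TRUE)
  validate_sample_meta(df)
  df
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path, cfg = NULL, seed = NULL) {
  write_lines_with_header(format_tsv(meta), path, provenance_comment(cfg, seed))
}

#' Cohort labels recognized throughout the package
#' @export
cohort_levels <- function() {
  c("control", "dyslexia", "autism_no_ID", "autism_ID", "ID", "ID_MCA")
}

validate_sample_meta <- function(meta) {
  need <- c("sample", "cohort")
  if (!all(need %in% names(meta))) stop("sample metadata needs columns sample, cohort")
  bad <- setdiff(unique(meta$cohort), cohort_levels())
  if (length(bad)) stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  for (col in c("father", "mother")) {
    if (col %in% names(meta)) {
      ref <- meta[[col]][!is.na(meta[[col]])]
      orphan <- setdiff(ref, meta$sample)
      if (length(orphan)) stop("parent id(s) not in table: ", paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  invisible(meta)
}

#' Read / write a control CNV map
#'
#' BED+count format: chrom, start, end, type, count. The total number of
#' control individuals behind the map is carried as the `n_controls`
#' attribute (written/read via a `# n_controls=` comment line).
#'
#' @param path file path
#' @param map control-map data.frame with `n_controls` attribute
#' @param n_controls denominator override when the file lacks the comment
#' @param cfg,seed optional provenance comment fields
#' @return `read_control_map`: data.frame (`chrom`, `start`, `end`,
#'   `type`, `count`) with attribute `n_controls`
#' @export
read_control_map <- function(path, n_controls = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*n_controls=", lines, value = TRUE)
  if (length(hdr) && is.null(n_controls)) {
    n_controls <- as.numeric(sub("^#\\s*n_controls=", "", hdr[1]))
  }
  map <- read_intervals(path, col_names = c("type", "count"))
  if (nrow(map) > 0 && !all(c("type", "count") %in% names(map)))
    stop("control map needs columns chrom, start, end, type, count: ", path)
  if (nrow(map) == 0) {
    map <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), count = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(n_controls)) stop("control map lacks an n_controls record: ", path)
  if (any(map$count < 0 | map$count > n_controls))
    stop("control counts must lie in [0, n_controls]")
  attr(map, "n_controls") <- n_controls
  map
}

#' @rdname read_control_map
#' @export
write_control_map <- function(map, path, cfg = NULL, seed = NULL) {
  n <- attr(map, "n_controls")
  if (is.null(n)) stop("control map lacks an n_controls attribute")
  con <- file(path, "w")
  on.exit(close(con))
  prov <- provenance_comment(cfg, seed)
  if (!is.null(prov)) writeLines(paste0("# ", prov), con)
  writeLines(paste0("# n_controls=", format(n, scientific = FALSE)), con)
  cols <- map[, c("chrom", "start", "end", "type", "count"), drop = FALSE]
  if (nrow(cols)) writeLines(do.call(paste, c(lapply(cols, as.character), sep = "\t")), con)
  invisible(path)
}

#' Read a gene table (BED + symbol)
#'
#' @param path BED-like file whose fourth column is the gene symbol
#' @param dialect coordinate dialect, see [read_intervals()]
#' @return data.frame (`chrom`, `start`, `end`, `symbol`)
#' @export
read_gene_table <- function(path, dialect = "bed") {
  g <- read_intervals(path, dialect = dialect, col_names = "symbol")
  if (nrow(g) > 0 && !"symbol" %in% names(g)) stop("gene table needs a symbol column: ", path)
  g
}
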