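## Annotation of CNV calls: hotspot class, control-map rarity, genes,
## genomic-disorder regions, trio inheritance.

## Deletion-family types match each other (a homozygous deletion in a
## proband can be assembled from single-copy parental deletions); they
## never match duplications.
type_matches <- function(a, b, type_blind = FALSE) {
  if (type_blind) return(rep(TRUE, length(b)))
  del <- c("deletion", "homozygous_deletion")
  (a %in% del & b %in% del) | (a == "duplication" & b == "duplication")
}

#' Classify calls against hotspot architecture
#'
#' `HS`: the call overlaps hotspot sequence by at least `fraction` of its
#' own length. `HS_assoc`: not `HS`, but a breakpoint lies inside a
#' hotspot or one of its segmental-duplication flank intervals.
#' `non_HS`: neither.
#'
#' @param calls call data.frame (`chrom`, `start`, `end`)
#' @param layout a `genome_layout`
#' @param fraction overlap fraction for the `HS` label (`>=`)
#' @return character vector of labels, one per call
#' @export
classify_hotspot <- function(calls, layout, fraction = 0.5) {
  n <- nrow(calls)
  if (n == 0) return(character())
  out <- rep("non_HS", n)
  hits <- overlap_pairs(calls, layout$hotspots)
  if (nrow(hits)) {
    cov <- tapply(hits$width, hits$query, sum)
    qi <- as.integer(names(cov))
    hs <- qi[cov / (calls$end[qi] - calls$start[qi]) >= fraction]
    out[hs] <- "HS"
  }
  assoc_iv <- rbind(layout$hotspots[, c("chrom", "start", "end")],
                    layout$flanks[, c("chrom", "start", "end")])
  bp_in <- position_in(calls$chrom, calls$start, assoc_iv) |
    position_in(calls$chrom, pmax(calls$end - 1, calls$start), assoc_iv)
  out[out != "HS" & bp_in] <- "HS_assoc"
  out
}

#' Count control individuals carrying each call
#'
#' Sums the carrier counts of control-map events of matching type whose
#' reciprocal overlap with the call is at least `fraction` in both
#' directions.
#'
#' @param calls call data.frame with a `type` column
#' @param map control CNV map (see [read_control_map()])
#' @param fraction reciprocal-overlap fraction (`>=`, both directions)
#' @param type_blind ignore deletion/duplication when matching
#' @return integer vector of control counts, one per call
#' @export
count_control_matches <- function(calls, map, fraction = 0.5, type_blind = FALSE) {
  n <- nrow(calls)
  counts <- rep(0, n)
  if (n == 0 || nrow(map) == 0) return(counts)
  hits <- overlap_pairs(calls, map)
  if (!nrow(hits)) return(counts)
  ok <- hits$frac_q >= fraction & hits$frac_s >= fraction &
    type_matches(calls$type[hits$query], map$type[hits$subject], type_blind)
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) return(counts)
  agg <- tapply(map$count[hits$subject], hits$query, sum)
  counts[as.integer(names(agg))] <- as.numeric(agg)
  counts
}

#' Rarity filtering against the control CNV map
#'
#' Strict mode keeps calls absent from the control map (control count 0);
#' relaxed mode keeps calls whose control frequency is strictly below the
#' rare-frequency bound (default < 0.1%, i.e. up to 8 of 8,635 controls).
#' Every strict-rare call is also relaxed-rare.
#'
#' @param calls call data.frame; a `control_count` column is used if
#'   present, otherwise computed from `map`
#' @param map control CNV map (required when `control_count` is absent)
#' @param mode `"strict"` or `"relaxed"`
#' @param config an [analysis_config()]
#' @return the surviving subset of `calls`, with `control_count`,
#'   `rare_strict` and `rare_relaxed` columns filled
#' @export
rarity_filter <- function(calls, map = NULL, mode = c("strict", "relaxed"),
                          config = analysis_config()) {
  mode <- match.arg(mode)
  calls <- annotate_rarity(calls, map, config)
  calls[if (mode == "strict") calls$rare_strict else calls$rare_relaxed, ,
        drop = FALSE]
}

#' @rdname rarity_filter
#' @export
annotate_rarity <- function(calls, map = NULL, config = analysis_config()) {
  if (!"control_count" %in% names(calls)) {
    if (is.null(map)) stop("need either a control_count column or a control map")
    calls$control_count <- count_control_matches(calls, map,
                                                 config$reciprocal_overlap,
                                                 config$type_blind_matching)
  }
  n_controls <- if (!is.null(map)) attr(map, "n_controls") else config$n_controls
  calls$rare_strict <- calls$control_count == 0
  calls$rare_relaxed <- calls$control_count / n_controls < config$rare_freq_bound
  calls
}

#' Gene content of calls
#'
#' `gene_count` is the number of genes overlapping the call by at least
#' one bp; `breaks_gene` is TRUE when a gene body strictly contains either
#' breakpoint coordinate (a CNV wholly containing genes does not "break"
#' them).
#'
#' @param calls call data.frame
#' @param genes gene table (`chrom`, `start`, `end`, `symbol`)
#' @return data.frame with columns `gene_count`, `breaks_gene`
#' @export
annotate_genes <- function(calls, genes) {
  n <- nrow(calls)
  gene_count <- rep(0L, n)
  breaks_gene <- rep(FALSE, n)
  if (n > 0 && nrow(genes) > 0) {
    hits <- overlap_pairs(calls, genes)
    if (nrow(hits)) {
      cnt <- table(hits$query)
      gene_count[as.integer(names(cnt))] <- as.integer(cnt)
      contains <- function(pos_idx) {
        g <- hits$subject
        genes$start[g] < pos_idx & pos_idx < genes$end[g]
      }
      brk <- contains(calls$start[hits$query]) | contains(calls$end[hits$query])
      hit_brk <- unique(hits$query[brk])
      breaks_gene[hit_brk] <- TRUE
    }
  }
  data.frame(gene_count = gene_count, breaks_gene = breaks_gene)
}

#' Match calls to known genomic-disorder regions
#'
#' Returns the label of the disorder region with reciprocal overlap at
#' least `fraction` (both directions); when several qualify, the one with
#' the largest overlap wins (deterministic tie-break by list order).
#'
#' @param calls call data.frame
#' @param regions labelled interval data.frame (`chrom`, `start`, `end`,
#'   `label`)
#' @param fraction reciprocal-overlap fraction
#' @return character vector of labels (NA when no region qualifies)
#' @export
match_genomic_disorder <- function(calls, regions, fraction = 0.5) {
  n <- nrow(calls)
  out <- rep(NA_character_, n)
  if (n == 0 || is.null(regions) || nrow(regions) == 0) return(out)
  hits <- overlap_pairs(calls, regions)
  hits <- hits[hits$frac_q >= fraction & hits$frac_s >= fraction, , drop = FALSE]
  if (!nrow(hits)) return(out)
  hits <- hits[order(hits$query, -hits$width, hits$subject), , drop = FALSE]
  first <- !duplicated(hits$query)
  out[hits$query[first]] <- regions$label[hits$subject[first]]
  out
}

#' Classify trio inheritance of proband calls
#'
#' A parent "carries" a proband call when the parent's own call set
#' contains a same-type call with reciprocal overlap at least `fraction`
#' in both directions. With both parents genotyped: neither carries it ->
#' `de_novo`; exactly one -> `maternal`/`paternal`; both -> `both`. With a
#' single genotyped parent, a match yields that parent's label and a
#' non-match yields NA (the call could still be de novo or from the
#' missing parent). With no parents, NA.
#'
#' @param proband_calls call data.frame for the proband
#' @param father_calls,mother_calls parental call data.frames, or NULL
#'   when the parent was not genotyped
#' @param fraction reciprocal-overlap fraction
#' @return character vector: `de_novo`, `maternal`, `paternal`, `both` or NA
#' @export
classify_inheritance <- function(proband_calls, father_calls = NULL,
                                 mother_calls = NULL, fraction = 0.5) {
  n <- nrow(proband_calls)
  if (n == 0) return(character())
  parent_has <- function(parent_calls) {
    if (is.null(parent_calls) || nrow(parent_calls) == 0) return(rep(FALSE, n))
    hits <- overlap_pairs(proband_calls, parent_calls)
    ok <- hits$frac_q >= fraction & hits$frac_s >= fraction &
      type_matches(proband_calls$type[hits$query], parent_calls$type[hits$subject])
    out <- rep(FALSE, n)
    out[unique(hits$query[ok])] <- TRUE
    out
  }
  fa_avail <- !is.null(father_calls)
  mo_avail <- !is.null(mother_calls)
  in_fa <- parent_has(father_calls)
  in_mo <- parent_has(mother_calls)
  out <- rep(NA_character_, n)
  if (fa_avail && mo_avail) {
    out[!in_fa & !in_mo] <- "de_novo"
    out[in_fa & !in_mo] <- "paternal"
    out[!in_fa & in_mo] <- "maternal"
    out[in_fa & in_mo] <- "both"
  } else if (fa_avail) {
    out[in_fa] <- "paternal"
  } else if (mo_avail) {
    out[in_mo] <- "maternal"
  }
  out
}

#' Annotate a cohort call table
#'
#' Fills every annotation column on the QC-passing calls of each proband:
#' hotspot class, control match count, strict/relaxed rarity flags, gene
#' count and breaks-gene flag, genomic-disorder label, inheritance (from
#' the parents' own pass-QC call sets) and parent availability.
#'
#' @param calls pipeline call table (all samples)
#' @param meta sample metadata (with `father`/`mother` ids; samples absent
#'   from the call table's sample universe are treated as not genotyped)
#' @param map control CNV map
#' @param genes gene table (optional)
#' @param disorders labelled disorder-region table (optional)
#' @param layout `genome_layout` (optional; recomputes hotspot class)
#' @param config an [analysis_config()]
#' @param genotyped sample ids that were assayed (defaults to all samples
#'   in `meta`); parents outside this set count as unavailable
#' @return annotated call data.frame (QC-passing proband calls)
#' @export
annotate_calls <- function(calls, meta, map, genes = NULL, disorders = NULL,
                           layout = NULL, config = analysis_config(),
                           genotyped = meta$sample) {
  keep <- calls$qc_pass %||% rep(TRUE, nrow(calls))
  qc_calls <- calls[keep, , drop = FALSE]
  probands <- if ("role" %in% names(meta)) meta[meta$role == "proband", ] else meta
  out <- qc_calls[qc_calls$sample %in% probands$sample, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(layout)) {
    out$hotspot_class <- classify_hotspot(out, layout, config$reciprocal_overlap)
  }
  out <- annotate_rarity(out, map, config)
  g <- annotate_genes(out, if (is.null(genes))
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               symbol = character(), stringsAsFactors = FALSE) else genes)
  out$gene_count <- g$gene_count
  out$breaks_gene <- g$breaks_gene
  out$disorder <- match_genomic_disorder(out, disorders, config$reciprocal_overlap)
  out$inheritance <- NA_character_
  out$parents_available <- 0L
  parent_calls <- function(pid) {
    if (is.na(pid) || !(pid %in% genotyped)) return(NULL)
    qc_calls[qc_calls$sample == pid, , drop = FALSE]
  }
  for (s in unique(out$sample)) {
    idx <- which(out$sample == s)
    row <- probands[probands$sample == s, ][1, ]
    fa <- parent_calls(if ("father" %in% names(row)) row$father else NA)
    mo <- parent_calls(if ("mother" %in% names(row)) row$mother else NA)
    out$inheritance[idx] <- classify_inheritance(
      out[idx, , drop = FALSE], fa, mo, config$reciprocal_overlap)
    out$parents_available[idx] <- (!is.null(fa)) + (!is.null(mo))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
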