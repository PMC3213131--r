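#' Build a synthetic genome layout with rearrangement hotspots
#'
#' Emulates, at reduced scale, a genome whose recurrent-rearrangement
#' hotspots (regions flanked by high-identity segmental duplications)
#' cover roughly 8% of the sequence: the default 4 x 50 Mbp genome with 27
#' hotspots of 300-900 kbp gives a hotspot fraction close to the ~251 Mbp
#' of hotspot sequence in a ~3.1 Gbp genome that the targeted-array design
#' oversamples. Each hotspot is flanked on both sides by short
#' segmental-duplication proxy intervals.
#'
#' @param seed integer seed; the layout is deterministic given it
#' @param n_chromosomes number of chromosomes
#' @param chromosome_length length of each chromosome (bp)
#' @param n_hotspots total hotspots across the genome
#' @param hotspot_size_range min/max hotspot size (bp)
#' @param flank_size size of each segmental-duplication flank (bp)
#' @return a `genome_layout` list: `chromosomes` (data.frame `chrom`,
#'   `length`), `hotspots` and `flanks` (interval data.frames)
#' @export
make_layout <- function(seed, n_chromosomes = 4, chromosome_length = 50e6,
                        n_hotspots = 27, hotspot_size_range = c(300e3, 900e3),
                        flank_size = 25e3) {
  stopifnot(n_chromosomes >= 1, chromosome_length > 0, n_hotspots >= 0,
            hotspot_size_range[1] > 0, hotspot_size_range[1] <= hotspot_size_range[2])
  set.seed(derive_seed(seed, 1))
  chroms <- paste0("chr", seq_len(n_chromosomes))
  per_chrom <- tabulate(sample(rep(seq_len(n_chromosomes), length.out = n_hotspots)),
                        nbins = n_chromosomes)
  hs <- list()
  for (i in seq_len(n_chromosomes)) {
    k <- per_chrom[i]
    if (k == 0) next
    sizes <- round(stats::runif(k, hotspot_size_range[1], hotspot_size_range[2]))
    # place left to right with at least `flank_size`+spacing between, error if they cannot fit
    margin <- flank_size + 2e5
    avail <- chromosome_length - 2 * margin - sum(sizes) - (k - 1) * margin
    if (avail < 0) stop("cannot pack ", k, " hotspots into chromosome ", chroms[i])
    gaps <- if (k > 0) diff(c(0, sort(stats::runif(k, 0, avail)))) else numeric()
    starts <- margin + cumsum(gaps) + c(0, cumsum(sizes[-k] + margin))[seq_len(k)]
    hs[[i]] <- data.frame(chrom = chroms[i], start = round(starts),
                          end = round(starts) + sizes, stringsAsFactors = FALSE)
  }
  hotspots <- if (length(hs)) normalize_intervals(do.call(rbind, hs)) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  flanks <- if (nrow(hotspots)) {
    normalize_intervals(rbind(
      data.frame(chrom = hotspots$chrom, start = hotspots$start - flank_size,
                 end = hotspots$start, stringsAsFactors = FALSE),
      data.frame(chrom = hotspots$chrom, start = hotspots$end,
                 end = hotspots$end + flank_size, stringsAsFactors = FALSE)))
  } else hotspots
  layout <- list(chromosomes = data.frame(chrom = chroms, length = chromosome_length,
                                          stringsAsFactors = FALSE),
                 hotspots = hotspots, flanks = flanks)
  class(layout) <- "genome_layout"
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  stopifnot(all(layout$chromosomes$length > 0))
  for (part in c("hotspots", "flanks")) {
    iv <- layout[[part]]
    if (nrow(iv) == 0) next
    validate_intervals(iv)
    len <- layout$chromosomes$length[match(iv$chrom, layout$chromosomes$chrom)]
    if (any(is.na(len)) || any(iv$end > len)) stop(part, " extend beyond chromosome bounds")
    by_chr <- split(iv, iv$chrom)
    for (d in by_chr) {
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        stop(part, " overlap after normalization")
    }
  }
  invisible(layout)
}

## Total hotspot bp / total genome bp.
hotspot_fraction <- function(layout) {
  sum(interval_size(layout$hotspots)) / sum(layout$chromosomes$length)
}

## TRUE for positions (chrom, pos vectors) lying inside any interval of iv.
position_in <- function(chrom, pos, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  q <- data.frame(chrom = chrom, start = pos, end = pos + 1, stringsAsFactors = FALSE)
  hits <- overlap_pairs(q, iv)
  out <- rep(FALSE, length(pos))
  out[unique(hits$query)] <- TRUE
  out
}

#' Lay out probes over a genome at hotspot and backbone densities
#'
#' Probes (60-mer proxies) are dropped with jittered spacing so that the
#' median start-to-start distance is the requested one: dense inside
#' hotspot regions, sparse in the backbone, mirroring a targeted aCGH
#' design with ~2.6 kbp hotspot and ~36 kbp backbone spacing.
#'
#' @param layout a `genome_layout`
#' @param hotspot_spacing median probe spacing inside hotspots (bp)
#' @param backbone_spacing median probe spacing elsewhere (bp)
#' @param seed integer seed
#' @param probe_length probe footprint (bp)
#' @return a `probe_design` data.frame: `chrom`, `start`, `end`,
#'   `probe_id`, `class` (`hotspot`/`backbone`), sorted by position
#' @export
make_probe_design <- function(layout, hotspot_spacing = 2600,
                              backbone_spacing = 36000, seed = 1,
                              probe_length = 60) {
  stopifnot(hotspot_spacing > 0, backbone_spacing > 0)
  set.seed(derive_seed(seed, 2))
  rows <- list()
  for (i in seq_len(nrow(layout$chromosomes))) {
    chrom <- layout$chromosomes$chrom[i]
    len <- layout$chromosomes$length[i]
    hs <- layout$hotspots[layout$hotspots$chrom == chrom, , drop = FALSE]
    # segments alternate backbone/hotspot along the chromosome
    bounds <- c(0, as.vector(t(as.matrix(hs[, c("start", "end")]))), len)
    for (j in seq_len(length(bounds) - 1)) {
      s <- bounds[j]; e <- bounds[j + 1]
      if (e - s <= 0) next
      in_hs <- (j %% 2 == 0)
      spacing <- if (in_hs) hotspot_spacing else backbone_spacing
      n_max <- ceiling((e - s) / (spacing * 0.8)) + 2
      gaps <- spacing * stats::runif(n_max, 0.8, 1.2)
      pos <- s + cumsum(gaps) - gaps[1] * stats::runif(1)
      pos <- round(pos[pos >= s & pos + probe_length <= e])
      if (!length(pos)) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = pos, end = pos + probe_length,
        class = if (in_hs) "hotspot" else "backbone", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    design <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                         probe_id = character(), class = character(),
                         stringsAsFactors = FALSE)
    class(design) <- c("probe_design", "data.frame")
    return(design)
  }
  design <- do.call(rbind, rows)
  design <- design[order(match(design$chrom, layout$chromosomes$chrom), design$start), ]
  design$probe_id <- sprintf("P%06d", seq_len(nrow(design)))
  design <- design[, c("chrom", "start", "end", "probe_id", "class")]
  rownames(design) <- NULL
  class(design) <- c("probe_design", "data.frame")
  design
}

#' Read / write a probe design as BED
#'
#' Columns: chrom, start, end, probe_id, class.
#'
#' @param path file path
#' @param design a `probe_design`
#' @param cfg,seed optional provenance comment fields
#' @return `read_probe_design`: a `probe_design` data.frame
#' @export
read_probe_design <- function(path) {
  d <- read_intervals(path, col_names = c("probe_id", "class"))
  if (nrow(d) && anyDuplicated(d$probe_id)) stop("duplicate probe ids in ", path)
  class(d) <- c("probe_design", "data.frame")
  d
}

#' @rdname read_probe_design
#' @export
write_probe_design <- function(design, path, cfg = NULL, seed = NULL) {
  write_intervals(as.data.frame(design), path, cfg = cfg, seed = seed)
}
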