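#' Genomic interval records
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' using 0-based half-open coordinates, so `size = end - start`. Published
#' CNV tables that print 1-based starts round-trip through the
#' `one_based` dialect of [read_intervals()], which shifts only the start.
#'
#' @param chrom character chromosome names
#' @param start,end integer-like coordinates, `0 <= start < end`
#' @param ... further equal-length annotation columns
#' @return a data.frame of validated interval records
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0) return(invisible(iv))
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  invisible(iv)
}

#' Interval size in base pairs
#'
#' @param iv interval data.frame (`chrom`, `start`, `end`)
#' @return numeric vector `end - start`
#' @export
interval_size <- function(iv) {
  iv$end - iv$start
}

#' Reciprocal overlap of two intervals
#'
#' Returns the overlap expressed as a fraction of each interval's own
#' length, the quantity used for 50%-reciprocal-overlap matching of CNVs
#' against control maps, parents and disorder regions. Intervals on
#' different chromosomes (or disjoint ones) overlap by 0 in both
#' directions.
#'
#' @param a,b single-row interval data.frames (or lists with `chrom`,
#'   `start`, `end`)
#' @return numeric length-2 vector `c(overlap/size(a), overlap/size(b))`
#' @export
reciprocal_overlap <- function(a, b) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(c(0, 0))
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  c(ov / (a$end - a$start), ov / (b$end - b$start))
}

## Vectorised helper: overlap widths of one interval against many.
overlap_width <- function(start, end, starts, ends) {
  pmax(0, pmin(end, ends) - pmax(start, starts))
}

#' Sort and normalize interval records
#'
#' Sorts by (chrom, start, end); with `merge = TRUE` unions overlapping or
#' touching intervals per chromosome. Idempotent.
#'
#' @param iv interval data.frame
#' @param merge merge overlapping/adjacent intervals (drops extra columns)
#' @return normalized data.frame
#' @export
normalize_intervals <- function(iv, merge = FALSE) {
  validate_intervals(iv)
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  if (!merge || nrow(iv) < 2) return(iv)
  out <- do.call(rbind, lapply(split(iv, iv$chrom), function(d) {
    s <- d$start; e <- d$end
    keep_s <- s[1]; keep_e <- e[1]; rs <- c(); re <- c()
    for (i in seq_len(nrow(d))[-1]) {
      if (s[i] <= keep_e) {
        keep_e <- max(keep_e, e[i])
      } else {
        rs <- c(rs, keep_s); re <- c(re, keep_e)
        keep_s <- s[i]; keep_e <- e[i]
      }
    }
    data.frame(chrom = d$chrom[1], start = c(rs, keep_s), end = c(re, keep_e),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

## data.frame of intervals -> GRanges (internal; GenomicRanges does the
## heavy interval scans, coordinates shift to 1-based closed on the way in).
as_granges <- function(iv) {
  if (nrow(iv) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(seqnames = iv$chrom,
                         ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end))
}

## All-vs-all overlap pairs between two interval data.frames, with overlap
## width and reciprocal fractions. Returns data.frame (query, subject, width,
## frac_q, frac_s); zero rows when either side is empty.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query = integer(), subject = integer(), width = numeric(),
                      frac_q = numeric(), frac_s = numeric()))
  }
  # disjoint chromosome sets are a legitimate no-overlap case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- pmin(query$end[qi], subject$end[si]) - pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, width = w,
             frac_q = w / (query$end[qi] - query$start[qi]),
             frac_s = w / (subject$end[si] - subject$start[si]))
}
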