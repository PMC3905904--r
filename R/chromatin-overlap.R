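#' Restrict a peak set to array-covered regions
#'
#' Clips every peak to its intersection with the covered regions; peaks
#' entirely outside the covered space are dropped, straddling peaks are
#' trimmed (and may be split by coverage gaps).
#'
#' @param peaks,covered BED-like data frames (chrom, start, end).
#' @return BED-like data frame of clipped peaks.
#' @export
restrict_to_array <- function(peaks, covered) {
  if (!nrow(peaks) || !nrow(covered)) {
    return(peaks[0, c("chrom", "start", "end"), drop = FALSE])
  }
  pg <- bed_to_gr(peaks)
  cg <- GenomicRanges::reduce(bed_to_gr(covered))
  hits <- GenomicRanges::findOverlaps(pg, cg)
  if (!length(hits)) {
    return(peaks[0, c("chrom", "start", "end"), drop = FALSE])
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    chrom = peaks$chrom[q],
    start = pmax(peaks$start[q], gr_to_bed(cg)$start[s]),
    end = pmin(peaks$end[q], gr_to_bed(cg)$end[s]),
    stringsAsFactors = FALSE
  )
  out <- out[out$end > out$start, , drop = FALSE]
  out <- out[order(match(out$chrom, unique(peaks$chrom)), out$start), ]
  rownames(out) <- NULL
  out
}

#' Regions carrying a peak of only one mark
#'
#' Subtracts the union of all other marks' peak coordinates from the
#' target mark's peaks; remaining fragments shorter than `min_width_bp`
#' are dropped as slivers.
#'
#' @param target BED-like peak table of the mark of interest.
#' @param others List of BED-like peak tables for the other marks.
#' @param min_width_bp Minimum surviving fragment width.
#' @return BED-like data frame of unique-mark fragments.
#' @export
unique_mark_peaks <- function(target, others, min_width_bp = 50L) {
  if (!nrow(target)) {
    return(target[0, c("chrom", "start", "end"), drop = FALSE])
  }
  tg <- GenomicRanges::reduce(bed_to_gr(target))
  other_rows <- Filter(function(d) nrow(d) > 0, others)
  if (length(other_rows)) {
    og <- GenomicRanges::reduce(
      do.call(c, unname(lapply(other_rows, bed_to_gr))))
    tg <- GenomicRanges::setdiff(tg, og)
  }
  out <- gr_to_bed(tg)
  out <- out[(out$end - out$start) >= min_width_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify enhancers into poised and active states
#'
#' Poised enhancers are H3K4me1 peaks overlapping no H3K27ac peak; active
#' enhancers overlap H3K27ac. By default H3K4me1 peaks overlapping
#' H3K4me3 are excluded from both states, so promoter-proximal H3K4me1 is
#' not misread as an enhancer.
#'
#' @param k4me1,k27ac,k4me3 BED-like peak tables.
#' @param exclude_promoters Drop H3K4me1 peaks overlapping H3K4me3.
#' @return List with `poised` and `active` BED-like tables.
#' @export
enhancer_states <- function(k4me1, k27ac, k4me3 = NULL,
                            exclude_promoters = TRUE) {
  if (!nrow(k4me1)) {
    return(list(poised = k4me1, active = k4me1))
  }
  g1 <- bed_to_gr(k4me1)
  has_ac <- if (nrow(k27ac)) IRanges::overlapsAny(g1, bed_to_gr(k27ac))
    else rep(FALSE, nrow(k4me1))
  has_me3 <- if (exclude_promoters && !is.null(k4me3) && nrow(k4me3)) {
    IRanges::overlapsAny(g1, bed_to_gr(k4me3))
  } else {
    rep(FALSE, nrow(k4me1))
  }
  list(poised = k4me1[!has_ac & !has_me3, , drop = FALSE],
       active = k4me1[has_ac & !has_me3, , drop = FALSE])
}

#' Fraction of feature peaks overlapping 5hmC peaks
#'
#' A feature peak counts as overlapping when it intersects any 5hmC peak
#' by at least 1 bp. The denominator (total feature peaks) is reported
#' alongside the percentage.
#'
#' @param features BED-like feature peak table (must be non-empty).
#' @param hmc_peaks BED-like 5hmC peak table.
#' @return List with `percent`, `n_overlapping`, `n_features`.
#' @export
overlap_fraction <- function(features, hmc_peaks) {
  if (!nrow(features)) stop("no feature peaks supplied")
  hit <- if (nrow(hmc_peaks)) {
    IRanges::overlapsAny(bed_to_gr(features), bed_to_gr(hmc_peaks))
  } else {
    rep(FALSE, nrow(features))
  }
  list(percent = 100 * mean(hit),
       n_overlapping = sum(hit),
       n_features = nrow(features))
}
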