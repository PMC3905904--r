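#' Probe-level signal track
#'
#' The central signal container: an ordered set of tiling-array probe
#' intervals with one column of log2(IP/input) values per sample, plus a
#' sample-metadata table. Coordinates are 0-based half-open, probes are
#' sorted by (chrom, start) and non-overlapping.
#'
#' @param probes data frame with columns `chrom`, `start`, `end`.
#' @param values numeric matrix, one row per probe, one column per sample.
#' @param samples data frame of sample metadata with at least a `sample_id`
#'   column (one row per column of `values`). If `NULL`, ids are taken from
#'   the column names of `values`.
#' @return An object of class `probe_track`.
#' @export
probe_track <- function(probes, values, samples = NULL) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "start", "end") %in% names(probes)))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(probes)
  if (nrow(values) != n) {
    stop("`values` must have one row per probe (", n, "), got ", nrow(values))
  }
  if (is.null(samples)) {
    ids <- colnames(values) %||% paste0("S", seq_len(ncol(values)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(samples)) {
    stop("`samples` must contain a `sample_id` column")
  }
  if (nrow(samples) != ncol(values)) {
    stop("`samples` must have one row per value column")
  }
  colnames(values) <- samples$sample_id
  if (any(probes$end <= probes$start)) {
    stop("probe end must be greater than start")
  }
  ord <- order(match(probes$chrom, unique(probes$chrom)), probes$start)
  if (!identical(ord, seq_len(n))) {
    stop("probes must be sorted by (chrom, start)")
  }
  if (n > 1L) {
    same <- probes$chrom[-1L] == probes$chrom[-n]
    if (any(same & probes$start[-1L] < probes$end[-n])) {
      stop("probes must not overlap")
    }
  }
  rownames(probes) <- NULL
  structure(
    list(probes = probes[c("chrom", "start", "end")],
         values = values, samples = samples),
    class = "probe_track"
  )
}

#' @export
print.probe_track <- function(x, ...) {
  cat("probe_track:", nrow(x$probes), "probes x", ncol(x$values),
      "samples\n")
  cat("samples:", paste(x$samples$sample_id, collapse = ", "), "\n")
  invisible(x)
}

#' Number of probes in a track
#' @param track A `probe_track`.
#' @return Integer probe count.
#' @export
n_probes <- function(track) nrow(track$probes)

#' Probe midpoints (0-based, possibly half-integer)
#' @param track A `probe_track`.
#' @return Numeric vector of midpoints.
#' @export
probe_midpoints <- function(track) (track$probes$start + track$probes$end) / 2

#' Probe intervals of a track as GRanges
#' @param track A `probe_track`.
#' @return A `GRanges` of probe intervals.
#' @export
track_granges <- function(track) bed_to_gr(track$probes)

# Resolve a sample spec (index, id, or NULL-for-single-sample) to an index.
sample_index <- function(track, sample) {
  if (is.null(sample)) {
    if (ncol(track$values) == 1L) return(1L)
    stop("`sample` must be given for a multi-sample track")
  }
  if (is.numeric(sample)) {
    idx <- as.integer(sample)
  } else {
    idx <- match(sample, track$samples$sample_id)
  }
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > ncol(track$values))) {
    stop("unknown sample: ", paste(sample, collapse = ", "))
  }
  idx
}

#' Contiguous tiling segments of a track
#'
#' Probes are grouped into runs broken at chromosome changes and at tiling
#' gaps larger than `max_gap_bp` (the distance between one probe's end and
#' the next probe's start). Window-based operations (peak calling,
#' autocorrelation, bias-region scans) never span segment boundaries.
#'
#' @param track A `probe_track`.
#' @param max_gap_bp Maximum tolerated inter-probe gap in bp.
#' @return Integer vector of segment ids, one per probe.
#' @export
track_segments <- function(track, max_gap_bp = 1000) {
  n <- n_probes(track)
  if (n == 0L) return(integer(0))
  brk <- c(TRUE,
           track$probes$chrom[-1L] != track$probes$chrom[-n] |
             (track$probes$start[-1L] - track$probes$end[-n]) > max_gap_bp)
  cumsum(brk)
}

#' Subset a track to selected samples
#' @param track A `probe_track`.
#' @param samples Sample ids or indices to keep.
#' @return A `probe_track` with the selected sample columns.
#' @export
select_samples <- function(track, samples) {
  idx <- sample_index(track, samples)
  probe_track(track$probes, track$values[, idx, drop = FALSE],
              track$samples[idx, , drop = FALSE])
}

#' Combine tracks over the same probe layout
#' @param ... `probe_track` objects sharing an identical probe layout.
#' @return A single `probe_track` with all sample columns.
#' @export
cbind_tracks <- function(...) {
  tracks <- list(...)
  ref <- tracks[[1L]]$probes
  for (t in tracks[-1L]) {
    if (!identical(t$probes, ref)) stop("probe layouts differ")
  }
  probe_track(ref,
              do.call(cbind, lapply(tracks, `[[`, "values")),
              do.call(rbind, lapply(tracks, function(t) {
                cols <- Reduce(intersect, lapply(tracks, function(x)
                  names(x$samples)))
                t$samples[, cols, drop = FALSE]
              })))
}
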