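#' Loess normalization of log-ratio probe values
#'
#' Removes intensity-dependent trend from M (log2 IP/input) values by a
#' robust locally weighted regression of M on A (mean log-intensity),
#' replacing M by the residuals. When no A-values are available — the case
#' for simulated tracks, which carry log2 ratios directly — the step is a
#' no-op and a notice is emitted.
#'
#' @param track A [probe_track()].
#' @param A Per-probe mean log-intensities: a numeric vector (shared by
#'   all samples) or a matrix with one column per sample. `NULL` skips the
#'   fit.
#' @param samples Samples to normalize (default all).
#' @param span Loess span (fraction of probes in each local window).
#' @return The normalized `probe_track`.
#' @export
loess_normalize <- function(track, A = NULL, samples = NULL, span = 0.3) {
  if (is.null(A)) {
    message("no A-values supplied; loess normalization skipped")
    return(track)
  }
  idx <- if (is.null(samples)) seq_len(ncol(track$values)) else
    sample_index(track, samples)
  n <- n_probes(track)
  if (n < 50L) stop("refusing to fit loess on fewer than 50 probes")
  if (is.matrix(A)) {
    if (nrow(A) != n) stop("`A` must have one row per probe")
  } else {
    if (length(A) != n) stop("`A` must have one value per probe")
    A <- matrix(A, nrow = n, ncol = ncol(track$values))
  }
  values <- track$values
  for (j in idx) {
    fit <- limma::loessFit(values[, j], A[, j], span = span,
                           iterations = 4L)
    values[, j] <- fit$residuals
  }
  probe_track(track$probes, values, track$samples)
}

#' Scale normalization across samples
#'
#' Equalizes spread between samples: each sample's values are divided by
#' that sample's median absolute deviation and multiplied by the geometric
#' mean of all samples' MADs. After the step every sample has the same MAD.
#'
#' @param track A [probe_track()].
#' @return The scale-normalized `probe_track`.
#' @export
scale_normalize <- function(track) {
  mads <- apply(track$values, 2L, mad)
  if (any(mads == 0)) {
    stop("zero MAD in sample(s): ",
         paste(track$samples$sample_id[mads == 0], collapse = ", "))
  }
  g <- geometric_mean(mads)
  values <- sweep(track$values, 2L, mads, "/") * g
  probe_track(track$probes, values, track$samples)
}

#' Normalize a track (loess within samples, then scale between samples)
#'
#' @inheritParams loess_normalize
#' @return The normalized `probe_track`.
#' @export
normalize_track <- function(track, A = NULL, span = 0.3) {
  scale_normalize(loess_normalize(track, A = A, span = span))
}

#' Average biological replicates
#'
#' @param track A [probe_track()].
#' @param grouping Character or factor of length `ncol(values)` assigning
#'   each sample to a replicate group; group order follows first
#'   appearance. By default samples are grouped by tissue and technique.
#' @return A `probe_track` with one sample per group; the sample table
#'   records the number of replicates averaged (`n_replicates`).
#' @export
average_replicates <- function(track, grouping = NULL) {
  if (is.null(grouping)) {
    if (!all(c("tissue", "technique") %in% names(track$samples))) {
      stop("no grouping given and samples lack tissue/technique metadata")
    }
    grouping <- paste(track$samples$tissue, track$samples$technique,
                      sep = "_")
  }
  grouping <- as.character(grouping)
  if (length(grouping) != ncol(track$values)) {
    stop("`grouping` must have one entry per sample")
  }
  if (anyNA(grouping)) stop("grouping contains missing values")
  groups <- unique(grouping)
  values <- vapply(groups, function(g) {
    cols <- which(grouping == g)
    rowMeans(track$values[, cols, drop = FALSE])
  }, numeric(n_probes(track)))
  counts <- vapply(groups, function(g) sum(grouping == g), integer(1L))
  if (any(counts == 0L)) stop("empty replicate group")
  meta <- lapply(groups, function(g) {
    rows <- track$samples[grouping == g, , drop = FALSE]
    keep <- vapply(rows, function(col) length(unique(col)) == 1L,
                   logical(1L))
    out <- rows[1L, keep, drop = FALSE]
    out$sample_id <- g
    out
  })
  common <- Reduce(intersect, lapply(meta, names))
  samples <- do.call(rbind, lapply(meta, `[`, common))
  samples$n_replicates <- counts
  probe_track(track$probes, values, samples)
}

#' Randomize a track by permuting probe values
#'
#' Values are permuted uniformly over probes (independently per sample);
#' probe coordinates are unchanged, so the value multiset of every sample
#' is preserved while all spatial structure is destroyed. Used as the
#' noise-only reference in autocorrelation analysis.
#'
#' @param track A [probe_track()].
#' @param seed Permutation seed.
#' @param samples Samples to permute (default all).
#' @return The randomized `probe_track`.
#' @export
randomize_track <- function(track, seed = 1L, samples = NULL) {
  idx <- if (is.null(samples)) seq_len(ncol(track$values)) else
    sample_index(track, samples)
  values <- track$values
  with_seed(seed, {
    for (j in idx) {
      values[, j] <- values[sample.int(nrow(values)), j]
    }
  })
  probe_track(track$probes, values, track$samples)
}
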