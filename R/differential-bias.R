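#' Bias-region detection parameters
#'
#' @param fold_threshold Absolute log2 difference a probe must exceed.
#' @param min_probes Minimum consecutive probes beyond threshold.
#' @param min_region_bp Minimum genomic span of the probe run.
#' @param max_gap_bp Runs are broken at tiling gaps larger than this.
#' @return An object of class `bias_region_params`.
#' @export
bias_region_params <- function(fold_threshold = 1.5, min_probes = 3L,
                               min_region_bp = 200L, max_gap_bp = 1000L) {
  if (fold_threshold <= 0) stop("fold_threshold must be > 0")
  if (min_probes < 1L) stop("min_probes must be >= 1")
  structure(list(fold_threshold = fold_threshold,
                 min_probes = as.integer(min_probes),
                 min_region_bp = as.integer(min_region_bp),
                 max_gap_bp = as.integer(max_gap_bp)),
            class = "bias_region_params")
}

#' Per-probe difference track (chemical capture minus antibody)
#'
#' Delta = hMeSeal - hmeDIP per probe on an identical probe layout.
#' Positive values mark chemical-capture-biased probes, negative values
#' antibody-biased probes.
#'
#' @param seal_track,dip_track Single-sample [probe_track()]s (or use
#'   `seal_sample` / `dip_sample` to pick columns) on the same layout.
#' @param seal_sample,dip_sample Optional sample ids/indices.
#' @return A single-sample `probe_track` named `"delta"`.
#' @export
delta_track <- function(seal_track, dip_track, seal_sample = NULL,
                        dip_sample = NULL) {
  if (!identical(seal_track$probes, dip_track$probes)) {
    stop("probe layouts differ between the two tracks")
  }
  vs <- seal_track$values[, sample_index(seal_track, seal_sample)]
  vd <- dip_track$values[, sample_index(dip_track, dip_sample)]
  probe_track(seal_track$probes,
              matrix(vs - vd, ncol = 1L,
                     dimnames = list(NULL, "delta")),
              data.frame(sample_id = "delta", stringsAsFactors = FALSE))
}

#' Detect technique-biased regions on a delta track
#'
#' Maximal runs of at least `min_probes` consecutive probes (never
#' spanning a gap larger than `max_gap_bp`) that all satisfy
#' delta > +fold_threshold (chemical-capture-biased set) or all
#' delta < -fold_threshold (antibody-biased set), and whose genomic span
#' is at least `min_region_bp`.
#'
#' @param delta A single-sample [probe_track()] from [delta_track()].
#' @param params A [bias_region_params()].
#' @return List with `hmeseal_biased` and `hmedip_biased` interval tables
#'   (chrom, start, end, n_probes, mean_delta) and the per-probe flags.
#' @export
find_bias_regions <- function(delta, params = bias_region_params()) {
  v <- delta$values[, 1L]
  seg <- track_segments(delta, params$max_gap_bp)
  scan <- function(flag) {
    iv <- peak_probe_intervals(delta, flag, seg)
    runs <- attr(iv, "runs")
    keep <- iv$n_probes >= params$min_probes &
      (iv$end - iv$start) >= params$min_region_bp
    iv <- iv[keep, , drop = FALSE]
    iv$mean_delta <- vapply(runs[keep], function(r) mean(v[r]),
                            numeric(1L))
    attr(iv, "runs") <- NULL
    rownames(iv) <- NULL
    iv
  }
  up <- v > params$fold_threshold
  dn <- v < -params$fold_threshold
  list(hmeseal_biased = scan(up), hmedip_biased = scan(dn),
       probes_hmeseal_biased = up, probes_hmedip_biased = dn)
}

# Wilcoxon rank-sum p-value: exact when both groups are small and tie-free,
# otherwise the normal approximation with tie and continuity correction.
wilcoxon_p <- function(x, y, exact_max_n = 25L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= exact_max_n && length(y) <= exact_max_n && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Signal distributions over repeat classes with technique comparison
#'
#' Probes overlapping (>= 1 bp) an interval of each repeat class
#' contribute their value; the two techniques are compared per class by a
#' two-sided Wilcoxon rank-sum test. Classes covered by no probe are
#' skipped with a notice.
#'
#' @param track A [probe_track()].
#' @param sample1,sample2 The two samples (techniques) to compare.
#' @param repeats Repeat table with `chrom`, `start`, `end`, `class`.
#' @return List with `stats` (class, n_probes, per-sample mean/median,
#'   Wilcoxon p) and `values` (per-class value lists).
#' @export
repeat_class_signal <- function(track, sample1, sample2, repeats) {
  j1 <- sample_index(track, sample1)
  j2 <- sample_index(track, sample2)
  pg <- track_granges(track)
  classes <- unique(repeats$class)
  rows <- list()
  values <- list()
  for (cls in classes) {
    sub <- repeats[repeats$class == cls, , drop = FALSE]
    idx <- which(suppressWarnings(
      IRanges::overlapsAny(pg, bed_to_gr(sub))))
    if (!length(idx)) {
      message("repeat class ", cls, " covered by no probe; skipped")
      next
    }
    x <- track$values[idx, j1]
    y <- track$values[idx, j2]
    rows[[cls]] <- data.frame(
      class = cls, n_probes = length(idx),
      mean1 = mean(x), mean2 = mean(y),
      median1 = median(x), median2 = median(y),
      p_value = wilcoxon_p(x, y),
      stringsAsFactors = FALSE
    )
    values[[cls]] <- list(sample1 = x, sample2 = y)
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  list(stats = stats, values = values,
       samples = track$samples$sample_id[c(j1, j2)])
}

#' CpG observed/expected ratio of sequence windows
#'
#' (CpG count x window length) / (C count x G count); windows lacking
#' either C or G yield `NA`.
#'
#' @param x Character vector of sequences (or a single
#'   [Biostrings::DNAStringSet]).
#' @return Numeric vector of o/e ratios.
#' @export
cpg_obs_exp <- function(x) {
  if (!methods::is(x, "DNAStringSet")) {
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  }
  cg <- Biostrings::vcountPattern("CG", x)
  freq <- Biostrings::letterFrequency(x, c("C", "G"))
  len <- Biostrings::width(x)
  unname(ifelse(freq[, "C"] > 0 & freq[, "G"] > 0,
                (cg * len) / (freq[, "C"] * freq[, "G"]),
                NA_real_))
}

#' CpG o/e distribution of fragments around peak probes
#'
#' Computes the observed/expected CpG ratio over fragment-size windows
#' centered on each peak-probe midpoint, characterizing the CpG
#' composition of the DNA fragments a technique enriches.
#'
#' @param track A [probe_track()].
#' @param peak_probes Logical per probe, or integer indices.
#' @param sequence A [Biostrings::DNAStringSet] of chromosome sequences.
#' @param fragment_bp Window width (sonication fragment size).
#' @return Numeric vector of o/e values (NA where the window lacks C or
#'   G); empty for an empty peak set.
#' @export
fragment_cpg_profile <- function(track, peak_probes, sequence,
                                 fragment_bp = 300L) {
  idx <- if (is.logical(peak_probes)) which(peak_probes) else
    as.integer(peak_probes)
  if (!length(idx)) return(numeric(0))
  mid <- probe_midpoints(track)[idx]
  window_cpg_oe(sequence, track$probes$chrom[idx], mid, fragment_bp)
}
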