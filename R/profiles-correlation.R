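#' Sample correlation matrix and hierarchical clustering
#'
#' Pearson correlations between samples over a common random probe subset,
#' followed by agglomerative clustering with Ward linkage. The dendrogram
#' is also serialized as newick.
#'
#' @param track A [probe_track()] with at least two samples.
#' @param n_random_probes Number of probes to sample without replacement;
#'   when it exceeds the probe count all probes are used (with a notice).
#' @param seed Sampling seed.
#' @param distance `"one_minus_cor"` (1 - Pearson r) or `"euclidean"`.
#' @return List of class `correlation_cluster`: `cor` (matrix), `hclust`,
#'   `newick`, `n_probes_used`.
#' @export
correlation_cluster <- function(track, n_random_probes = 500000L,
                                seed = 1L,
                                distance = c("one_minus_cor", "euclidean")) {
  distance <- match.arg(distance)
  if (ncol(track$values) < 2L) stop("need at least two samples")
  n <- n_probes(track)
  if (n_random_probes > n) {
    message("n_random_probes (", n_random_probes, ") exceeds probe count (",
            n, "); using all probes")
    idx <- seq_len(n)
  } else {
    idx <- with_seed(seed, sort(sample.int(n, n_random_probes)))
  }
  sub <- track$values[idx, , drop = FALSE]
  sds <- apply(sub, 2L, sd)
  if (any(sds == 0)) {
    stop("constant-valued sample(s), correlation undefined: ",
         paste(track$samples$sample_id[sds == 0], collapse = ", "))
  }
  cmat <- cor(sub)
  d <- switch(distance,
              one_minus_cor = as.dist(1 - cmat),
              euclidean = dist(t(sub)))
  hc <- hclust(d, method = "ward.D2")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(cor = cmat, hclust = hc, newick = newick,
                 n_probes_used = length(idx), distance = distance),
            class = "correlation_cluster")
}

#' Probe-signal autocorrelation by lag
#'
#' For lag k, the Pearson correlation of (value_i, value_{i+k}) over all
#' probe pairs lying in the same contiguous tiling segment (same
#' chromosome, no inter-probe gap larger than `max_gap_bp` anywhere
#' between them). Lag 0 is 1 by definition.
#'
#' @param track A [probe_track()].
#' @param sample Sample id or index.
#' @param max_lag_probes Largest lag, in probes (40 probes at 250 bp
#'   spacing is ~10 kb).
#' @param max_gap_bp Segment-breaking gap.
#' @return data frame with `lag` (0..max_lag), `r`, `n_pairs`.
#' @export
autocorrelation <- function(track, sample = NULL, max_lag_probes = 40L,
                            max_gap_bp = 1000L) {
  j <- sample_index(track, sample)
  v <- track$values[, j]
  seg <- track_segments(track, max_gap_bp)
  n <- length(v)
  if (max_lag_probes >= max(table(seg))) {
    stop("max_lag_probes must be smaller than the longest tiling segment")
  }
  out <- data.frame(lag = 0:max_lag_probes, r = NA_real_,
                    n_pairs = NA_integer_)
  out$r[1L] <- 1
  out$n_pairs[1L] <- n
  for (k in seq_len(max_lag_probes)) {
    i <- seq_len(n - k)
    ok <- seg[i] == seg[i + k]
    if (sum(ok) < 3L) stop("too few pairs at lag ", k)
    out$r[k + 1L] <- cor(v[i][ok], v[i + k][ok])
    out$n_pairs[k + 1L] <- sum(ok)
  }
  out
}

#' Length-adjusted gene-level 5hmC scores
#'
#' The mean of all probe values whose midpoints fall inside the gene body,
#' divided by gene length in bp. Genes covered by no probe get `NA`.
#'
#' @param track A [probe_track()].
#' @param genes Gene table with `chrom`, `start`, `end`, `gene_id`.
#' @param samples Samples to score (default all).
#' @return data frame: `gene_id`, `n_probes`, one score column per sample.
#' @export
gene_scores <- function(track, genes, samples = NULL) {
  idx <- if (is.null(samples)) seq_len(ncol(track$values)) else
    sample_index(track, samples)
  mid <- probe_midpoints(track)
  mp <- points_to_gr(track$probes$chrom, mid)
  hits <- GenomicRanges::findOverlaps(mp, bed_to_gr(genes))
  q <- S4Vectors::queryHits(hits)
  g <- S4Vectors::subjectHits(hits)
  len <- genes$end - genes$start
  out <- data.frame(gene_id = genes$gene_id,
                    n_probes = tabulate(g, nbins = nrow(genes)))
  for (j in idx) {
    score <- rep(NA_real_, nrow(genes))
    if (length(q)) {
      agg <- rowsum(track$values[q, j], g)
      gi <- as.integer(rownames(agg))
      score[gi] <- (agg[, 1L] / out$n_probes[gi]) / len[gi]
    }
    out[[track$samples$sample_id[j]]] <- score
  }
  out
}

#' Concordance of gene-level scores between two samples
#'
#' @param scores Output of [gene_scores()].
#' @param sample1,sample2 Column names of the two samples.
#' @return List with `r` (Pearson, over genes non-missing in both),
#'   `n_genes` and the paired `table`.
#' @export
gene_score_concordance <- function(scores, sample1, sample2) {
  x <- scores[[sample1]]
  y <- scores[[sample2]]
  if (is.null(x) || is.null(y)) stop("unknown sample column")
  ok <- complete.cases(x, y)
  if (sum(ok) < 3L) stop("fewer than 3 genes scored in both samples")
  list(r = cor(x[ok], y[ok]), n_genes = sum(ok),
       table = data.frame(gene_id = scores$gene_id[ok],
                          x = x[ok], y = y[ok]))
}

#' Metagene profile parameters
#'
#' @param flank_fraction Flank length as a fraction of gene length.
#' @param n_body_bins Bins across the gene body.
#' @param n_flank_bins Bins across each flank.
#' @param min_probes_per_bin Bins with fewer probes in a gene are missing
#'   for that gene (not zero), so sparse coverage does not bias the mean.
#' @return An object of class `metagene_params`.
#' @export
metagene_params <- function(flank_fraction = 0.25, n_body_bins = 100L,
                            n_flank_bins = 25L, min_probes_per_bin = 1L) {
  if (flank_fraction < 0 || flank_fraction > 1) {
    stop("flank_fraction must lie in [0, 1]")
  }
  if (n_body_bins < 1L || (flank_fraction > 0 && n_flank_bins < 1L)) {
    stop("bin counts must be positive")
  }
  structure(list(flank_fraction = flank_fraction,
                 n_body_bins = as.integer(n_body_bins),
                 n_flank_bins = as.integer(n_flank_bins),
                 min_probes_per_bin = as.integer(min_probes_per_bin)),
            class = "metagene_params")
}

#' Length-normalized metagene signal profile
#'
#' Each gene (plus flanks of `flank_fraction` of its length on either
#' side) is mapped onto a fixed grid of flank + body + flank bins by
#' fractional position, oriented so bin 1 is upstream-most regardless of
#' strand. Probes are assigned to the bin containing their midpoint; the
#' profile is the across-gene mean of per-gene bin means.
#'
#' @param track A [probe_track()].
#' @param sample Sample id or index.
#' @param genes Gene table with strand.
#' @param params A [metagene_params()].
#' @return data frame: `bin`, `zone` (upstream/body/downstream),
#'   `position` (fractional gene coordinate of the bin center, 0 = TSS,
#'   1 = TES), `mean_signal`, `n_genes`.
#' @export
metagene_profile <- function(track, sample = NULL, genes,
                             params = metagene_params()) {
  j <- sample_index(track, sample)
  v <- track$values[, j]
  if (any(genes$end <= genes$start)) stop("zero-length gene")
  ff <- params$flank_fraction
  nb <- params$n_body_bins
  nf <- if (ff > 0) params$n_flank_bins else 0L
  B <- nb + 2L * nf

  mid <- probe_midpoints(track)
  len <- genes$end - genes$start
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0, floor(genes$start - ff * len)),
                    end = ceiling(genes$end + ff * len))
  hits <- GenomicRanges::findOverlaps(points_to_gr(track$probes$chrom, mid),
                                      bed_to_gr(win))
  q <- S4Vectors::queryHits(hits)
  g <- S4Vectors::subjectHits(hits)

  # oriented fractional position: 0 at TSS, 1 at TES
  t_pos <- ifelse(genes$strand[g] == "+",
                  (mid[q] - genes$start[g]) / len[g],
                  (genes$end[g] - mid[q]) / len[g])
  bin <- integer(length(t_pos))
  up <- t_pos < 0
  body <- t_pos >= 0 & t_pos < 1
  down <- t_pos >= 1
  if (nf > 0L) {
    bin[up] <- pmax(1L, nf + 1L + as.integer(floor(t_pos[up] / ff * nf)))
    bin[down] <- pmin(B, nf + nb + 1L +
                        as.integer(floor((t_pos[down] - 1) / ff * nf)))
  }
  bin[body] <- nf + 1L + as.integer(floor(t_pos[body] * nb))
  keep <- bin >= 1L & bin <= B & !(nf == 0L & !body)
  bin <- bin[keep]; q <- q[keep]; g <- g[keep]

  key <- (g - 1) * B + bin
  cnt <- tabulate(key, nbins = nrow(genes) * B)
  sums <- numeric(nrow(genes) * B)
  if (length(key)) {
    agg <- rowsum(v[q], key)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  gene_bin_mean <- matrix(ifelse(cnt >= params$min_probes_per_bin,
                                 sums / pmax(cnt, 1L), NA_real_),
                          nrow = nrow(genes), ncol = B, byrow = TRUE)
  prof <- colMeans(gene_bin_mean, na.rm = TRUE)
  ngen <- colSums(!is.na(gene_bin_mean))
  prof[ngen == 0L] <- NA_real_

  zone <- rep(c("upstream", "body", "downstream"), c(nf, nb, nf))
  pos <- c(if (nf) -ff + (seq_len(nf) - 0.5) / nf * ff,
           (seq_len(nb) - 0.5) / nb,
           if (nf) 1 + (seq_len(nf) - 0.5) / nf * ff)
  data.frame(bin = seq_len(B), zone = zone, position = pos,
             mean_signal = prof, n_genes = ngen)
}

#' Fixed-width signal profile around interval midpoints
#'
#' Expands each interval to `+/- half_width_bp` around its midpoint, bins
#' the window into `n_bins` equal-width bins, and averages per-interval
#' bin means across intervals. Used to profile 5hmC around histone-mark
#' peaks.
#'
#' @param track A [probe_track()].
#' @param sample Sample id or index.
#' @param intervals BED-like data frame (chrom, start, end); must be
#'   non-empty.
#' @param half_width_bp Half window width.
#' @param n_bins Number of bins across the window.
#' @return data frame: `bin`, `offset` (bin center relative to midpoint),
#'   `mean_signal`, `n_intervals`.
#' @export
midpoint_window_profile <- function(track, sample = NULL, intervals,
                                    half_width_bp = 5000L, n_bins = 50L) {
  if (is.null(intervals) || !nrow(intervals)) {
    stop("empty interval set")
  }
  j <- sample_index(track, sample)
  v <- track$values[, j]
  mid_i <- (intervals$start + intervals$end) / 2
  win <- data.frame(chrom = intervals$chrom,
                    start = pmax(0, floor(mid_i - half_width_bp)),
                    end = ceiling(mid_i + half_width_bp))
  mid_p <- probe_midpoints(track)
  hits <- GenomicRanges::findOverlaps(
    points_to_gr(track$probes$chrom, mid_p), bed_to_gr(win))
  q <- S4Vectors::queryHits(hits)
  g <- S4Vectors::subjectHits(hits)
  off <- mid_p[q] - mid_i[g]
  bin <- 1L + as.integer(floor((off + half_width_bp) /
                                 (2 * half_width_bp) * n_bins))
  keep <- bin >= 1L & bin <= n_bins
  bin <- bin[keep]; q <- q[keep]; g <- g[keep]
  key <- (g - 1) * n_bins + bin
  cnt <- tabulate(key, nbins = nrow(intervals) * n_bins)
  sums <- numeric(nrow(intervals) * n_bins)
  if (length(key)) {
    agg <- rowsum(v[q], key)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  m <- matrix(ifelse(cnt > 0L, sums / pmax(cnt, 1L), NA_real_),
              nrow = nrow(intervals), ncol = n_bins, byrow = TRUE)
  prof <- colMeans(m, na.rm = TRUE)
  nn <- colSums(!is.na(m))
  prof[nn == 0L] <- NA_real_
  centers <- -half_width_bp + (seq_len(n_bins) - 0.5) *
    (2 * half_width_bp / n_bins)
  data.frame(bin = seq_len(n_bins), offset = centers,
             mean_signal = prof, n_intervals = nn)
}
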