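test_that("correlation clustering recovers trivial sample relations", {
  set.seed(20)
  x <- rnorm(800)
  y <- rnorm(800)
  tr <- toy_track(cbind(a = x, b = x, c = y, d = -x))
  cl <- suppressMessages(correlation_cluster(tr, 1e6, seed = 1L))
  expect_equal(cl$cor["a", "b"], 1)
  expect_equal(cl$cor["a", "d"], -1)
  # duplicate samples merge first (at height ~0)
  first <- cl$hclust$merge[1L, ]
  expect_setequal(cl$hclust$labels[-first], c("a", "b"))
  expect_lt(cl$hclust$height[1L], 1e-12)
  expect_match(cl$newick, "^\\(")
  # constant sample is named
  bad <- toy_track(cbind(a = x, frozen = rep(1, 800)))
  expect_error(suppressMessages(correlation_cluster(bad, 1e6)), "frozen")
  expect_message(correlation_cluster(tr, 1e6, seed = 1L), "all probes")
})

test_that("sampled clustering is seed-reproducible", {
  st <- small_study()
  c1 <- correlation_cluster(st$track, 2000L, seed = 3L)
  c2 <- correlation_cluster(st$track, 2000L, seed = 3L)
  expect_identical(c1$cor, c2$cor)
  expect_equal(c1$n_probes_used, 2000L)
})

test_that("autocorrelation is 1 at lag 0 and tracks a known AR process", {
  # permuted values: null bound 3/sqrt(n)
  set.seed(21)
  n <- 20000L
  white <- toy_track(matrix(rnorm(n), ncol = 1L))
  ac0 <- autocorrelation(white, 1L, max_lag_probes = 5L)
  expect_equal(ac0$r[1L], 1)
  expect_true(all(abs(ac0$r[-1L]) < 3 / sqrt(n)))
  # AR(1) with rho = 0.5
  rho <- 0.5
  e <- rnorm(n)
  v <- as.numeric(stats::filter(e, rho, method = "recursive"))
  ar <- toy_track(matrix(v, ncol = 1L))
  expect_equal(autocorrelation(ar, 1L, 3L)$r[2L], rho, tolerance = 0.02)
  expect_error(autocorrelation(toy_track(matrix(rnorm(10), ncol = 1L)),
                               1L, 20L), "segment")
})

test_that("autocorrelation does not couple probes across gaps", {
  # two segments with opposite constant+trend signals: within-segment
  # lag-1 pairs only
  starts <- c(0, 250, 500, 750, 10000, 10250, 10500, 10750)
  v <- c(1, 2, 3, 4, -1, -2, -3, -4)
  tr <- gap_track(starts, v)
  ac <- autocorrelation(tr, 1L, max_lag_probes = 2L)
  expect_equal(ac$n_pairs[2L], 6L)
  # oracle: the six within-segment pairs only
  expect_equal(ac$r[2L], cor(c(1, 2, 3, -1, -2, -3),
                             c(2, 3, 4, -2, -3, -4)))
})

test_that("gene scores equal mean probe value over gene length", {
  genes <- data.frame(chrom = "chr1", start = c(1000L, 90000L),
                      end = c(6000L, 95000L),
                      gene_id = c("g1", "empty"),
                      stringsAsFactors = FALSE)
  tr <- toy_track(matrix(7, 400L, 1L))   # probes cover 0..1e5
  tr2 <- probe_track(tr$probes[tr$probes$start < 50000, , drop = FALSE],
                     tr$values[tr$probes$start < 50000, , drop = FALSE])
  gs <- gene_scores(tr2, genes)
  expect_equal(gs[gs$gene_id == "g1", 3L], 7 / 5000)
  expect_true(is.na(gs[gs$gene_id == "empty", 3L]))
  # brute-force oracle on a random instance
  set.seed(22)
  v <- rnorm(400)
  tr3 <- toy_track(matrix(v, ncol = 1L))
  g <- data.frame(chrom = "chr1", start = 10000L, end = 30000L,
                  gene_id = "gx", stringsAsFactors = FALSE)
  mid <- probe_midpoints(tr3)
  inside <- mid >= 10000 & mid < 30000
  expect_equal(gene_scores(tr3, g)[1L, 3L],
               mean(v[inside]) / 20000)
})

test_that("gene-score concordance behaves at the extremes", {
  sc <- data.frame(gene_id = paste0("g", 1:10), n_probes = 1L,
                   a = 1:10, b = 1:10, c = -(1:10))
  expect_equal(gene_score_concordance(sc, "a", "b")$r, 1)
  expect_equal(gene_score_concordance(sc, "a", "c")$r, -1)
  expect_error(gene_score_concordance(sc, "a", "zz"), "unknown")
})

test_that("metagene profile is flat for a constant track", {
  genes <- data.frame(chrom = "chr1", start = c(10000L, 60000L),
                      end = c(30000L, 80000L), strand = c("+", "-"),
                      gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  tr <- toy_track(matrix(1.5, 400L, 1L))
  mg <- metagene_profile(tr, 1L, genes)
  expect_true(all(abs(mg$mean_signal - 1.5) < 1e-12, na.rm = TRUE))
  expect_equal(nrow(mg), 150L)
  expect_error(metagene_profile(tr, 1L, transform(genes, end = start)),
               "zero-length")
})

test_that("metagene binning matches a single-gene manual oracle", {
  gene <- data.frame(chrom = "chr1", start = 10000L, end = 20000L,
                     strand = "+", gene_id = "g", stringsAsFactors = FALSE)
  set.seed(23)
  v <- rnorm(200)
  tr <- toy_track(matrix(v, ncol = 1L))
  p <- metagene_params(flank_fraction = 0.25, n_body_bins = 10L,
                       n_flank_bins = 5L)
  mg <- metagene_profile(tr, 1L, gene, p)
  mid <- probe_midpoints(tr)
  len <- 10000
  t_pos <- (mid - 10000) / len
  manual <- vapply(seq_len(20L), function(b) {
    # bins: 5 upstream ([-0.25,0) in 5 steps), 10 body, 5 downstream
    lo <- c(seq(-0.25, -0.05, by = 0.05),
            seq(0, 0.9, by = 0.1), seq(1, 1.2, by = 0.05))[b]
    hi <- lo + if (b <= 5L || b > 15L) 0.05 else 0.1
    sel <- t_pos >= lo & t_pos < hi
    if (any(sel)) mean(v[sel]) else NA_real_
  }, numeric(1L))
  expect_equal(mg$mean_signal, manual)
})

test_that("metagene profile is invariant under strand flip with mirrored signal", {
  n <- 400L
  set.seed(24)
  v <- rnorm(n)
  tr_fwd <- toy_track(matrix(v, ncol = 1L))
  tr_rev <- toy_track(matrix(rev(v), ncol = 1L))
  # gene on + strand vs its mirror image on - strand; L chosen so the
  # probe-midpoint grid maps onto itself under reflection
  L <- 250 * (n - 1) + 60
  g_fwd <- data.frame(chrom = "chr1", start = 20000L, end = 50000L,
                      strand = "+", gene_id = "g", stringsAsFactors = FALSE)
  g_rev <- data.frame(chrom = "chr1", start = L - 50000L, end = L - 20000L,
                      strand = "-", gene_id = "g", stringsAsFactors = FALSE)
  m1 <- metagene_profile(tr_fwd, 1L, g_fwd)
  m2 <- metagene_profile(tr_rev, 1L, g_rev)
  expect_equal(m1$mean_signal, m2$mean_signal, tolerance = 1e-9)
})

test_that("midpoint window profiles average correctly", {
  tr <- toy_track(matrix(2, 400L, 1L))
  iv <- data.frame(chrom = "chr1", start = c(20000L, 50000L),
                   end = c(21000L, 51000L))
  mp <- midpoint_window_profile(tr, 1L, iv, 5000L, 20L)
  expect_true(all(abs(mp$mean_signal - 2) < 1e-12, na.rm = TRUE))
  expect_error(midpoint_window_profile(tr, 1L, iv[0, ]), "empty")
  # symmetric signal around a midpoint gives a symmetric profile; the
  # center sits midway between two probes so the probe grid maps onto
  # itself under reflection
  center <- 50155
  v <- exp(-((probe_midpoints(tr) - center) / 2000)^2)
  trs <- toy_track(matrix(v, ncol = 1L))
  mps <- midpoint_window_profile(trs, 1L,
                                 data.frame(chrom = "chr1",
                                            start = center - 10L,
                                            end = center + 10L),
                                 5000L, 20L)
  expect_equal(mps$mean_signal, rev(mps$mean_signal), tolerance = 1e-9)
})
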