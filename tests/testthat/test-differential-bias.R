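test_that("delta track is the per-probe hMeSeal minus hmeDIP difference", {
  set.seed(30)
  v1 <- rnorm(100); v2 <- rnorm(100)
  seal <- toy_track(matrix(v1, ncol = 1L))
  dip <- toy_track(matrix(v2, ncol = 1L))
  d <- delta_track(seal, dip)
  expect_equal(d$values[, 1L], v1 - v2)
  expect_equal(delta_track(dip, seal)$values[, 1L], -(v1 - v2))
  expect_equal(delta_track(seal, seal)$values[, 1L], rep(0, 100))
  shifted <- toy_track(matrix(v2, ncol = 1L), start0 = 10L)
  expect_error(delta_track(seal, shifted), "layout")
})

test_that("bias regions require sustained runs beyond the threshold", {
  # alternating +2/-2: no run of three
  alt <- toy_track(matrix(rep(c(2, -2), 10L), ncol = 1L))
  r <- find_bias_regions(alt)
  expect_equal(nrow(r$hmeseal_biased), 0L)
  expect_equal(nrow(r$hmedip_biased), 0L)
  # five consecutive +2 probes spanning 1 kb: one chemical-capture region
  v <- rep(0, 20); v[8:12] <- 2
  run <- toy_track(matrix(v, ncol = 1L))
  r2 <- find_bias_regions(run)
  expect_equal(nrow(r2$hmeseal_biased), 1L)
  expect_equal(r2$hmeseal_biased$n_probes, 5L)
  expect_equal(r2$hmeseal_biased$start, 7L * 250)
  expect_equal(r2$hmeseal_biased$mean_delta, 2)
  expect_equal(nrow(r2$hmedip_biased), 0L)
})

test_that("bias-region scan matches the brute-force run oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(50:800, 1L)
    starts <- cumsum(sample(c(rep(250L, 15L), 2500L), n, replace = TRUE))
    v <- rnorm(n, 0, 1.3)
    tr <- gap_track(starts, v)
    params <- bias_region_params()
    got <- find_bias_regions(tr, params)
    seg <- track_segments(tr, params$max_gap_bp)
    up <- brute_force_bias_intervals(tr, v > params$fold_threshold, seg,
                                     params$min_probes,
                                     params$min_region_bp)
    dn <- brute_force_bias_intervals(tr, v < -params$fold_threshold, seg,
                                     params$min_probes,
                                     params$min_region_bp)
    expect_equal(got$hmeseal_biased[c("chrom", "start", "end")], up,
                 ignore_attr = TRUE)
    expect_equal(got$hmedip_biased[c("chrom", "start", "end")], dn,
                 ignore_attr = TRUE)
  }
})

test_that("the two bias sets are disjoint and swap under negation", {
  set.seed(32)
  v <- rnorm(500, 0, 1.5)
  tr <- toy_track(matrix(v, ncol = 1L))
  neg <- toy_track(matrix(-v, ncol = 1L))
  r <- find_bias_regions(tr)
  rn <- find_bias_regions(neg)
  expect_false(any(r$probes_hmeseal_biased & r$probes_hmedip_biased))
  expect_equal(r$hmeseal_biased[c("chrom", "start", "end", "n_probes")],
               rn$hmedip_biased[c("chrom", "start", "end", "n_probes")])
  expect_equal(r$hmeseal_biased$mean_delta, -rn$hmedip_biased$mean_delta)
  expect_equal(r$hmedip_biased[c("chrom", "start", "end", "n_probes")],
               rn$hmeseal_biased[c("chrom", "start", "end", "n_probes")])
})

test_that("repeat-class comparison uses the Wilcoxon rank-sum test", {
  set.seed(33)
  n <- 1000L
  reps <- data.frame(chrom = "chr1", start = 0L, end = 250L * n,
                     class = "Line1", stringsAsFactors = FALSE)
  # identical samples: p ~ 1
  x <- rnorm(n)
  same <- toy_track(cbind(a = x, b = x),
                    samples = data.frame(sample_id = c("a", "b")))
  rs <- repeat_class_signal(same, "a", "b", reps)
  expect_gte(rs$stats$p_value, 0.99)
  # one-sd shift at n = 1000: overwhelming evidence
  shift <- toy_track(cbind(a = x + 1, b = x),
                     samples = data.frame(sample_id = c("a", "b")))
  expect_lt(repeat_class_signal(shift, "a", "b", reps)$stats$p_value,
            1e-10)
  # classes without probes are skipped with a notice
  reps2 <- rbind(reps, data.frame(chrom = "chr9", start = 0L, end = 100L,
                                  class = "SINE"))
  expect_message(out <- repeat_class_signal(same, "a", "b", reps2),
                 "SINE")
  expect_equal(out$stats$class, "Line1")
})

test_that("wilcoxon p-values match exact enumeration on small samples", {
  set.seed(34)
  for (i in 1:8) {
    n1 <- sample(2:8, 1L); n2 <- sample(2:8, 1L)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    expect_equal(hmcompare:::wilcoxon_p(x, y),
                 wilcoxon_exact_enum(x, y), tolerance = 1e-12)
  }
})

test_that("CpG observed/expected follows the counting definition", {
  expect_equal(cpg_obs_exp("CGCGCG"), 2.0)
  expect_equal(cpg_obs_exp("CCGG"), 1.0)
  expect_true(is.na(cpg_obs_exp("AATT")))
  expect_equal(cpg_obs_exp(c("CGCGCG", "AATT", "CCGG")),
               c(2, NA, 1))
})

test_that("fragment CpG profiles separate island-like and background peaks", {
  g <- tiny_genome()
  ann <- g$annotation
  probes <- tile_probes(ann)
  tr <- probe_track(probes, matrix(0, nrow(probes), 1L))
  pg <- bed_to_gr(probes)
  in_cgi <- IRanges::overlapsAny(pg, bed_to_gr(ann$cgi))
  occupied <- bed_to_gr(rbind(ann$cgi[c("chrom", "start", "end")],
                              ann$repeats[c("chrom", "start", "end")]))
  in_bg <- !IRanges::overlapsAny(pg, occupied)
  oe_cgi <- fragment_cpg_profile(tr, which(in_cgi), g$sequence)
  oe_bg <- fragment_cpg_profile(tr, which(in_bg)[1:200], g$sequence)
  expect_gt(mean(oe_cgi, na.rm = TRUE), mean(oe_bg, na.rm = TRUE))
  expect_length(fragment_cpg_profile(tr, integer(0), g$sequence), 0L)
})
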