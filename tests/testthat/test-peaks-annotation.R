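test_that("degenerate all-equal track peaks every gap-delimited run", {
  starts <- c(0, 250, 500, 750, 1000, 5000, 5250, 5500, 5750)
  tr <- gap_track(starts, rep(2, 9L))
  pc <- call_peaks(tr, 1L)
  expect_equal(pc$threshold, 2)
  expect_true(all(pc$peak_probes))
  expect_equal(nrow(pc$peaks), 2L)                 # one peak per segment
  expect_equal(pc$peaks$start, c(0, 5000))
  expect_equal(pc$peaks$n_probes, c(5L, 4L))
})

test_that("an isolated run of three hot probes is recovered exactly", {
  v <- rep(0, 30)
  v[11:13] <- 10
  tr <- toy_track(matrix(v, ncol = 1L))
  pc <- call_peaks(tr, 1L)
  # threshold (95th pct) sits between 0 and 10; any 4-window containing
  # the 3 hot probes passes, so probes 10..14 become peak probes
  expect_equal(which(pc$peak_probes), 10:14)
  seg <- track_segments(tr, 1000L)
  oracle <- brute_force_peak_probes(v, seg, 95, 4L, 3L)
  expect_identical(pc$peak_probes, oracle)
})

test_that("peak caller matches the brute-force window oracle", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(60:1500, 1L)
    starts <- cumsum(sample(c(rep(250L, 20L), 3000L), n, replace = TRUE))
    v <- rnorm(n) + sample(c(0, 3), n, replace = TRUE, prob = c(0.9, 0.1))
    w <- sample(3:5, 1L)
    mh <- sample(seq_len(w), 1L)
    pct <- sample(c(80, 90, 95), 1L)
    tr <- gap_track(starts, v)
    params <- peak_call_params(pct, w, mh)
    pc <- call_peaks(tr, 1L, params)
    seg <- track_segments(tr, params$max_gap_bp)
    expect_identical(pc$peak_probes,
                     brute_force_peak_probes(v, seg, pct, w, mh))
  }
})

test_that("raising the percentile never increases the peak-probe count", {
  set.seed(11)
  tr <- toy_track(matrix(rnorm(2000), ncol = 1L))
  counts <- vapply(c(50, 70, 90, 95, 99), function(p) {
    sum(call_peaks(tr, 1L, peak_call_params(percentile = p))$peak_probes)
  }, numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("probes are classified strand-aware into the five regions", {
  genes <- data.frame(
    chrom = "chr1",
    start = c(10000L, 40000L),
    end = c(20000L, 50000L),
    strand = c("+", "-"),
    gene_id = c("gA", "gB"),
    stringsAsFactors = FALSE
  )
  # gA TSS = 10000 (+); gB TSS = 49999 (-)
  probes <- data.frame(
    chrom = "chr1",
    start = c(9990,            # at gA TSS -> core
              9450,            # 520 bp upstream of gA -> proximal
              8300,            # 1.7 kb upstream -> distal
              15000,           # inside gA body
              30000,           # between genes
              50450,           # 520 bp upstream of gB (right of TSS)
              51500,           # 1.5 kb upstream of gB -> distal
              45000),          # gB body
    stringsAsFactors = FALSE
  )
  probes$end <- probes$start + 20L
  probes <- probes[order(probes$start), ]
  got <- classify_probes(probes, genes)
  expected <- c("promoter_distal", "promoter_proximal", "promoter_core",
                "intra_genic", "inter_genic", "intra_genic",
                "promoter_proximal", "promoter_distal")
  expect_equal(as.character(got), expected)
})

test_that("probes claimed by two genes are excluded", {
  genes <- data.frame(
    chrom = "chr1",
    start = c(1000L, 3000L),
    end = c(5000L, 8000L),   # gB body contains gA... no: overlap region
    strand = c("+", "+"),
    gene_id = c("gA", "gB"),
    stringsAsFactors = FALSE
  )
  # probe at 2500: inside gA body AND in gB promoter proximal
  # (gB TSS = 3000; 2500 is 500 bp upstream)
  probes <- data.frame(chrom = "chr1", start = 2490L, end = 2510L)
  expect_equal(as.character(classify_probes(probes, genes)), "excluded")
  expect_error(classify_probes(probes,
                               transform(genes, end = start)), "end")
})

test_that("every probe gets exactly one category (partition property)", {
  st <- small_study()
  cats <- classify_probes(st$track, st$genome$annotation$genes)
  expect_equal(length(cats), n_probes(st$track))
  expect_false(anyNA(cats))
})

test_that("peak distribution percentages sum to 100", {
  cats <- factor(c(rep("inter_genic", 5), rep("intra_genic", 10),
                   rep("excluded", 2)),
                 levels = c("promoter_core", "promoter_proximal",
                            "promoter_distal", "intra_genic",
                            "inter_genic", "excluded"))
  d <- peak_distribution(cats)
  expect_equal(sum(d$percent), 100, tolerance = 1e-9)
  expect_equal(d$n_used, 15L)
  only_inter <- peak_distribution(factor(rep("inter_genic", 4),
                                         levels = levels(cats)))
  expect_equal(unname(only_inter$percent["inter_genic"]), 100)
})

test_that("CGI peak-probe accounting handles edge cases", {
  tr <- toy_track(matrix(c(0, 0, 5, 5, 0, 0), ncol = 1L))
  peaks <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  genes <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0))
  # no CGIs
  none <- cgi_peak_overlap(tr, peaks, data.frame(chrom = character(0),
                                                 start = integer(0),
                                                 end = integer(0)), genes)
  expect_equal(none$n_cgi_peak_probes, 0L)
  # one CGI covering everything: percent equals peak-probe fraction
  all_cgi <- cgi_peak_overlap(tr, peaks,
                              data.frame(chrom = "chr1", start = 0L,
                                         end = 10000L), genes)
  expect_equal(all_cgi$percent_of_array, 100 * 2 / 6)
  expect_equal(all_cgi$n_orphan, 2L)   # no genes, so the CGI is orphan
})
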