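test_that("genome generation is deterministic and byte-identical on disk", {
  g1 <- build_genome(tiny_spec())
  g2 <- build_genome(tiny_spec())
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  expect_identical(g1$annotation, g2$annotation)
  d1 <- tempfile(); d2 <- tempfile()
  write_genome(g1, d1); write_genome(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("a gene-free spec yields an empty gene table but valid sequence", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length_bp = 2e5,
                                n_genes = 0L, n_enhancers = 4L,
                                n_repeat_blocks_per_class = 3L, seed = 3L)
  g <- build_genome(spec)
  expect_equal(nrow(g$annotation$genes), 0L)
  expect_equal(Biostrings::width(g$sequence), 2e5)
  expect_true(all(Biostrings::letterFrequency(
    g$sequence, "ACGT", as.prob = TRUE) == 1))
})

test_that("invalid genome specs are rejected", {
  expect_error(synthetic_genome_spec(probe_length_bp = 300,
                                     probe_spacing_bp = 250),
               "probe_length_bp")
  expect_error(synthetic_genome_spec(frac_expressed = 1.5), "probabilities")
  expect_error(synthetic_genome_spec(n_chroms = 0), "positive")
  expect_error(tissue_profile("x", global_hmc_frac_of_dG = 2), "fractions")
  expect_error(technique_model("hmedip", gain = 1, noise_sd = -1),
               "noise_sd")
})

test_that("CpG islands are CpG-rich while the background is depleted", {
  g <- tiny_genome()
  ann <- g$annotation
  cgi_seq <- vapply(seq_len(nrow(ann$cgi)), function(i) {
    as.character(Biostrings::subseq(g$sequence[[ann$cgi$chrom[i]]],
                                    ann$cgi$start[i] + 1L, ann$cgi$end[i]))
  }, character(1L))
  expect_gt(mean(cpg_obs_exp(cgi_seq), na.rm = TRUE), 0.6)
  # background windows clear of islands and repeats
  occupied <- bed_to_gr(rbind(ann$cgi[c("chrom", "start", "end")],
                              ann$repeats[c("chrom", "start", "end")]))
  starts <- seq(0L, ann$chrom_lengths[[1L]] - 500L, by = 5000L)
  win <- data.frame(chrom = "chr1", start = starts, end = starts + 500L)
  win <- win[!IRanges::overlapsAny(bed_to_gr(win), occupied), ]
  bg_seq <- vapply(seq_len(nrow(win)), function(i) {
    as.character(Biostrings::subseq(g$sequence[[1L]], win$start[i] + 1L,
                                    win$end[i]))
  }, character(1L))
  expect_lt(mean(cpg_obs_exp(bg_seq), na.rm = TRUE), 0.4)
})

test_that("true modification map follows the tissue architecture", {
  g <- tiny_genome()
  map <- tiny_map()
  ann <- g$annotation
  expect_true(all(map$p_hmc + map$p_mc <= 1 + 1e-12))
  # map mean matches the tissue global level (exactly, by scaling)
  expect_equal(mean(map$p_hmc), 0.007, tolerance = 1e-6)
  # CpG positions really are CG dinucleotides
  idx <- sample(nrow(map), 50L)
  two <- vapply(idx, function(i) {
    as.character(Biostrings::subseq(g$sequence[[map$chrom[i]]],
                                    map$pos[i] + 1L, map$pos[i] + 2L))
  }, character(1L))
  expect_true(all(two == "CG"))
  # TSS depletion at expressed genes
  expressed <- ann$genes[ann$genes$gene_id %in%
                           tiny_tissue()$expressed_genes, ]
  tss <- gene_tss(expressed)
  pt <- bed_to_gr(data.frame(chrom = map$chrom, start = map$pos,
                             end = map$pos + 1L))
  near <- IRanges::overlapsAny(pt, bed_to_gr(
    data.frame(chrom = expressed$chrom, start = pmax(0, tss - 100),
               end = tss + 101)))
  expect_lt(mean(map$p_hmc[near]), 0.2 * mean(map$p_hmc))
  # CGI CpGs are unmethylated
  incgi <- IRanges::overlapsAny(pt, bed_to_gr(ann$cgi))
  expect_lt(mean(map$p_mc[incgi]), 0.05)
})

test_that("brain-like and liver-like maps differ ~10-fold in mean 5hmC", {
  g <- tiny_genome()
  brain <- assign_true_modifications(g, tiny_tissue(g, 0.007), seed = 5L)
  liver <- assign_true_modifications(g, tiny_tissue(g, 0.0007, "liver"),
                                     seed = 6L)
  ratio <- mean(brain$p_hmc) / mean(liver$p_hmc)
  expect_gt(ratio, 7)
  expect_lt(ratio, 13)
})

test_that("a zero-gain pure-noise model yields a white-noise track", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length_bp = 2.5e6,
                                n_genes = 0L, n_enhancers = 0L,
                                n_repeat_blocks_per_class = 0L, seed = 9L)
  g <- build_genome(spec)
  map <- assign_true_modifications(g, tissue_profile("t", 0.007), seed = 1L)
  m <- technique_model("jbp1", gain = 0, noise_sd = 1, tss_artifact = 0)
  tr <- simulate_probe_track(map, g, m, 1L, seed = 2L, tissue_name = "t")
  expect_gte(n_probes(tr), 9999L)
  r1 <- autocorrelation(tr, 1L, max_lag_probes = 1L)$r[2L]
  expect_lt(abs(r1), 0.05)
})

test_that("replicates share truth but draw independent noise", {
  g <- tiny_genome()
  map <- tiny_map()
  m <- default_technique_models()$hmeseal
  tr <- simulate_probe_track(map, g, m, 2L, seed = 4L)
  comp <- technique_signal_components(map, g, m)
  resid <- tr$values - comp$det
  expect_equal(sd(resid[, 1L]), m$noise_sd, tolerance = 0.05)
  expect_lt(abs(cor(resid[, 1L], resid[, 2L])), 0.05)
})

test_that("noiseless regression on signal components recovers the gain", {
  g <- tiny_genome()
  map <- tiny_map()
  for (m in default_technique_models()) {
    m$noise_sd <- 0
    comp <- technique_signal_components(map, g, m)
    fit <- lm(det ~ density + cpg_excess + repeat_add + prox + tss,
              data = comp)
    expect_lt(abs(coef(fit)[["density"]] - m$gain) / m$gain, 0.01)
  }
})

test_that("histone peak sets are consistent with the annotation", {
  g <- tiny_genome()
  tis <- tiny_tissue()
  pk <- simulate_histone_peaks(g$annotation, tis, seed = 7L)
  genes <- g$annotation$genes
  expressed <- genes[genes$gene_id %in% tis$expressed_genes, ]
  silent <- genes[!genes$gene_id %in% tis$expressed_genes, ]
  # every expressed TSS carries H3K4me3
  tssg <- bed_to_gr(data.frame(chrom = expressed$chrom,
                               start = gene_tss(expressed),
                               end = gene_tss(expressed) + 1L))
  expect_true(all(IRanges::overlapsAny(tssg, bed_to_gr(pk$H3K4me3))))
  # enhancers partition exactly into poised + active
  st <- enhancer_states(pk$H3K4me1, pk$H3K27ac, pk$H3K4me3)
  expect_equal(nrow(st$poised) + nrow(st$active),
               nrow(g$annotation$enhancers))
  # silent gene bodies carry no H3K36me3
  if (nrow(silent) && nrow(pk$H3K36me3)) {
    expect_equal(sum(IRanges::overlapsAny(bed_to_gr(pk$H3K36me3),
                                          bed_to_gr(silent))), 0L)
  }
})

test_that("simulated gRES assays follow the restriction-enzyme logic", {
  # fully methylated, no 5hmC: MspI cut in both branches, HpaII intact
  a <- simulate_gres_ct(c(0, 1, 0), ct_uncut = 28, noise_sd = 0)
  expect_true(all(a$ct[a$enzyme == "MspI"] >= 50))
  expect_equal(a$ct[a$enzyme == "HpaII"], c(28, 28))
  expect_equal(a$ct[a$enzyme == "uncut"], c(28, 28))
  # fully unmodified: every digest cuts
  b <- simulate_gres_ct(c(0, 0, 1), ct_uncut = 28, noise_sd = 0)
  expect_true(all(b$ct[b$enzyme != "uncut"] >= 50))
  expect_true(all(b$ct[b$enzyme == "uncut"] == 28))
  # invalid fractions
  expect_error(simulate_gres_ct(c(0.6, 0.6, 0.2)), "sum")
  expect_error(simulate_gres_ct(c(-0.1, 0.5, 0.6)), "non-negative")
})
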