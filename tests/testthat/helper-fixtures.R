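# Shared fixtures (memoized: built once per test run) and independent
# brute-force oracles used to validate the vectorized implementations.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_spec <- function(seed = 101L) {
  synthetic_genome_spec(n_chroms = 1L, chrom_length_bp = 6e5,
                        n_genes = 14L, n_enhancers = 6L,
                        n_repeat_blocks_per_class = 6L, seed = seed)
}

tiny_genome <- function() memo("tiny_genome", function() {
  build_genome(tiny_spec())
})

tiny_tissue <- function(genome = tiny_genome(), level = 0.007,
                        name = "brain") {
  genes <- genome$annotation$genes
  tissue_profile(name, level, 0.045,
                 genes$gene_id[genes$expression == "expressed"])
}

tiny_map <- function() memo("tiny_map", function() {
  assign_true_modifications(tiny_genome(), tiny_tissue(), seed = 5L)
})

# a small complete study (1 chromosome, ~8k probes)
small_study <- function() memo("small_study", function() {
  simulate_study(
    synthetic_genome_spec(n_chroms = 1L, chrom_length_bp = 2e6,
                          n_genes = 60L, n_enhancers = 20L,
                          n_repeat_blocks_per_class = 30L),
    seed = 11L
  )
})

# quick single-chromosome track over an explicit value matrix
toy_track <- function(values, spacing = 250L, len = 60L, chrom = "chr1",
                      start0 = 0L, samples = NULL) {
  values <- as.matrix(values)
  starts <- start0 + spacing * (seq_len(nrow(values)) - 1L)
  probe_track(data.frame(chrom = chrom, start = starts,
                         end = starts + len), values, samples)
}

# track with explicit probe starts (for gap scenarios)
gap_track <- function(starts, values, len = 60L, chrom = "chr1") {
  probe_track(data.frame(chrom = chrom, start = starts,
                         end = starts + len), as.matrix(values))
}

# ---------------------------------------------------------------------------
# oracles

# O(n*w) enumeration of the percentile sliding-window peak caller
brute_force_peak_probes <- function(values, seg, percentile, w, min_hits) {
  thr <- unname(quantile(values, percentile / 100, type = 7))
  n <- length(values)
  peak <- logical(n)
  if (n >= w) {
    for (i in seq_len(n - w + 1L)) {
      idx <- i:(i + w - 1L)
      if (seg[i] != seg[i + w - 1L]) next
      if (sum(values[idx] >= thr) >= min_hits) peak[idx] <- TRUE
    }
  }
  peak
}

# per-probe run scan for bias regions: flag probes lying in a maximal run
# of >= min_probes consecutive same-segment probes beyond the threshold,
# spanning >= min_region_bp
brute_force_bias_intervals <- function(track, flag, seg, min_probes,
                                       min_region_bp) {
  n <- length(flag)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (!flag[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && flag[j + 1L] && seg[j + 1L] == seg[j]) j <- j + 1L
    span <- track$probes$end[j] - track$probes$start[i]
    if ((j - i + 1L) >= min_probes && span >= min_region_bp) {
      out <- rbind(out, data.frame(chrom = track$probes$chrom[i],
                                   start = track$probes$start[i],
                                   end = track$probes$end[j]))
    }
    i <- j + 1L
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  }
  out
}

# exact two-sided Wilcoxon rank-sum p by full enumeration (tie-free input)
wilcoxon_exact_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  ws <- colSums(matrix(ranks[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  # the null is symmetric around mu, so the mass at |W - mu| >= |w - mu|
  # is exactly the two-sided p-value
  mu <- n1 * n2 / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# per-bp membership set difference oracle for interval subtraction
bp_setdiff_oracle <- function(target, others, chrom_len = 10000L) {
  inset <- function(df) {
    v <- logical(chrom_len)
    for (i in seq_len(nrow(df))) {
      if (df$end[i] > df$start[i]) {
        v[(df$start[i] + 1L):df$end[i]] <- TRUE
      }
    }
    v
  }
  v <- inset(target)
  for (o in others) v <- v & !inset(o)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}
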