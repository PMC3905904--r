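#' Specification of a synthetic genome
#'
#' Parameters controlling the synthetic genome, its annotation and the tiled
#' probe layout. The defaults give a desk-scale study — 2 chromosomes of
#' 5 Mb, 200 genes, ~40k probes at 250 bp spacing — large enough for stable
#' percentile thresholds while remaining fast to simulate. The 250 bp
#' spacing makes 40 probes span roughly 10 kb, the distance scale used by
#' the autocorrelation diagnostics.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param n_genes Total number of genes (0 allowed).
#' @param frac_expressed Fraction of genes in the reference "expressed"
#'   class.
#' @param cgi_per_gene_prob Probability that a gene carries a promoter CpG
#'   island.
#' @param n_enhancers Number of intergenic enhancer elements.
#' @param n_repeat_blocks_per_class Repeat blocks generated for each class.
#' @param repeat_classes Repeat class labels. Simple classes (`CA_simple`,
#'   `TC_simple`, `other_simple`) are written as literal tandem motifs;
#'   interspersed classes (Line1, LTR, SINE) tile a per-class random
#'   consensus.
#' @param probe_spacing_bp Distance between consecutive probe starts.
#' @param probe_length_bp Probe length; must not exceed the spacing.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chroms = 2L,
                                  chrom_length_bp = 5e6,
                                  n_genes = 200L,
                                  frac_expressed = 0.5,
                                  cgi_per_gene_prob = 0.7,
                                  n_enhancers = 60L,
                                  n_repeat_blocks_per_class = 250L,
                                  repeat_classes = c("Line1", "LTR", "SINE",
                                                     "CA_simple", "TC_simple",
                                                     "other_simple"),
                                  probe_spacing_bp = 250L,
                                  probe_length_bp = 60L,
                                  seed = 1L) {
  spec <- list(
    n_chroms = as.integer(n_chroms),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_genes = as.integer(n_genes),
    frac_expressed = frac_expressed,
    cgi_per_gene_prob = cgi_per_gene_prob,
    n_enhancers = as.integer(n_enhancers),
    n_repeat_blocks_per_class = as.integer(n_repeat_blocks_per_class),
    repeat_classes = repeat_classes,
    probe_spacing_bp = as.integer(probe_spacing_bp),
    probe_length_bp = as.integer(probe_length_bp),
    seed = as.integer(seed)
  )
  if (spec$n_chroms < 1L || spec$chrom_length_bp < 1L) {
    stop("chromosome counts and lengths must be positive")
  }
  if (spec$n_genes < 0L) stop("n_genes must be >= 0")
  if (spec$probe_length_bp > spec$probe_spacing_bp ||
      spec$probe_spacing_bp > spec$chrom_length_bp) {
    stop("require probe_length_bp <= probe_spacing_bp <= chrom_length_bp")
  }
  probs <- c(spec$frac_expressed, spec$cgi_per_gene_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(spec, class = "genome_spec")
}

#' Tissue profile: global modification levels and expressed-gene set
#'
#' The two default profiles mirror mouse whole brain (high 5hmC, 0.7% of dG)
#' and liver (low, 0.07% of dG); 5mC is comparable between tissues at 4.5%
#' of dG.
#'
#' @param name Tissue label.
#' @param global_hmc_frac_of_dG Global 5hmC level as a fraction of dG;
#'   the true-modification map is scaled so that the mean per-CpG 5hmC
#'   probability equals this value.
#' @param global_mc_frac_of_dG Global 5mC level (fraction of dG).
#' @param expressed_genes Character vector of gene ids expressed in this
#'   tissue.
#' @return An object of class `tissue_profile`.
#' @export
tissue_profile <- function(name,
                           global_hmc_frac_of_dG = 0.007,
                           global_mc_frac_of_dG = 0.045,
                           expressed_genes = character(0)) {
  if (global_hmc_frac_of_dG < 0 || global_hmc_frac_of_dG > 1 ||
      global_mc_frac_of_dG < 0 || global_mc_frac_of_dG > 1) {
    stop("global modification fractions must lie in [0, 1]")
  }
  structure(list(name = name,
                 global_hmc_frac_of_dG = global_hmc_frac_of_dG,
                 global_mc_frac_of_dG = global_mc_frac_of_dG,
                 expressed_genes = as.character(expressed_genes)),
            class = "tissue_profile")
}

#' Technique transfer-function model
#'
#' Parameterizes how an enrichment technique converts local true 5hmC
#' density into an observed probe-level log2(IP/input) signal:
#' gain x density, plus an additive CpG-density term (antibody), additive
#' per-repeat-class biases (antibody), a promoter-proximal boost (chemical
#' capture), a TSS artifact (protein affinity) and Gaussian noise in log2
#' space.
#'
#' @param name One of `"hmedip"`, `"hmeseal"`, `"jbp1"`.
#' @param gain Signal per unit normalized local 5hmC density.
#' @param cpg_bias_coeff Signal per unit CpG observed/expected in excess of
#'   `cpg_reference_oe`.
#' @param cpg_reference_oe Reference CpG o/e below which no CpG bias is
#'   added.
#' @param repeat_bias Named numeric, additive signal per repeat class.
#' @param promoter_proximal_boost Additive signal for probes 100 bp - 1 kb
#'   upstream of a TSS.
#' @param tss_artifact Additive signal for probes within 100 bp of a TSS.
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @param fragment_bp Sonication fragment size: the window over which local
#'   true density and CpG composition are evaluated.
#' @param recovery_ct_offset Typical qPCR cycle offset of enriched material
#'   relative to input (low-recovery techniques take more cycles).
#' @return An object of class `technique_model`.
#' @export
technique_model <- function(name,
                            gain,
                            cpg_bias_coeff = 0,
                            cpg_reference_oe = 0.2,
                            repeat_bias = numeric(0),
                            promoter_proximal_boost = 0,
                            tss_artifact = 0,
                            noise_sd = 0.3,
                            fragment_bp = 300L,
                            recovery_ct_offset = 5) {
  name <- match.arg(name, c("hmedip", "hmeseal", "jbp1"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(name = name, gain = gain,
                 cpg_bias_coeff = cpg_bias_coeff,
                 cpg_reference_oe = cpg_reference_oe,
                 repeat_bias = repeat_bias,
                 promoter_proximal_boost = promoter_proximal_boost,
                 tss_artifact = tss_artifact,
                 noise_sd = noise_sd,
                 fragment_bp = as.integer(fragment_bp),
                 recovery_ct_offset = recovery_ct_offset),
            class = "technique_model")
}

#' Default technique models
#'
#' Antibody enrichment (hmeDIP) carries a CpG-density bias plus additive
#' biases over Line1 and simple tandem repeats and a higher noise floor;
#' chemical capture (hMeSeal) has the lowest noise and a promoter-proximal
#' elevation; JBP-1 protein affinity has near-zero gain (noise-dominated)
#' with a spurious signal directly over TSSs. All techniques read local
#' density through the same 300 bp sonication fragment window.
#'
#' @return Named list of `technique_model` objects.
#' @export
default_technique_models <- function() {
  list(
    hmedip = technique_model(
      "hmedip", gain = 0.8,
      cpg_bias_coeff = 1.8, cpg_reference_oe = 0.15,
      repeat_bias = c(Line1 = 1.3, LTR = 0.6, SINE = 0.3,
                      CA_simple = 1.4, TC_simple = 1.4, other_simple = 1.3),
      noise_sd = 0.45, fragment_bp = 300L, recovery_ct_offset = 3
    ),
    hmeseal = technique_model(
      "hmeseal", gain = 0.9,
      promoter_proximal_boost = 0.4,
      noise_sd = 0.22, fragment_bp = 300L, recovery_ct_offset = 6
    ),
    jbp1 = technique_model(
      "jbp1", gain = 0.03,
      tss_artifact = 0.9,
      noise_sd = 0.45, fragment_bp = 300L, recovery_ct_offset = 18
    )
  )
}

# ---------------------------------------------------------------------------
# genome construction

# sample placement of non-overlapping blocks in free space, avoiding a set
# of occupied intervals (data frame chrom/start/end); returns placed blocks.
place_blocks <- function(chrom_lengths, lengths, occupied, margin = 0L,
                         max_tries = 50L) {
  chroms <- names(chrom_lengths)
  occ_gr <- if (nrow(occupied)) {
    bed_to_gr(data.frame(chrom = occupied$chrom,
                         start = pmax(0L, occupied$start - margin),
                         end = occupied$end + margin))
  } else {
    GenomicRanges::GRanges()
  }
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1L)
      maxs <- chrom_lengths[[ch]] - len
      if (maxs <= 0) next
      st <- floor(runif(1L, 0, maxs))
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st + 1L,
                                                          st + len))
      if (length(occ_gr) == 0L ||
          !any(IRanges::overlapsAny(cand, occ_gr))) {
        out[[i]] <- data.frame(chrom = ch, start = st, end = st + len,
                               stringsAsFactors = FALSE)
        occ_gr <- c(occ_gr, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place a feature block of length ", len,
                      "; genome too crowded")
  }
  do.call(rbind, out)
}

#' Build a synthetic genome and its annotation
#'
#' Generates per-chromosome nucleotide sequence with a CpG-depleted
#' background (most background CpGs are deaminated to TpG), CpG-enriched
#' islands at flagged promoters plus a set of orphan (non-promoter)
#' islands, literal simple tandem repeat blocks ((CA)n, (TC)n, ...) and
#' consensus-tiled interspersed repeats, non-overlapping genes with strand
#' and an expression class, and intergenic enhancer elements. Fully
#' deterministic given the spec (including its seed).
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list of class `synthetic_genome` with elements `sequence`
#'   (a [Biostrings::DNAStringSet]), `annotation` (class
#'   `genome_annotation`: chromosome lengths, gene/CGI/repeat/enhancer
#'   tables and probe-layout parameters) and `spec`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chroms))
    L <- spec$chrom_length_bp
    chrom_lengths <- setNames(rep(L, spec$n_chroms), chroms)

    ## genes: lay out sequentially per chromosome with random gaps
    genes <- NULL
    if (spec$n_genes > 0L) {
      per <- diff(round(seq(0, spec$n_genes, length.out = spec$n_chroms + 1)))
      gl <- list()
      gid <- 1L
      for (ci in seq_along(chroms)) {
        ng <- per[ci]
        if (ng == 0L) next
        lens <- round(runif(ng, 5000, 30000))
        gaps <- round(runif(ng + 1L, 3000, 40000))
        total <- sum(lens) + sum(gaps)
        budget <- floor(0.95 * L)
        if (total > budget) {
          avail <- budget - sum(lens)
          if (avail < (ng + 1L) * 2500) {
            stop("genes exceed chromosome bounds on ", chroms[ci],
                 ": need ", total, " bp of ", L)
          }
          gaps <- pmax(2500, round(gaps * avail / sum(gaps)))
        }
        starts <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0, lens[-ng]))
        ends <- starts + lens
        if (any(ends > L)) {
          stop("genes exceed chromosome bounds on ", chroms[ci])
        }
        gl[[ci]] <- data.frame(
          chrom = chroms[ci], start = starts, end = ends,
          strand = sample(c("+", "-"), ng, replace = TRUE),
          gene_id = sprintf("gene%04d", seq(gid, gid + ng - 1L)),
          stringsAsFactors = FALSE
        )
        gid <- gid + ng
      }
      genes <- do.call(rbind, gl)
      expressed <- sample(genes$gene_id,
                          round(spec$frac_expressed * nrow(genes)))
      genes$expression <- ifelse(genes$gene_id %in% expressed,
                                 "expressed", "silent")
    } else {
      genes <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          gene_id = character(0), expression = character(0),
                          stringsAsFactors = FALSE)
    }
    rownames(genes) <- NULL

    ## promoter CGIs: 800 bp upstream to 200 bp downstream of the TSS
    cgi <- NULL
    if (nrow(genes)) {
      has_cgi <- runif(nrow(genes)) < spec$cgi_per_gene_prob
      gg <- genes[has_cgi, , drop = FALSE]
      if (nrow(gg)) {
        tss <- ifelse(gg$strand == "+", gg$start, gg$end - 1L)
        # islands straddle the TSS, centred slightly into the gene
        cs <- ifelse(gg$strand == "+", tss - 300L, tss - 700L)
        ce <- cs + 1000L
        cs <- pmax(0L, as.integer(cs))
        ce <- pmin(L, as.integer(ce))
        cgi <- data.frame(chrom = gg$chrom, start = cs, end = ce,
                          cgi_id = paste0("cgi_", gg$gene_id),
                          type = "promoter", stringsAsFactors = FALSE)
      }
    }
    ## orphan CGIs placed away from genes
    n_orphan <- max(0L, round(0.3 * spec$n_genes))
    occupied <- rbind(
      if (nrow(genes)) genes[c("chrom", "start", "end")] else NULL,
      if (!is.null(cgi)) cgi[c("chrom", "start", "end")] else NULL
    )
    if (is.null(occupied)) {
      occupied <- data.frame(chrom = character(0), start = integer(0),
                             end = integer(0))
    }
    if (n_orphan > 0L) {
      orph <- place_blocks(chrom_lengths, rep(1000L, n_orphan), occupied,
                           margin = 2500L)
      orph$cgi_id <- sprintf("cgi_orphan%03d", seq_len(n_orphan))
      orph$type <- "orphan"
      cgi <- rbind(cgi, orph)
      occupied <- rbind(occupied, orph[c("chrom", "start", "end")])
    }
    if (is.null(cgi)) {
      cgi <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), cgi_id = character(0),
                        type = character(0), stringsAsFactors = FALSE)
    }
    cgi <- cgi[order(match(cgi$chrom, chroms), cgi$start), ]
    rownames(cgi) <- NULL

    ## intermediate-CpG-content (ICP) patches inside some gene bodies:
    ## CpG-denser than bulk sequence but well below island density
    icp <- NULL
    if (nrow(genes)) {
      for (gi in seq_len(nrow(genes))) {
        if (runif(1L) >= 0.3) next
        glen <- genes$end[gi] - genes$start[gi]
        if (glen < 4000L) next
        np <- sample(2:4, 1L)
        for (k in seq_len(np)) {
          plen <- round(runif(1L, 300, 500))
          ps <- genes$start[gi] +
            floor(runif(1L, 1000, glen - 1000 - plen))
          icp <- rbind(icp, data.frame(chrom = genes$chrom[gi],
                                       start = as.integer(ps),
                                       end = as.integer(ps + plen),
                                       stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(icp)) {
      icp <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    }

    ## enhancers: intergenic, kept clear of promoters (>= 3 kb from genes)
    enhancers <- if (spec$n_enhancers > 0L) {
      e <- place_blocks(chrom_lengths,
                        round(runif(spec$n_enhancers, 800, 1500)),
                        occupied, margin = 3000L)
      e$enhancer_id <- sprintf("enh%03d", seq_len(spec$n_enhancers))
      e
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 enhancer_id = character(0), stringsAsFactors = FALSE)
    }
    occupied <- rbind(occupied, enhancers[c("chrom", "start", "end")])
    enhancers <- enhancers[order(match(enhancers$chrom, chroms),
                                 enhancers$start), ]
    rownames(enhancers) <- NULL

    ## repeat blocks, intergenic
    rep_len_range <- list(Line1 = c(2000, 4000), LTR = c(600, 1200),
                          SINE = c(150, 300), CA_simple = c(300, 600),
                          TC_simple = c(300, 600), other_simple = c(300, 600))
    repeats <- NULL
    for (cls in spec$repeat_classes) {
      rng <- rep_len_range[[cls]] %||% c(300, 600)
      nl <- spec$n_repeat_blocks_per_class
      if (nl == 0L) next
      lens <- round(runif(nl, rng[1], rng[2]))
      blk <- place_blocks(chrom_lengths, lens, occupied, margin = 500L)
      blk$class <- cls
      repeats <- rbind(repeats, blk)
      occupied <- rbind(occupied, blk[c("chrom", "start", "end")])
    }
    if (is.null(repeats)) {
      repeats <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), class = character(0),
                            stringsAsFactors = FALSE)
    }
    repeats <- repeats[order(match(repeats$chrom, chroms), repeats$start), ]
    rownames(repeats) <- NULL

    ## per-class consensus for interspersed repeats; aged repeats are
    ## CpG-poor, so consensus CpGs are largely deaminated too
    deplete_cpg <- function(s, rate = 0.8) {
      x <- strsplit(s, "")[[1L]]
      cgp <- which(x[-length(x)] == "C" & x[-1L] == "G")
      hit <- cgp[runif(length(cgp)) < rate]
      x[hit] <- "T"
      paste(x, collapse = "")
    }
    consensus <- list(
      Line1 = deplete_cpg(paste(sample(c("A", "C", "G", "T"), 300,
        replace = TRUE, prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")),
      LTR = deplete_cpg(paste(sample(c("A", "C", "G", "T"), 200,
        replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")),
      SINE = deplete_cpg(paste(sample(c("A", "C", "G", "T"), 120,
        replace = TRUE, prob = c(0.25, 0.25, 0.25, 0.25)), collapse = ""))
    )
    other_motifs <- c("GATA", "AAG", "CAG", "ATTT")

    ## assemble sequence per chromosome
    seqs <- character(spec$n_chroms)
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      x <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
      # CpG depletion of the background: deaminate ~85% of CpG cytosines
      is_cg <- which(x[-L] == "C" & x[-1L] == "G")
      dea <- is_cg[runif(length(is_cg)) < 0.85]
      x[dea] <- "T"
      # CpG islands: GC-rich, undepleted
      for (j in which(cgi$chrom == ch)) {
        idx <- (cgi$start[j] + 1L):cgi$end[j]
        x[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE,
                         prob = c(0.2, 0.3, 0.3, 0.2))
      }
      # ICP patches: moderately CpG-enriched, partially depleted
      for (j in which(icp$chrom == ch)) {
        idx <- (icp$start[j] + 1L):icp$end[j]
        p <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE,
                    prob = c(0.25, 0.25, 0.25, 0.25))
        pcg <- which(p[-length(p)] == "C" & p[-1L] == "G")
        p[pcg[runif(length(pcg)) < 0.4]] <- "T"
        x[idx] <- p
      }
      # repeat blocks: literal motifs / tiled consensus
      for (j in which(repeats$chrom == ch)) {
        idx <- (repeats$start[j] + 1L):repeats$end[j]
        cls <- repeats$class[j]
        unit <- switch(cls,
                       CA_simple = "CA",
                       TC_simple = "TC",
                       other_simple = other_motifs[1L + (j %% length(other_motifs))],
                       consensus[[cls]] %||% consensus$SINE)
        tile <- strsplit(strrep(unit, ceiling(length(idx) / nchar(unit))),
                         "")[[1L]][seq_along(idx)]
        x[idx] <- tile
      }
      seqs[ci] <- paste(x, collapse = "")
    }
    sequence <- Biostrings::DNAStringSet(seqs)
    names(sequence) <- chroms

    ## bounds check on all features
    feats <- rbind(genes[c("chrom", "start", "end")],
                   icp[c("chrom", "start", "end")],
                   cgi[c("chrom", "start", "end")],
                   repeats[c("chrom", "start", "end")],
                   enhancers[c("chrom", "start", "end")])
    if (nrow(feats) &&
        any(feats$end > chrom_lengths[feats$chrom] | feats$start < 0)) {
      bad <- which(feats$end > chrom_lengths[feats$chrom] | feats$start < 0)[1]
      stop("feature exceeds chromosome bounds: ", feats$chrom[bad], ":",
           feats$start[bad], "-", feats$end[bad])
    }

    annotation <- structure(
      list(chrom_lengths = chrom_lengths, genes = genes, cgi = cgi,
           repeats = repeats, enhancers = enhancers, icp = icp,
           probe_spacing_bp = spec$probe_spacing_bp,
           probe_length_bp = spec$probe_length_bp),
      class = "genome_annotation"
    )
    structure(list(sequence = sequence, annotation = annotation,
                   spec = spec),
              class = "synthetic_genome")
  })
}

#' TSS coordinates of a gene table (0-based)
#' @param genes Gene table with `start`, `end`, `strand`.
#' @return Numeric vector of TSS positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Tile probes across an annotated genome
#' @param annotation A `genome_annotation`.
#' @return data frame of probe intervals (chrom, start, end), sorted.
#' @export
tile_probes <- function(annotation) {
  sp <- annotation$probe_spacing_bp
  pl <- annotation$probe_length_bp
  out <- lapply(names(annotation$chrom_lengths), function(ch) {
    L <- annotation$chrom_lengths[[ch]]
    starts <- seq(0L, L - pl, by = sp)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + pl), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# ground-truth modification map

#' Assign ground-truth 5hmC/5mC probabilities to every CpG
#'
#' Every CG dinucleotide of the generated sequence receives a 5hmC
#' probability shaped by the annotation — elevated in expressed gene bodies
#' and enhancers, zero within 100 bp of any TSS and inside CpG islands, low
#' over repeat blocks — then scaled so its genome-wide mean equals the
#' tissue's global 5hmC level. 5mC is high genome-wide except in CpG
#' islands.
#'
#' @param genome A `synthetic_genome` from [build_genome()].
#' @param tissue A [tissue_profile()]; its `expressed_genes` set defines
#'   which gene bodies carry 5hmC.
#' @param seed Seed for the per-CpG jitter.
#' @return A data frame of class `modification_map` with columns `chrom`,
#'   `pos` (0-based C position), `p_hmc`, `p_mc`.
#' @export
assign_true_modifications <- function(genome, tissue, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(tissue, "tissue_profile"))
  ann <- genome$annotation
  cpg <- do.call(rbind, lapply(names(genome$sequence), function(ch) {
    m <- Biostrings::matchPattern("CG", genome$sequence[[ch]])
    data.frame(chrom = ch, pos = BiocGenerics::start(m) - 1L,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(cpg)
  pt <- points_to_gr(cpg$chrom, cpg$pos)

  shape <- rep(0.15, n)
  mark <- function(df, value) {
    if (!nrow(df)) return()
    hit <- IRanges::overlapsAny(pt, bed_to_gr(df))
    shape[hit] <<- value
  }
  mark(ann$repeats, 0.05)
  expressed <- ann$genes[ann$genes$gene_id %in% tissue$expressed_genes, ,
                         drop = FALSE]
  mark(expressed, 1.0)
  # intermediate-CpG patches: per-CpG modification drops with CpG
  # density, so the summed 5hmC of a patch stays near body level
  if (!is.null(ann$icp)) mark(ann$icp, 0.15)
  mark(ann$enhancers, 1.2)
  mark(ann$cgi, 0)
  if (nrow(ann$genes)) {
    tss <- gene_tss(ann$genes)
    mark(data.frame(chrom = ann$genes$chrom,
                    start = pmax(0, tss - 100), end = tss + 101), 0)
  }

  with_seed(seed, {
    jitter <- runif(n, 0.7, 1.3)
  })
  p_hmc <- shape * jitter
  mh <- mean(p_hmc)
  if (mh > 0) p_hmc <- p_hmc * tissue$global_hmc_frac_of_dG / mh
  p_hmc <- pmin(p_hmc, 0.95)

  p_mc <- rep(0.85, n)
  if (nrow(ann$cgi)) {
    p_mc[IRanges::overlapsAny(pt, bed_to_gr(ann$cgi))] <- 0.01
  }
  p_mc <- pmin(p_mc, 1 - p_hmc)

  structure(data.frame(chrom = cpg$chrom, pos = cpg$pos,
                       p_hmc = p_hmc, p_mc = p_mc,
                       stringsAsFactors = FALSE),
            class = c("modification_map", "data.frame"),
            tissue = tissue$name)
}

#' Local true 5hmC density around probe midpoints
#'
#' Sums the per-CpG 5hmC probabilities inside a fragment-size window
#' centered on each probe midpoint. With `normalize = TRUE` (default) the
#' sums are divided by their genome-wide mean over probes, giving a
#' dimensionless density of mean 1 — the quantity a relative-enrichment
#' (IP/input) measurement responds to.
#'
#' @param map A `modification_map`.
#' @param probes Probe table (chrom, start, end) or a `probe_track`.
#' @param window_bp Window width in bp.
#' @param normalize Divide by the mean over probes.
#' @return Numeric vector, one density per probe.
#' @export
local_hmc_density <- function(map, probes, window_bp = 300L,
                              normalize = TRUE) {
  if (inherits(probes, "probe_track")) probes <- probes$probes
  mid <- (probes$start + probes$end) / 2
  half <- window_bp / 2
  win <- GenomicRanges::GRanges(
    probes$chrom,
    IRanges::IRanges(start = pmax(1, floor(mid - half) + 1),
                     end = floor(mid + half))
  )
  pt <- points_to_gr(map$chrom, map$pos)
  hits <- GenomicRanges::findOverlaps(pt, win)
  dens <- numeric(nrow(probes))
  if (length(hits)) {
    agg <- rowsum(map$p_hmc[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits))
    dens[as.integer(rownames(agg))] <- agg[, 1L]
  }
  if (normalize) {
    m <- mean(dens)
    if (m > 0) dens <- dens / m
  }
  dens
}

# per-window CpG observed/expected via cumulative counts; centers 0-based.
window_cpg_oe <- function(sequence, chrom, centers, window_bp,
                          min_count = 1L) {
  oe <- rep(NA_real_, length(centers))
  half <- window_bp / 2
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    s <- sequence[[ch]]
    L <- length(s)
    chars <- strsplit(as.character(s), "")[[1L]]
    cC <- c(0, cumsum(chars == "C"))
    cG <- c(0, cumsum(chars == "G"))
    cgpos <- BiocGenerics::start(Biostrings::matchPattern("CG", s)) # 1-based
    cCG <- c(0, cumsum(tabulate(cgpos, nbins = L)))
    lo <- pmax(1, floor(centers[sel] - half) + 1) # 1-based inclusive
    hi <- pmin(L, floor(centers[sel] + half))
    nC <- cC[hi + 1L] - cC[lo]
    nG <- cG[hi + 1L] - cG[lo]
    nCG <- cCG[pmin(hi, L)] - cCG[lo]
    w <- hi - lo + 1
    val <- ifelse(nC >= max(1L, min_count) & nG >= max(1L, min_count),
                  (nCG * w) / (nC * nG), NA_real_)
    oe[sel] <- val
  }
  oe
}

#' Deterministic components of a technique's probe signal
#'
#' Evaluates, per probe, every term of the technique transfer function:
#' the normalized local 5hmC density, the CpG o/e excess, the
#' repeat-class additive bias, the promoter-proximal and TSS indicator
#' terms, and their sum `det` (the noiseless signal). Exposing the
#' components makes the simulator auditable: regressing `det` on the
#' components recovers the model coefficients exactly.
#'
#' @param map A `modification_map`.
#' @param genome The `synthetic_genome` the map was derived from.
#' @param model A [technique_model()].
#' @return data frame with one row per probe: `density`, `cpg_excess`,
#'   `repeat_add`, `prox`, `tss` and `det`.
#' @export
technique_signal_components <- function(map, genome, model) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(model, "technique_model"))
  ann <- genome$annotation
  probes <- tile_probes(ann)
  mid <- (probes$start + probes$end) / 2
  n <- nrow(probes)

  density <- local_hmc_density(map, probes, window_bp = model$fragment_bp)

  cpg_excess <- numeric(n)
  if (model$cpg_bias_coeff != 0) {
    # composition bias needs a minimally informative window: o/e
    # estimated from a handful of C/G bases (deep inside AT-rich
    # repeats) is noise, not CpG density
    oe <- window_cpg_oe(genome$sequence, probes$chrom, mid,
                        model$fragment_bp, min_count = 10L)
    cpg_excess <- pmax(0, oe - model$cpg_reference_oe)
    cpg_excess[is.na(cpg_excess)] <- 0
  }

  repeat_add <- numeric(n)
  if (length(model$repeat_bias) && nrow(ann$repeats)) {
    pg <- bed_to_gr(probes)
    hits <- GenomicRanges::findOverlaps(pg, bed_to_gr(ann$repeats))
    if (length(hits)) {
      first <- !duplicated(S4Vectors::queryHits(hits))
      q <- S4Vectors::queryHits(hits)[first]
      cls <- ann$repeats$class[S4Vectors::subjectHits(hits)[first]]
      b <- model$repeat_bias[cls]
      b[is.na(b)] <- 0
      repeat_add[q] <- b
    }
  }

  prox <- numeric(n)
  tss_ind <- numeric(n)
  if (nrow(ann$genes)) {
    tss <- gene_tss(ann$genes)
    mp <- points_to_gr(probes$chrom, mid)
    up <- ifelse(ann$genes$strand == "+", tss - 1000, tss + 101)
    dn <- ifelse(ann$genes$strand == "+", tss - 100, tss + 1001)
    prox_reg <- data.frame(chrom = ann$genes$chrom,
                           start = pmax(0, pmin(up, dn)),
                           end = pmax(up, dn))
    prox <- as.numeric(IRanges::overlapsAny(mp, bed_to_gr(prox_reg)))
    core <- data.frame(chrom = ann$genes$chrom,
                       start = pmax(0, tss - 100), end = tss + 101)
    tss_ind <- as.numeric(IRanges::overlapsAny(mp, bed_to_gr(core)))
  }

  det <- model$gain * density +
    model$cpg_bias_coeff * cpg_excess +
    repeat_add +
    model$promoter_proximal_boost * prox +
    model$tss_artifact * tss_ind

  data.frame(density = density, cpg_excess = cpg_excess,
             repeat_add = repeat_add, prox = prox, tss = tss_ind,
             det = det)
}

#' Simulate a technique-specific probe signal track
#'
#' Applies a technique transfer function to the ground-truth modification
#' map: per probe, signal = gain x normalized local 5hmC density (over the
#' technique's fragment-size window) + CpG-density bias + repeat-class bias
#' + promoter-proximal boost + TSS artifact + Gaussian log2 noise.
#' Replicates share the deterministic part and draw independent noise.
#'
#' @param map A `modification_map`.
#' @param genome The `synthetic_genome` the map was derived from (sequence
#'   is needed for the CpG-composition bias).
#' @param model A [technique_model()].
#' @param n_replicates Number of biological replicates to simulate.
#' @param seed Noise seed.
#' @param tissue_name Label recorded in the sample metadata.
#' @return A [probe_track()] with one sample per replicate.
#' @export
simulate_probe_track <- function(map, genome, model, n_replicates = 1L,
                                 seed = 1L, tissue_name = attr(map, "tissue")) {
  comp <- technique_signal_components(map, genome, model)
  probes <- tile_probes(genome$annotation)
  det <- comp$det
  values <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      det + rnorm(length(det), 0, model$noise_sd)
    }, numeric(length(det)))
  })
  samples <- data.frame(
    sample_id = paste(tissue_name %||% "tissue", model$name,
                      seq_len(n_replicates), sep = "_"),
    tissue = tissue_name %||% NA_character_,
    technique = model$name,
    replicate = seq_len(n_replicates),
    stringsAsFactors = FALSE
  )
  probe_track(probes, values, samples)
}

# ---------------------------------------------------------------------------
# histone peaks

jitter_interval <- function(center, half, L) {
  s <- pmax(0, round(center - half * runif(length(center), 0.7, 1.3)))
  e <- pmin(L, round(center + half * runif(length(center), 0.7, 1.3)))
  data.frame(start = as.integer(s), end = as.integer(pmax(e, s + 50L)))
}

#' Simulate chromatin-mark and binding-protein peak sets
#'
#' Builds ENCODE-style peak BED tables from the annotation and the tissue's
#' expressed-gene set: H3K4me3, H3K27ac and RNAPII at expressed promoters;
#' H3K36me3 across expressed gene bodies; H3K4me1 at every enhancer with
#' H3K27ac added at the active subset; H3K27me3 at a subset of silent
#' genes; CTCF at scattered sites.
#'
#' @param annotation A `genome_annotation`.
#' @param tissue A [tissue_profile()].
#' @param seed Seed for peak-boundary jitter and subset draws.
#' @param active_enhancer_frac Fraction of enhancers marked active
#'   (H3K27ac+) in this tissue.
#' @return Named list of BED-like data frames (chrom, start, end, name),
#'   one per mark: H3K4me3, H3K27me3, H3K4me1, H3K27ac, H3K36me3, RNAPII,
#'   CTCF.
#' @export
simulate_histone_peaks <- function(annotation, tissue, seed = 1L,
                                   active_enhancer_frac = 0.4) {
  with_seed(seed, {
    genes <- annotation$genes
    expressed <- genes[genes$gene_id %in% tissue$expressed_genes, ,
                       drop = FALSE]
    silent <- genes[!genes$gene_id %in% tissue$expressed_genes, ,
                    drop = FALSE]
    Lof <- function(ch) annotation$chrom_lengths[ch]
    mk <- function(df, nm) {
      if (is.null(df) || !nrow(df)) {
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          stringsAsFactors = FALSE))
      }
      df$name <- paste0(nm, "_", seq_len(nrow(df)))
      df <- df[order(match(df$chrom, names(annotation$chrom_lengths)),
                     df$start), ]
      rownames(df) <- NULL
      df[c("chrom", "start", "end", "name")]
    }

    tss_e <- gene_tss(expressed)
    k4me3 <- if (nrow(expressed)) {
      cbind(chrom = expressed$chrom,
            jitter_interval(tss_e, 700, Lof(expressed$chrom)))
    } else NULL
    rnapii <- if (nrow(expressed)) {
      cbind(chrom = expressed$chrom,
            jitter_interval(tss_e, 350, Lof(expressed$chrom)))
    } else NULL
    k27ac_prom <- if (nrow(expressed)) {
      cbind(chrom = expressed$chrom,
            jitter_interval(tss_e, 500, Lof(expressed$chrom)))
    } else NULL

    ## gene bodies: 1-3 H3K36me3 peaks spanning most of each expressed body
    k36 <- NULL
    if (nrow(expressed)) {
      pieces <- lapply(seq_len(nrow(expressed)), function(i) {
        len <- expressed$end[i] - expressed$start[i]
        npk <- sample(1:3, 1L)
        edges <- round(seq(expressed$start[i] + 0.05 * len,
                           expressed$end[i] - 0.05 * len,
                           length.out = npk + 1L))
        data.frame(chrom = expressed$chrom[i],
                   start = as.integer(head(edges, -1L)),
                   end = as.integer(tail(edges, -1L) - 1L),
                   stringsAsFactors = FALSE)
      })
      k36 <- do.call(rbind, pieces)
      k36 <- k36[k36$end > k36$start, , drop = FALSE]
    }

    enh <- annotation$enhancers
    k4me1 <- if (nrow(enh)) {
      data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                 stringsAsFactors = FALSE)
    } else NULL
    active_idx <- if (nrow(enh)) {
      sort(sample(nrow(enh), round(active_enhancer_frac * nrow(enh))))
    } else integer(0)
    k27ac_enh <- if (length(active_idx)) {
      e <- enh[active_idx, , drop = FALSE]
      mid <- (e$start + e$end) / 2
      cbind(chrom = e$chrom, jitter_interval(mid, 400, Lof(e$chrom)))
    } else NULL
    k27ac <- rbind(k27ac_prom, k27ac_enh)

    k27me3 <- NULL
    if (nrow(silent)) {
      sub <- silent[runif(nrow(silent)) < 0.4, , drop = FALSE]
      if (nrow(sub)) {
        tss_s <- gene_tss(sub)
        k27me3 <- cbind(chrom = sub$chrom,
                        jitter_interval(tss_s, 1200, Lof(sub$chrom)))
      }
    }

    n_ctcf <- 150L
    ctcf_chrom <- sample(names(annotation$chrom_lengths), n_ctcf,
                         replace = TRUE)
    ctcf_start <- floor(runif(n_ctcf, 0,
                              annotation$chrom_lengths[ctcf_chrom] - 300))
    ctcf <- data.frame(chrom = ctcf_chrom,
                       start = as.integer(ctcf_start),
                       end = as.integer(ctcf_start + 300L),
                       stringsAsFactors = FALSE)

    list(H3K4me3 = mk(k4me3, "H3K4me3"),
         H3K27me3 = mk(k27me3, "H3K27me3"),
         H3K4me1 = mk(k4me1, "H3K4me1"),
         H3K27ac = mk(k27ac, "H3K27ac"),
         H3K36me3 = mk(k36, "H3K36me3"),
         RNAPII = mk(rnapii, "RNAPII"),
         CTCF = mk(ctcf, "CTCF"))
  })
}

# ---------------------------------------------------------------------------
# gRES-qPCR simulation

#' Simulate a gRES-qPCR assay from true modification fractions
#'
#' Applies the enzyme logic of glucosyl-sensitive restriction digestion at
#' a CCGG site: MspI cuts C, 5mC and 5hmC but is blocked by
#' glucosyl-5hmC; HpaII cuts only unmodified C. The intact template
#' fraction of each digest sets its cycle threshold under ideal doubling:
#' Ct = ct_uncut - log2(intact) + noise. A fully cut template yields a
#' no-amplification sentinel Ct.
#'
#' @param fractions Numeric length 3: true (5hmC, 5mC, C) fractions at the
#'   site; must be non-negative and sum to at most 1 (any remainder counts
#'   as unmodified).
#' @param ct_uncut Cycle threshold of the uncut tubes.
#' @param noise_sd Ct noise, in cycles.
#' @param seed Noise seed.
#' @param locus Locus id.
#' @param replicate Replicate id.
#' @param sentinel_ct Ct reported for a fully cut (zero template) reaction.
#' @return A data frame of class `gres_assay` with six rows
#'   (bgt in {"+","-"} x enzyme in {MspI, HpaII, uncut}) and columns
#'   `locus`, `bgt`, `enzyme`, `replicate`, `ct`.
#' @export
simulate_gres_ct <- function(fractions, ct_uncut = 28, noise_sd = 0,
                             seed = 1L, locus = "locus1", replicate = 1L,
                             sentinel_ct = 55) {
  if (length(fractions) != 3L || any(fractions < 0)) {
    stop("`fractions` must be three non-negative values (hmc, mc, c)")
  }
  if (sum(fractions) > 1 + 1e-9) {
    stop("`fractions` must sum to at most 1")
  }
  h <- fractions[1L]
  m <- fractions[2L]
  intact <- c(mspi_plus = h,            # glucosyl-5hmC blocks MspI
              mspi_minus = 0,           # MspI cuts C, 5mC and 5hmC
              hpaii_plus = h + m,       # any modification blocks HpaII
              hpaii_minus = h + m,
              uncut_plus = 1,
              uncut_minus = 1)
  with_seed(seed, {
    noise <- rnorm(6L, 0, noise_sd)
  })
  ct <- ifelse(intact <= 0, sentinel_ct,
               ct_uncut - log2(intact) + noise)
  ct <- pmin(ct, sentinel_ct)
  structure(
    data.frame(locus = locus,
               bgt = rep(c("+", "-"), 3L),
               enzyme = rep(c("MspI", "HpaII", "uncut"), each = 2L),
               replicate = replicate,
               ct = as.numeric(ct[c("mspi_plus", "mspi_minus",
                                    "hpaii_plus", "hpaii_minus",
                                    "uncut_plus", "uncut_minus")]),
               stringsAsFactors = FALSE),
    class = c("gres_assay", "data.frame")
  )
}

# ---------------------------------------------------------------------------
# whole-study convenience

#' Simulate the default comparative enrichment study
#'
#' Builds the synthetic genome, two tissue profiles (brain-like: 0.7% of
#' dG; liver-like: 0.07% of dG; half the expressed genes shared), their
#' ground-truth modification maps, probe tracks for antibody and chemical
#' capture (2 biological replicates per tissue) plus a single brain-like
#' protein-affinity sample, and per-tissue chromatin peak sets.
#'
#' @param spec A [synthetic_genome_spec()]; its seed is replaced by `seed`.
#' @param models Technique models, default [default_technique_models()].
#' @param n_replicates Biological replicates per tissue/technique.
#' @param seed Master seed for the whole study.
#' @return List of class `hmc_study` with elements `genome`, `tissues`,
#'   `maps`, `track` (all samples combined), `models`, `histone`
#'   (per-tissue peak lists) and `seed`.
#' @export
simulate_study <- function(spec = synthetic_genome_spec(),
                           models = default_technique_models(),
                           n_replicates = 2L,
                           seed = 1L) {
  spec$seed <- as.integer(seed)
  genome <- build_genome(spec)
  genes <- genome$annotation$genes$gene_id

  n_e <- round(spec$frac_expressed * length(genes))
  sets <- with_seed(child_seed(seed, 1L), {
    brain <- sample(genes, n_e)
    shared <- sample(brain, round(n_e / 2))
    rest <- setdiff(genes, brain)
    liver <- c(shared, sample(rest, min(length(rest), n_e - length(shared))))
    list(brain = brain, liver = liver)
  })
  tissues <- list(
    brain = tissue_profile("brain", 0.007, 0.045, sets$brain),
    liver = tissue_profile("liver", 0.0007, 0.045, sets$liver)
  )
  maps <- list(
    brain = assign_true_modifications(genome, tissues$brain,
                                      seed = child_seed(seed, 2L)),
    liver = assign_true_modifications(genome, tissues$liver,
                                      seed = child_seed(seed, 3L))
  )
  tracks <- list(
    simulate_probe_track(maps$brain, genome, models$hmedip, n_replicates,
                         seed = child_seed(seed, 11L)),
    simulate_probe_track(maps$brain, genome, models$hmeseal, n_replicates,
                         seed = child_seed(seed, 12L)),
    simulate_probe_track(maps$liver, genome, models$hmedip, n_replicates,
                         seed = child_seed(seed, 13L)),
    simulate_probe_track(maps$liver, genome, models$hmeseal, n_replicates,
                         seed = child_seed(seed, 14L)),
    simulate_probe_track(maps$brain, genome, models$jbp1, 1L,
                         seed = child_seed(seed, 15L))
  )
  track <- do.call(cbind_tracks, tracks)
  histone <- list(
    brain = simulate_histone_peaks(genome$annotation, tissues$brain,
                                   seed = child_seed(seed, 21L)),
    liver = simulate_histone_peaks(genome$annotation, tissues$liver,
                                   seed = child_seed(seed, 22L))
  )
  structure(list(genome = genome, tissues = tissues, maps = maps,
                 track = track, models = models, histone = histone,
                 seed = seed),
            class = "hmc_study")
}
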