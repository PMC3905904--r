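#' Pipeline configuration
#'
#' Collects every stage's parameters for [run_pipeline()]. Any field can
#' be overridden; the defaults reproduce the default synthetic
#' comparative study.
#'
#' @param seed Master seed, recorded in all outputs.
#' @param outdir Output directory.
#' @param genome_spec A [synthetic_genome_spec()].
#' @param models Technique models.
#' @param n_replicates Biological replicates per tissue/technique.
#' @param peak_params A [peak_call_params()].
#' @param bias_params A [bias_region_params()].
#' @param metagene A [metagene_params()].
#' @param n_random_probes Probes sampled for correlation clustering.
#' @param max_lag_probes Autocorrelation depth in probes.
#' @param gres_loci Named list of true (5hmC, 5mC, C) fraction triples for
#'   the gRES-qPCR validation stage.
#' @param gres_noise_sd Ct noise of the simulated assays (cycles).
#' @param write_tracks Also write every sample as bedGraph.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("hmc_run_"),
                            genome_spec = synthetic_genome_spec(),
                            models = default_technique_models(),
                            n_replicates = 2L,
                            peak_params = peak_call_params(),
                            bias_params = bias_region_params(),
                            metagene = metagene_params(),
                            n_random_probes = 500000L,
                            max_lag_probes = 40L,
                            gres_loci = list(
                              cgi_control = c(0.01, 0.02, 0.97),
                              repeat_locus = c(0.03, 0.60, 0.37),
                              genic_locus = c(0.20, 0.50, 0.30)),
                            gres_noise_sd = 0.15,
                            write_tracks = FALSE) {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 genome_spec = genome_spec, models = models,
                 n_replicates = as.integer(n_replicates),
                 peak_params = peak_params, bias_params = bias_params,
                 metagene = metagene,
                 n_random_probes = as.integer(n_random_probes),
                 max_lag_probes = as.integer(max_lag_probes),
                 gres_loci = gres_loci, gres_noise_sd = gres_noise_sd,
                 write_tracks = write_tracks),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparative study end to end
#'
#' simulate -> normalize -> average replicates -> peak calling ->
#' genomic/CGI annotation -> correlation clustering & autocorrelation ->
#' metagene profiling -> technique-bias detection, repeat statistics and
#' fragment CpG composition -> chromatin-state overlap -> gRES-qPCR
#' quantification. All intermediate artifacts are written to
#' `config$outdir` in standard formats and a machine-readable summary
#' (JSON, including seed and parameters) is written as `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed,
                  package_version = as.character(
                    utils::packageVersion("hmcompare")),
                  genome_spec = unclass(config$genome_spec))

  study <- pipeline_stage("simulate", {
    simulate_study(config$genome_spec, config$models,
                   config$n_replicates, seed = config$seed)
  })
  ann <- study$genome$annotation

  norm <- pipeline_stage("normalize", {
    suppressMessages(normalize_track(study$track))
  })
  avg <- pipeline_stage("average", average_replicates(norm))
  if (config$write_tracks) {
    for (sid in norm$samples$sample_id) {
      write_bedgraph(norm, sid,
                     file.path(config$outdir, paste0(sid, ".bedGraph")))
    }
  }

  calls <- pipeline_stage("callpeaks", {
    out <- lapply(avg$samples$sample_id, function(sid) {
      call_peaks(avg, sid, config$peak_params)
    })
    names(out) <- avg$samples$sample_id
    out
  })
  for (sid in names(calls)) {
    write_bed(calls[[sid]]$peaks,
              file.path(config$outdir, paste0("peaks_", sid, ".bed")))
  }
  summary$peaks <- lapply(calls, function(pc) {
    list(n_peak_probes = sum(pc$peak_probes),
         n_peaks = nrow(pc$peaks), threshold = pc$threshold)
  })

  annot <- pipeline_stage("annotate", {
    cats <- classify_probes(avg, ann$genes)
    lapply(calls, function(pc) {
      cgi <- cgi_peak_overlap(avg, pc$peak_probes, ann$cgi, ann$genes)
      used <- cats[pc$peak_probes]
      if (any(used != "excluded")) {
        dist <- peak_distribution(used)
        list(distribution = as.list(dist$percent), n_used = dist$n_used,
             cgi_peak_probes = cgi$n_cgi_peak_probes,
             cgi_percent_of_array = cgi$percent_of_array)
      } else {
        list(distribution = NULL, n_used = 0L,
             cgi_peak_probes = cgi$n_cgi_peak_probes,
             cgi_percent_of_array = cgi$percent_of_array)
      }
    })
  })
  summary$annotation <- annot

  clust <- pipeline_stage("cluster", {
    suppressMessages(
      correlation_cluster(norm, config$n_random_probes,
                          seed = child_seed(config$seed, 31L)))
  })
  writeLines(clust$newick, file.path(config$outdir, "dendrogram.nwk"))
  write.table(round(clust$cor, 6), file.path(config$outdir, "cor.tsv"),
              sep = "\t", quote = FALSE)
  summary$correlation <- as.list(as.data.frame(clust$cor))

  autoc <- pipeline_stage("autocorr", {
    ids <- avg$samples$sample_id
    rnd <- randomize_track(avg, seed = child_seed(config$seed, 32L))
    out <- lapply(ids, function(sid) {
      autocorrelation(avg, sid, config$max_lag_probes)$r
    })
    names(out) <- ids
    out$randomized <- autocorrelation(
      rnd, avg$samples$sample_id[1L], config$max_lag_probes)$r
    out
  })
  summary$autocorr_lag1 <- lapply(autoc, `[`, 2L)

  prof <- pipeline_stage("profile", {
    out <- lapply(avg$samples$sample_id, function(sid) {
      metagene_profile(avg, sid, ann$genes, config$metagene)
    })
    names(out) <- avg$samples$sample_id
    out
  })
  ptab <- do.call(cbind, c(list(prof[[1L]][c("bin", "zone", "position")]),
                           lapply(prof, `[[`, "mean_signal")))
  write.table(ptab, file.path(config$outdir, "metagene.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  bias <- pipeline_stage("diffbias", {
    out <- list()
    for (tis in names(study$tissues)) {
      seal <- select_samples(avg, paste0(tis, "_hmeseal"))
      dip <- select_samples(avg, paste0(tis, "_hmedip"))
      dl <- delta_track(seal, dip)
      reg <- find_bias_regions(dl, config$bias_params)
      write_bed(reg$hmeseal_biased,
                file.path(config$outdir,
                          paste0("bias_hmeseal_", tis, ".bed")))
      write_bed(reg$hmedip_biased,
                file.path(config$outdir,
                          paste0("bias_hmedip_", tis, ".bed")))
      rep_stats <- repeat_class_signal(avg, paste0(tis, "_hmedip"),
                                       paste0(tis, "_hmeseal"),
                                       ann$repeats)
      oe_dip <- fragment_cpg_profile(
        avg, calls[[paste0(tis, "_hmedip")]]$peak_probes,
        study$genome$sequence)
      oe_seal <- fragment_cpg_profile(
        avg, calls[[paste0(tis, "_hmeseal")]]$peak_probes,
        study$genome$sequence)
      out[[tis]] <- list(
        n_regions_hmeseal_biased = nrow(reg$hmeseal_biased),
        n_regions_hmedip_biased = nrow(reg$hmedip_biased),
        pct_probes_biased = 100 *
          mean(reg$probes_hmeseal_biased | reg$probes_hmedip_biased),
        repeat_stats = rep_stats$stats,
        fragment_oe_mean_hmedip = mean(oe_dip, na.rm = TRUE),
        fragment_oe_mean_hmeseal = mean(oe_seal, na.rm = TRUE))
    }
    out
  })
  summary$bias <- lapply(bias, function(b) {
    b$repeat_stats <- NULL
    b
  })
  for (tis in names(bias)) {
    write.table(bias[[tis]]$repeat_stats,
                file.path(config$outdir,
                          paste0("repeat_stats_", tis, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  overlap <- pipeline_stage("overlap", {
    covered <- data.frame(chrom = names(ann$chrom_lengths), start = 0,
                          end = unname(ann$chrom_lengths))
    out <- list()
    for (tis in names(study$histone)) {
      marks <- lapply(study$histone[[tis]], restrict_to_array, covered)
      hist_names <- c("H3K4me3", "H3K27me3", "H3K4me1", "H3K27ac",
                      "H3K36me3")
      uniq <- lapply(hist_names, function(mk) {
        unique_mark_peaks(marks[[mk]], marks[setdiff(hist_names, mk)])
      })
      names(uniq) <- hist_names
      enh <- enhancer_states(marks$H3K4me1, marks$H3K27ac, marks$H3K4me3)
      feats <- c(uniq, list(poised_enhancer = enh$poised,
                            active_enhancer = enh$active,
                            RNAPII = marks$RNAPII, CTCF = marks$CTCF))
      techs <- grep(paste0("^", tis, "_"),
                    avg$samples$sample_id, value = TRUE)
      if (tis == "brain") techs <- c(techs, "brain_jbp1")
      techs <- intersect(techs, names(calls))
      out[[tis]] <- lapply(techs, function(sid) {
        pk <- calls[[sid]]$peaks
        lapply(feats, function(f) {
          if (!nrow(f)) return(list(percent = NA, n_features = 0L))
          ov <- overlap_fraction(f, pk)
          list(percent = ov$percent, n_features = ov$n_features)
        })
      })
      names(out[[tis]]) <- techs
    }
    out
  })
  summary$chromatin_overlap <- overlap

  gres <- pipeline_stage("gresqpcr", {
    res <- list()
    for (nm in names(config$gres_loci)) {
      fr <- config$gres_loci[[nm]]
      reps <- lapply(1:2, function(r) {
        assay <- simulate_gres_ct(fr, noise_sd = config$gres_noise_sd,
                                  seed = child_seed(config$seed,
                                                    40L + r + match(nm,
                                                      names(config$gres_loci)) * 10L),
                                  locus = nm, replicate = r)
        # Ct noise routinely moves the two HpaII branches apart by more
        # than the interactive-use warning threshold; the summary keeps
        # the reconciled values
        suppressWarnings(compute_fractions(assay))
      })
      agg <- aggregate_replicates_gres(reps)
      res[[nm]] <- list(true = as.list(setNames(100 * fr,
                                                c("hmc", "mc", "c"))),
                        mean = as.list(setNames(agg$mean, agg$mark)),
                        se = as.list(setNames(agg$se, agg$mark)))
    }
    res
  })
  summary$gres <- gres

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
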