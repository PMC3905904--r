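#' Peak-calling parameters
#'
#' Enriched "peak probes" are defined by a percentile sliding-window rule:
#' within a window of `window_probes` consecutive probes, at least
#' `min_hits` probes must reach the per-sample percentile threshold.
#' Windows never span chromosome ends or tiling gaps larger than
#' `max_gap_bp`.
#'
#' @param percentile Threshold quantile of all probe values (percent).
#' @param window_probes Window size in probes.
#' @param min_hits Minimum probes at/above threshold per window.
#' @param max_gap_bp Maximum inter-probe gap inside a window.
#' @return An object of class `peak_call_params`.
#' @export
peak_call_params <- function(percentile = 95, window_probes = 4L,
                             min_hits = 3L, max_gap_bp = 1000L) {
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100")
  }
  if (min_hits > window_probes) stop("min_hits must not exceed window_probes")
  if (min_hits < 1L) stop("min_hits must be >= 1")
  structure(list(percentile = percentile,
                 window_probes = as.integer(window_probes),
                 min_hits = as.integer(min_hits),
                 max_gap_bp = as.integer(max_gap_bp)),
            class = "peak_call_params")
}

#' Call 5hmC-enriched peak probes and peaks
#'
#' The threshold is the stated percentile of all the sample's probe values
#' genome-wide (linear interpolation between order statistics; ties at the
#' threshold count as hits). A sliding window of `window_probes`
#' consecutive probes — broken at chromosome ends and at gaps larger than
#' `max_gap_bp` — passes when at least `min_hits` of its probes reach the
#' threshold. Peak probes are the union of probes in passing windows;
#' peaks are maximal runs of adjacent peak probes merged into intervals.
#'
#' @param track A normalized [probe_track()].
#' @param sample Sample id or index.
#' @param params A [peak_call_params()].
#' @return List of class `peak_call`: `peak_probes` (logical per probe),
#'   `peaks` (data frame chrom/start/end/n_probes/score), `threshold`,
#'   `sample`.
#' @export
call_peaks <- function(track, sample = NULL, params = peak_call_params()) {
  j <- sample_index(track, sample)
  v <- track$values[, j]
  n <- length(v)
  thr <- unname(quantile(v, params$percentile / 100, type = 7))
  hit <- v >= thr
  seg <- track_segments(track, params$max_gap_bp)
  w <- params$window_probes

  peak <- logical(n)
  cs <- cumsum(c(0L, as.integer(hit)))
  # window starting at i is valid if probes i..i+w-1 share a segment
  if (n >= w) {
    starts <- seq_len(n - w + 1L)
    valid <- seg[starts] == seg[starts + w - 1L]
    wins <- cs[starts + w] - cs[starts]
    pass <- valid & wins >= params$min_hits
    pidx <- which(pass)
    for (off in 0:(w - 1L)) peak[pidx + off] <- TRUE
  }

  peaks <- peak_probe_intervals(track, peak, seg)
  vmeans <- if (nrow(peaks)) {
    runs <- attr(peaks, "runs")
    vapply(runs, function(r) mean(v[r]), numeric(1L))
  } else numeric(0)
  peaks$score <- vmeans
  attr(peaks, "runs") <- NULL
  structure(list(peak_probes = peak, peaks = peaks, threshold = thr,
                 sample = track$samples$sample_id[j]),
            class = "peak_call")
}

# merge runs of adjacent flagged probes (within a segment) into intervals
peak_probe_intervals <- function(track, flag, seg) {
  n <- n_probes(track)
  if (!any(flag)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "runs") <- list()
    return(out)
  }
  idx <- which(flag)
  newrun <- c(TRUE, diff(idx) != 1L | seg[idx[-1L]] != seg[idx[-length(idx)]])
  run_id <- cumsum(newrun)
  runs <- split(idx, run_id)
  out <- data.frame(
    chrom = vapply(runs, function(r) track$probes$chrom[r[1L]],
                   character(1L)),
    start = vapply(runs, function(r) track$probes$start[r[1L]],
                   numeric(1L)),
    end = vapply(runs, function(r) track$probes$end[r[length(r)]],
                 numeric(1L)),
    n_probes = lengths(runs),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "runs") <- unname(runs)
  out
}

#' Genomic category of each probe
#'
#' Maps every probe (by its midpoint) to one of five regions, strand-aware
#' relative to the nearest gene: promoter core (TSS +/- 100 bp), promoter
#' proximal (100 bp - 1 kb upstream of the TSS), promoter distal (1 - 2 kb
#' upstream), intra-genic (inside the gene body) or inter-genic.
#' A probe claimed by two different genes (e.g. the promoter of one lying
#' inside the body of another) is non-uniquely mapping and is `excluded`.
#' Within a single gene, promoter categories take precedence over the
#' body.
#'
#' @param track A [probe_track()] or a probe table (chrom, start, end).
#' @param genes Gene table with `chrom`, `start`, `end`, `strand`,
#'   `gene_id`.
#' @return Factor of length n_probes with levels promoter_core,
#'   promoter_proximal, promoter_distal, intra_genic, inter_genic,
#'   excluded.
#' @export
classify_probes <- function(track, genes) {
  probes <- if (inherits(track, "probe_track")) track$probes else track
  lvls <- c("promoter_core", "promoter_proximal", "promoter_distal",
            "intra_genic", "inter_genic", "excluded")
  if (!nrow(genes)) {
    return(factor(rep("inter_genic", nrow(probes)), levels = lvls))
  }
  if (any(genes$end <= genes$start)) {
    stop("gene with end <= start: ",
         genes$gene_id[which(genes$end <= genes$start)[1L]])
  }
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  reg <- function(cat, s, e) {
    data.frame(chrom = genes$chrom, start = pmax(0, s), end = pmax(0, e),
               gene_id = genes$gene_id, category = cat,
               stringsAsFactors = FALSE)
  }
  # promoter core: TSS +/- 100 bp (inclusive both sides)
  core <- reg("promoter_core", tss - 100, tss + 101)
  prox <- reg("promoter_proximal",
              ifelse(plus, tss - 1000, tss + 101),
              ifelse(plus, tss - 100, tss + 1001))
  dist <- reg("promoter_distal",
              ifelse(plus, tss - 2000, tss + 1001),
              ifelse(plus, tss - 1000, tss + 2001))
  body <- reg("intra_genic", genes$start, genes$end)
  regions <- rbind(core, prox, dist, body)
  regions <- regions[regions$end > regions$start, , drop = FALSE]

  mid <- (probes$start + probes$end) / 2
  mp <- points_to_gr(probes$chrom, mid)
  hits <- GenomicRanges::findOverlaps(mp, bed_to_gr(regions))
  q <- S4Vectors::queryHits(hits)
  gid <- regions$gene_id[S4Vectors::subjectHits(hits)]
  cat <- regions$category[S4Vectors::subjectHits(hits)]

  out <- rep("inter_genic", nrow(probes))
  if (length(q)) {
    ngenes <- vapply(split(gid, q), function(g) length(unique(g)),
                     integer(1L))
    prio <- match(cat, lvls)
    best <- vapply(split(prio, q), min, integer(1L))
    uq <- as.integer(names(ngenes))
    out[uq] <- ifelse(ngenes > 1L, "excluded", lvls[best])
  }
  factor(out, levels = lvls)
}

#' Distribution of peak probes over genomic categories
#'
#' @param categories Factor from [classify_probes()] restricted to (or
#'   subset by) peak probes.
#' @return List with `percent` (named vector over the five categories,
#'   summing to 100 over non-excluded probes), `counts` (including
#'   excluded) and `n_used`.
#' @export
peak_distribution <- function(categories) {
  counts <- table(categories)
  used <- categories[categories != "excluded"]
  if (!length(used)) stop("no uniquely mapping peak probes")
  pct <- 100 * table(droplevels(factor(used,
    levels = setdiff(levels(categories), "excluded")))) / length(used)
  list(percent = c(unclass(pct)), counts = c(unclass(counts)),
       n_used = length(used))
}

#' Overlap of peak probes with CpG islands
#'
#' A peak probe counts if its interval overlaps a CpG-island interval by
#' at least 1 bp. Islands are split into promoter CGIs (within 2 kb
#' upstream through the promoter core of any TSS, strand-aware) and
#' orphan (non-promoter) CGIs.
#'
#' @param track A [probe_track()].
#' @param peak_probes Logical per probe (from [call_peaks()]).
#' @param cgi CGI table (chrom, start, end).
#' @param genes Gene table (for the promoter definition).
#' @return List with counts of CGI peak probes (total, promoter-CGI,
#'   orphan-CGI), `percent_of_array` (share of all array probes) and the
#'   CGI table annotated with promoter status.
#' @export
cgi_peak_overlap <- function(track, peak_probes, cgi, genes) {
  n <- n_probes(track)
  if (!nrow(cgi)) {
    return(list(n_cgi_peak_probes = 0L, n_promoter = 0L, n_orphan = 0L,
                percent_of_array = 0, cgi = cgi))
  }
  promoter <- rep(FALSE, nrow(cgi))
  if (nrow(genes)) {
    tss <- gene_tss(genes)
    plus <- genes$strand == "+"
    prom <- data.frame(chrom = genes$chrom,
                       start = pmax(0, ifelse(plus, tss - 2000, tss - 100)),
                       end = ifelse(plus, tss + 101, tss + 2001))
    promoter <- IRanges::overlapsAny(bed_to_gr(cgi), bed_to_gr(prom))
  }
  cgi$promoter_status <- ifelse(promoter, "promoter", "orphan")
  pk <- which(peak_probes)
  if (!length(pk)) {
    return(list(n_cgi_peak_probes = 0L, n_promoter = 0L, n_orphan = 0L,
                percent_of_array = 0, cgi = cgi))
  }
  pg <- bed_to_gr(track$probes[pk, , drop = FALSE])
  hit_prom <- IRanges::overlapsAny(
    pg, bed_to_gr(cgi[promoter, , drop = FALSE]))
  hit_orph <- IRanges::overlapsAny(
    pg, bed_to_gr(cgi[!promoter, , drop = FALSE]))
  n_cgi <- sum(hit_prom | hit_orph)
  list(n_cgi_peak_probes = n_cgi,
       n_promoter = sum(hit_prom),
       n_orphan = sum(hit_orph & !hit_prom),
       percent_of_array = 100 * n_cgi / n,
       cgi = cgi)
}
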