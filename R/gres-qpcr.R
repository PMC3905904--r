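#' Intact template fraction from a digest/uncut Ct pair
#'
#' Under ideal doubling, the template fraction surviving digestion is
#' 2^(ct_uncut - ct_digest), capped at 1. A sentinel cycle threshold
#' (>= `sentinel_ct`) means no amplification: fully cut, intact fraction
#' zero.
#'
#' @param ct_digest Ct of the digested reaction (vectorized).
#' @param ct_uncut Ct of the matching uncut reaction.
#' @param sentinel_ct No-amplification sentinel.
#' @return Numeric intact fractions in [0, 1].
#' @export
intact_fraction <- function(ct_digest, ct_uncut, sentinel_ct = 50) {
  ifelse(ct_digest >= sentinel_ct, 0,
         pmin(1, 2^(ct_uncut - ct_digest)))
}

gres_ct <- function(assay, bgt, enzyme) {
  row <- assay$bgt == bgt & assay$enzyme == enzyme
  if (sum(row) != 1L) {
    stop("assay must contain exactly one (", enzyme, ", bgt", bgt,
         ") reaction")
  }
  assay$ct[row]
}

#' 5hmC/5mC/C fractions from a six-reaction gRES-qPCR assay
#'
#' Uses the enzyme chemistry of glucosyl-sensitive restriction digestion:
#' MspI cuts C, 5mC and 5hmC but is blocked by glucosyl-5hmC, so the
#' glucosylated (+bGT) MspI-resistant fraction minus the untreated one is
#' 5hmC. HpaII cuts only unmodified C, so its resistant fraction is the
#' total modified (5hmC + 5mC) fraction; glucosylation does not alter
#' HpaII blocking, so the -bGT tube is used and the +bGT tube serves as a
#' consistency check (a warning is issued when they disagree by more than
#' 10 percentage points). Each digest is compared to the uncut tube of
#' its own bGT branch. Negative intermediate values are clamped to zero
#' and the three marks are scaled to sum to exactly 100 percent. (The
#' kit vendor's worksheet formulas are not public; this reconstruction
#' follows the stated enzyme chemistry.)
#'
#' @param assay A `gres_assay` data frame: columns `bgt` ("+"/"-"),
#'   `enzyme` (MspI/HpaII/uncut), `ct` (six rows).
#' @param sentinel_ct No-amplification sentinel Ct.
#' @return List of class `modification_fractions`: `pct_hmc`, `pct_mc`,
#'   `pct_c` (summing to 100), and `raw` (pre-clamp fractions).
#' @export
compute_fractions <- function(assay, sentinel_ct = 50) {
  u_plus <- gres_ct(assay, "+", "uncut")
  u_minus <- gres_ct(assay, "-", "uncut")
  m_plus <- intact_fraction(gres_ct(assay, "+", "MspI"), u_plus,
                            sentinel_ct)
  m_minus <- intact_fraction(gres_ct(assay, "-", "MspI"), u_minus,
                             sentinel_ct)
  h_minus <- intact_fraction(gres_ct(assay, "-", "HpaII"), u_minus,
                             sentinel_ct)
  h_plus <- intact_fraction(gres_ct(assay, "+", "HpaII"), u_plus,
                            sentinel_ct)
  if (abs(h_plus - h_minus) > 0.10) {
    warning("HpaII +/-bGT tubes disagree by ",
            round(100 * abs(h_plus - h_minus), 1),
            " percentage points at locus ", assay$locus[1L])
  }
  hmc_raw <- m_plus - m_minus
  blocked_raw <- h_minus
  mc_raw <- blocked_raw - hmc_raw
  c_raw <- 1 - blocked_raw
  raw <- c(hmc = hmc_raw, mc = mc_raw, c = c_raw)
  clamped <- pmax(raw, 0)
  total <- sum(clamped)
  if (total <= 0) {
    stop("all raw fractions are zero at locus ", assay$locus[1L],
         "; modification fractions undefined")
  }
  pct <- 100 * clamped / total
  structure(list(pct_hmc = unname(pct["hmc"]),
                 pct_mc = unname(pct["mc"]),
                 pct_c = unname(pct["c"]),
                 raw = raw,
                 locus = assay$locus[1L]),
            class = "modification_fractions")
}

#' @export
print.modification_fractions <- function(x, ...) {
  cat(sprintf("%s: 5hmC %.1f%%  5mC %.1f%%  C %.1f%%\n",
              x$locus %||% "locus", x$pct_hmc, x$pct_mc, x$pct_c))
  invisible(x)
}

#' Aggregate modification fractions over biological replicates
#'
#' @param fractions_list List of `modification_fractions`.
#' @return data frame with per-mark mean and standard error (sd/sqrt(n));
#'   a single replicate yields SE `NA` with a notice.
#' @export
aggregate_replicates_gres <- function(fractions_list) {
  m <- do.call(rbind, lapply(fractions_list, function(f) {
    c(hmc = f$pct_hmc, mc = f$pct_mc, c = f$pct_c)
  }))
  n <- nrow(m)
  if (n == 1L) message("single replicate: standard error undefined")
  data.frame(
    mark = c("5hmC", "5mC", "C"),
    mean = colMeans(m),
    se = if (n > 1L) apply(m, 2L, sd) / sqrt(n) else NA_real_,
    n = n,
    row.names = NULL
  )
}

#' Compute fractions for every locus/replicate of a gRES plate table
#'
#' @param plate data frame with columns `locus`, `bgt`, `enzyme`,
#'   `replicate`, `ct` (as read by [read_ct_csv()]).
#' @param sentinel_ct No-amplification sentinel Ct.
#' @return data frame: one row per locus x replicate with the three
#'   percentages.
#' @export
gres_plate_fractions <- function(plate, sentinel_ct = 50) {
  need <- c("locus", "bgt", "enzyme", "replicate", "ct")
  if (!all(need %in% names(plate))) {
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  }
  keys <- unique(plate[c("locus", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- plate[plate$locus == keys$locus[i] &
                   plate$replicate == keys$replicate[i], , drop = FALSE]
    f <- compute_fractions(sub, sentinel_ct)
    data.frame(locus = keys$locus[i], replicate = keys$replicate[i],
               pct_hmc = f$pct_hmc, pct_mc = f$pct_mc, pct_c = f$pct_c,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
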