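#' @importFrom stats cor dist hclust mad median quantile rnorm runif sd
#'   setNames wilcox.test as.dist complete.cases aggregate
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a locally-seeded RNG; the caller's RNG state is
# restored afterwards so simulations never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv()),
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}

# Derive a distinct child seed from a base seed; kept < 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1103L + as.numeric(k) * 12347) %% 2147483629
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Convert a BED-like data frame to a GRanges object
#'
#' Coordinates are 0-based half-open on input (BED convention) and become
#' 1-based closed internally, as GRanges requires.
#'
#' @param df data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open); any further columns are carried as metadata.
#' @return A [GenomicRanges::GRanges] object.
#' @export
bed_to_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, extra, drop = FALSE])
  }
  gr
}

#' Convert a GRanges object to a BED-like data frame (0-based half-open)
#'
#' @param gr A `GRanges` object.
#' @return data frame with `chrom`, `start`, `end` and any metadata columns.
#' @export
gr_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc))
  rownames(df) <- NULL
  df
}

# point GRanges at (possibly fractional) positions: floor() to the containing
# base, 0-based input.
points_to_gr <- function(chrom, pos) {
  p <- as.integer(floor(pos))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = p + 1L, width = 1L))
}
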