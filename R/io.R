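read_interval_file <- function(path, min_cols, col_names, col_types,
                               what = "BED") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) {
    out <- as.data.frame(setNames(lapply(col_types, function(t)
      vector(t, 0L)), col_names), stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < min_cols)) {
    bad <- rows[which(ncols < min_cols)[1L]]
    stop("malformed ", what, " line at ", path, ":", bad,
         " (expected >= ", min_cols, " tab-separated fields)")
  }
  use <- min(min(ncols), length(col_names))
  out <- lapply(seq_len(use), function(k) {
    v <- vapply(parts, `[[`, character(1L), k)
    if (col_types[k] %in% c("integer", "double", "numeric")) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num)) {
        bad <- rows[which(is.na(num))[1L]]
        stop("malformed ", what, " line at ", path, ":", bad,
             " (non-numeric '", v[which(is.na(num))[1L]], "' in column ",
             col_names[k], ")")
      }
      if (col_types[k] == "integer") as.integer(num) else num
    } else v
  })
  names(out) <- col_names[seq_len(use)]
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (all(c("start", "end") %in% names(out)) &&
      any(out$end <= out$start)) {
    bad <- rows[which(out$end <= out$start)[1L]]
    stop("coordinate end <= start at ", path, ":", bad)
  }
  out
}

#' Read a BED file (0-based half-open)
#'
#' Track/browser/comment lines are skipped; malformed lines raise an
#' error naming file and line; an empty file yields an empty table.
#'
#' @param path Path to a BED file.
#' @return data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  read_interval_file(path, 3L,
                     c("chrom", "start", "end", "name", "score", "strand"),
                     c("character", "integer", "integer", "character",
                       "double", "character"))
}

#' Write a BED-like data frame
#' @param df data frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a single-sample probe track
#' @param path Path to a bedGraph (chrom, start, end, value).
#' @param sample_id Sample id for the track.
#' @return A [probe_track()].
#' @export
read_bedgraph <- function(path, sample_id = basename(path)) {
  df <- read_interval_file(path, 4L,
                           c("chrom", "start", "end", "value"),
                           c("character", "integer", "integer", "double"),
                           what = "bedGraph")
  if (!nrow(df)) {
    return(probe_track(df[c("chrom", "start", "end")],
                       matrix(numeric(0), ncol = 1L,
                              dimnames = list(NULL, sample_id))))
  }
  probe_track(df[c("chrom", "start", "end")],
              matrix(df$value, ncol = 1L,
                     dimnames = list(NULL, sample_id)))
}

#' Write one sample of a probe track as bedGraph
#' @param track A [probe_track()].
#' @param sample Sample id or index.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, sample = NULL, path) {
  j <- sample_index(track, sample)
  df <- cbind(track$probes,
              value = format(track$values[, j], digits = 8,
                             trim = TRUE, scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene table (TSV with header)
#'
#' Expected columns: chrom, start, end, strand, gene_id, expression.
#' Coordinates may be converted from 1-based closed (GFF-style) input with
#' `one_based = TRUE`.
#'
#' @param path Path to the TSV.
#' @param one_based Input uses 1-based closed coordinates.
#' @return data frame of genes with 0-based half-open coordinates.
#' @export
read_gene_table <- function(path, one_based = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (one_based) df$start <- df$start - 1L
  if (any(df$end <= df$start)) {
    stop("gene with end <= start in ", path, ": ",
         df$gene_id[which(df$end <= df$start)[1L]])
  }
  df
}

#' Write a gene table as TSV
#' @param genes Gene table.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gRES-qPCR plate CSV
#'
#' Columns: locus, bgt (+/-), enzyme (MspI/HpaII/uncut), replicate, ct.
#'
#' @param path Path to the CSV.
#' @return data frame of Ct values.
#' @export
read_ct_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE, quote = "\"")
  need <- c("locus", "bgt", "enzyme", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("Ct table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- !df$enzyme %in% c("MspI", "HpaII", "uncut")
  if (any(bad)) {
    stop("unknown enzyme '", df$enzyme[which(bad)[1L]], "' in ", path)
  }
  if (any(df$ct <= 0)) stop("non-positive Ct value in ", path)
  df
}

#' Write a gRES-qPCR plate CSV
#' @param plate Ct table.
#' @param path Output path.
#' @export
write_ct_csv <- function(plate, path) {
  write.table(plate, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write FASTA sequences
#' @param sequence A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(sequence, path) {
  Biostrings::writeXStringSet(sequence, path)
  invisible(path)
}

#' Read FASTA sequences
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a synthetic genome to disk (FASTA + BED tables)
#'
#' Writes `genome.fa`, `genes.tsv`, and BED files for CGIs, repeats
#' (class in the name field) and enhancers. Deterministic given the
#' genome object.
#'
#' @param genome A `synthetic_genome` from [build_genome()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- genome$annotation
  write_fasta(genome$sequence, file.path(dir, "genome.fa"))
  write_gene_table(ann$genes, file.path(dir, "genes.tsv"))
  cgi <- ann$cgi
  if (nrow(cgi)) cgi$name <- paste(cgi$cgi_id, cgi$type, sep = "|")
  write_bed(cgi, file.path(dir, "cgi.bed"))
  reps <- ann$repeats
  if (nrow(reps)) reps$name <- reps$class
  write_bed(reps, file.path(dir, "repeats.bed"))
  enh <- ann$enhancers
  if (nrow(enh)) enh$name <- enh$enhancer_id
  write_bed(enh, file.path(dir, "enhancers.bed"))
  invisible(dir)
}
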