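#' Read and write BED-style interval files
#'
#' Plain BED handling on the package's 0-based half-open convention.
#' `write_bed()` writes any data frame with `chrom`, `start`, `end` (plus
#' optional `name`, `score`, `strand` and extra columns); `read_bed()`
#' reads it back, naming the first six columns canonically.
#'
#' @param x A data frame of intervals.
#' @param path File path.
#' @param extra_names Names for columns beyond the sixth when reading.
#' @return `read_bed()` returns a tibble; `write_bed()` its input,
#'   invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  lead <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  x <- x[, c(lead, setdiff(names(x), lead))]
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(x)
}

#' @rdname write_bed
#' @export
read_bed <- function(path, extra_names = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  k <- min(ncol(x), 6L)
  names(x)[seq_len(k)] <- base[seq_len(k)]
  if (ncol(x) > 6L) {
    extra <- extra_names %||% paste0("V", seq_len(ncol(x) - 6L))
    names(x)[7:ncol(x)] <- extra
  }
  x
}

#' Write mapped ends as single-base BED6 intervals
#'
#' Each end becomes `[pos, pos + 1)` with
#' `name = sample:barcode:umi:end_type` and score 1.
#'
#' @param ends A mapped-ends tibble.
#' @param path Output path.
#' @export
write_ends_bed <- function(ends, path) {
  write_bed(tibble(
    chrom = ends$chrom, start = ends$pos, end = ends$pos + 1L,
    name = paste(ends$sample_id, ends$cell_barcode, ends$umi,
                 ends$end_type, sep = ":"),
    score = 1L, strand = ends$strand
  ), path)
}

#' @rdname write_ends_bed
#' @export
read_ends_bed <- function(path) {
  x <- read_bed(path)
  parts <- stringr::str_split_fixed(x$name, ":", 4)
  tibble(
    chrom = x$chrom, pos = as.integer(x$start), strand = x$strand,
    end_type = parts[, 4], sample_id = parts[, 1],
    cell_barcode = ifelse(parts[, 2] == "NA", NA_character_, parts[, 2]),
    umi = ifelse(parts[, 3] == "NA", NA_character_, parts[, 3])
  )
}

#' Write called peaks as BED6+ with cluster columns
#'
#' Columns beyond BED6: `dominant_pos`, `dominant_tpm`, `total_tpm`,
#' `n_positions`, `end_type`.
#'
#' @param peaks A peak tibble from [call_peaks()].
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  write_bed(tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$peak_id, score = round(peaks$total_signal, 3),
    strand = peaks$strand,
    dominant_pos = peaks$dominant_pos,
    dominant_tpm = peaks$dominant_signal,
    total_tpm = peaks$total_signal,
    n_positions = peaks$n_positions,
    end_type = peaks$end_type
  ), path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  x <- read_bed(path, extra_names = c("dominant_pos", "dominant_tpm",
                                      "total_tpm", "n_positions", "end_type"))
  tibble(
    peak_id = x$name, chrom = x$chrom, strand = x$strand,
    start = as.integer(x$start), end = as.integer(x$end),
    dominant_pos = as.integer(x$dominant_pos),
    dominant_signal = x$dominant_tpm, total_signal = x$total_tpm,
    width = as.integer(x$end - x$start),
    n_positions = as.integer(x$n_positions), end_type = x$end_type
  )
}

#' Write a genome as FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read/write the gene annotation as a flat end table
#'
#' The annotation travels as a TSV of annotated isoform ends (`gene_id`,
#' `chrom`, `strand`, `pos`, `end_type`), the input of [gene_models()].
#'
#' @param genes Gene models (for writing) — expanded to the end table.
#' @param path File path.
#' @export
write_gene_annotation <- function(genes, path) {
  readr::write_tsv(annotated_end_table(genes), path)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  gene_models(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}
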