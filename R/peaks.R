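#' Tabulate mapped ends into a per-position count track
#'
#' Counts ends per `(chrom, strand, pos, sample)` — by reads, or by distinct
#' `(cell_barcode, UMI)` molecules when `count_by = "umi"` — producing the
#' track that peak calling consumes. The track is sorted by
#' `(chrom, strand, pos)`.
#'
#' @param ends A mapped-ends tibble (see [extract_mapped_ends()]).
#' @param count_by `"reads"` or `"umi"`.
#' @return A tibble `chrom`, `strand`, `pos`, `end_type`, `sample_id`,
#'   `count`.
#' @export
end_count_track <- function(ends, count_by = c("reads", "umi")) {
  count_by <- match.arg(count_by)
  stopifnot(all(c("chrom", "pos", "strand", "sample_id") %in% names(ends)))
  if (!("end_type" %in% names(ends))) ends$end_type <- NA_character_
  grouped <- dplyr::group_by(as_tibble(ends),
                             .data$chrom, .data$strand, .data$pos,
                             .data$end_type, .data$sample_id)
  track <- if (count_by == "umi") {
    dplyr::summarise(grouped,
                     count = dplyr::n_distinct(.data$cell_barcode, .data$umi),
                     .groups = "drop")
  } else {
    dplyr::summarise(grouped, count = dplyr::n(), .groups = "drop")
  }
  dplyr::arrange(track, .data$chrom, .data$strand, .data$pos)
}

#' Peak-calling parameters for distance-based tag clustering
#'
#' Parameter object for [call_peaks()], defaulting to the distance-based
#' clustering settings `threshold = 3` (in tags per million),
#' `nr_pass_threshold = 1`, `max_dist = 20`, singletons kept
#' (`remove_singletons = FALSE`, `keep_singletons_above = 10`).
#'
#' @param threshold Signal cutoff a position must reach to seed a cluster.
#' @param threshold_is_tpm Interpret `threshold` on the tags-per-million
#'   scale (default) rather than raw counts.
#' @param nr_pass_threshold Number of samples in which a position must pass
#'   the threshold.
#' @param max_dist Maximum gap, in bp, between adjacent seed positions merged
#'   into one cluster (inclusive).
#' @param remove_singletons Drop single-position clusters whose signal is at
#'   or below `keep_singletons_above`.
#' @param keep_singletons_above Signal above which singletons are always
#'   kept.
#' @return A `peak_params` list.
#' @export
peak_params <- function(threshold = 3, threshold_is_tpm = TRUE,
                        nr_pass_threshold = 1L, max_dist = 20L,
                        remove_singletons = FALSE,
                        keep_singletons_above = 10) {
  stopifnot(threshold >= 0, max_dist >= 0, nr_pass_threshold >= 1)
  structure(
    list(threshold = threshold, threshold_is_tpm = threshold_is_tpm,
         nr_pass_threshold = as.integer(nr_pass_threshold),
         max_dist = as.integer(max_dist),
         remove_singletons = remove_singletons,
         keep_singletons_above = keep_singletons_above),
    class = "peak_params"
  )
}

#' Normalize a count track to tags per million
#'
#' Adds a `tpm` column: per sample, `count / library_size * 1e6`, where the
#' library size is that sample's total counted ends. Per sample the TPM
#' column sums to one million whenever the library is non-empty.
#'
#' @param track An end count track (see [end_count_track()]).
#' @return The track with a `tpm` column.
#' @export
tpm_normalize <- function(track) {
  stopifnot(all(c("sample_id", "count") %in% names(track)))
  track <- dplyr::group_by(as_tibble(track), .data$sample_id)
  track <- dplyr::mutate(track, .lib = sum(.data$count))
  track <- dplyr::ungroup(track)
  if (any(track$.lib == 0)) {
    warning("sample(s) with zero library size: TPM set to 0")
  }
  track$tpm <- ifelse(track$.lib > 0, track$count / track$.lib * 1e6, 0)
  track$.lib <- NULL
  track
}

#' Pool count tracks across samples or cells
#'
#' Sums per-position counts over samples, optionally into groups (e.g. cells
#' into cell types). Library sizes add accordingly.
#'
#' @param track An end count track.
#' @param grouping Optional mapping from `sample_id` to a pooled label: a
#'   named character vector, or a data frame with columns `sample_id` and
#'   `group`. Default pools everything into `"pooled"`.
#' @return A pooled end count track.
#' @export
pool_samples <- function(track, grouping = NULL) {
  stopifnot(all(c("chrom", "strand", "pos", "sample_id", "count") %in% names(track)))
  track <- as_tibble(track)
  if (!("end_type" %in% names(track))) track$end_type <- NA_character_
  group_of <- if (is.null(grouping)) {
    rep("pooled", nrow(track))
  } else if (is.data.frame(grouping)) {
    stopifnot(all(c("sample_id", "group") %in% names(grouping)))
    grouping$group[match(track$sample_id, grouping$sample_id)]
  } else {
    unname(grouping[track$sample_id])
  }
  if (anyNA(group_of)) stop("grouping does not cover every sample_id")
  track$sample_id <- group_of
  out <- dplyr::summarise(
    dplyr::group_by(track, .data$chrom, .data$strand, .data$pos,
                    .data$end_type, .data$sample_id),
    count = sum(.data$count), .groups = "drop"
  )
  dplyr::arrange(out, .data$chrom, .data$strand, .data$pos)
}

#' Call TSS/TES peaks by distance-based clustering of end positions
#'
#' Reimplements distance-based tag clustering: positions whose signal passes
#' `threshold` in at least `nr_pass_threshold` samples seed clusters;
#' adjacent seeds on the same chromosome and strand are merged while the gap
#' between them is at most `max_dist` bp. Sub-threshold positions inside a
#' cluster's span contribute to the cluster's total signal (and may carry
#' the dominant position) but never seed or extend a cluster. The dominant
#' position is the argmax of the pooled signal; ties go to the 5'-most
#' position in transcript orientation.
#'
#' @param track An end count track sorted by `(chrom, strand, pos)`; an
#'   unsorted track is an error.
#' @param params A [peak_params()] object.
#' @param end_type Optional end-type label if the track lacks one.
#' @return A tibble of tag clusters: `peak_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open span of seed positions), `dominant_pos`,
#'   `dominant_signal`, `total_signal`, `width`, `n_positions` (positions
#'   with signal inside the span), `n_seeds` (above-threshold positions),
#'   `end_type`.
#' @export
call_peaks <- function(track, params = peak_params(), end_type = NULL) {
  stopifnot(inherits(params, "peak_params"),
            all(c("chrom", "strand", "pos", "sample_id", "count") %in% names(track)))
  track <- as_tibble(track)
  if (!("end_type" %in% names(track))) {
    track$end_type <- end_type %||% NA_character_
  }
  if (nrow(track) == 0L) return(empty_peaks())
  key <- paste(track$chrom, track$strand, track$end_type, sep = "\r")
  if (any(vapply(split(track$pos, key), is.unsorted, logical(1)))) {
    stop("track is not sorted by (chrom, strand, pos)")
  }
  track <- if (params$threshold_is_tpm) tpm_normalize(track) else
    dplyr::mutate(track, tpm = .data$count)

  # per-position: pooled signal and number of samples passing the threshold
  per_pos <- dplyr::summarise(
    dplyr::group_by(track, .data$chrom, .data$strand, .data$end_type, .data$pos),
    pooled = sum(.data$tpm),
    n_pass = sum(.data$tpm >= params$threshold),
    .groups = "drop"
  )
  per_pos <- dplyr::arrange(per_pos, .data$chrom, .data$strand, .data$pos)
  per_pos$seed <- per_pos$n_pass >= params$nr_pass_threshold

  groups <- dplyr::group_split(
    dplyr::group_by(per_pos, .data$chrom, .data$strand, .data$end_type)
  )
  clusters <- purrr::map(groups, cluster_one_strand, params = params)
  out <- dplyr::bind_rows(clusters)
  if (nrow(out) == 0L) return(empty_peaks())
  out <- dplyr::arrange(out, .data$chrom, .data$strand, .data$start)
  out$peak_id <- sprintf("%s:%s:%s:%d", out$end_type, out$chrom,
                         out$strand, out$dominant_pos)
  dplyr::select(out, "peak_id", dplyr::everything())
}

cluster_one_strand <- function(g, params) {
  seeds <- g$pos[g$seed]
  if (length(seeds) == 0L) return(NULL)
  brk <- c(0L, cumsum(diff(seeds) > params$max_dist))
  spans <- tibble(
    start = as.integer(tapply(seeds, brk, min)),
    last = as.integer(tapply(seeds, brk, max)),
    n_seeds = as.integer(tapply(seeds, brk, length))
  )
  res <- purrr::pmap(spans, function(start, last, n_seeds) {
    member <- g$pos >= start & g$pos <= last
    pooled <- g$pooled[member]
    pos <- g$pos[member]
    top <- pooled == max(pooled)
    dom <- if (g$strand[1] == "-") max(pos[top]) else min(pos[top])
    tibble(
      chrom = g$chrom[1], strand = g$strand[1],
      start = start, end = last + 1L,
      dominant_pos = dom,
      dominant_signal = max(pooled),
      total_signal = sum(pooled),
      width = last + 1L - start,
      n_positions = sum(member),
      n_seeds = as.integer(n_seeds),
      end_type = g$end_type[1]
    )
  })
  res <- dplyr::bind_rows(res)
  if (params$remove_singletons) {
    drop <- res$n_seeds == 1L & res$total_signal <= params$keep_singletons_above
    res <- res[!drop, , drop = FALSE]
  }
  res
}

empty_peaks <- function() {
  tibble(
    peak_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), dominant_pos = integer(),
    dominant_signal = double(), total_signal = double(),
    width = integer(), n_positions = integer(), n_seeds = integer(),
    end_type = character()
  )
}
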