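#' @keywords internal
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    g <- setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
    return(toupper(g))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  toupper(genome)
}

# 0-based half-open window, padded with N beyond contig edges
genome_window <- function(genome, chrom, start, end) {
  if (!(chrom %in% names(genome))) {
    stop("contig '", chrom, "' not found in genome")
  }
  n <- nchar(genome[[chrom]])
  left_pad <- max(0L, -start)
  right_pad <- max(0L, end - n)
  s <- substr(genome[[chrom]], max(start, 0L) + 1L, min(end, n))
  paste0(strrep("N", left_pad), s, strrep("N", right_pad))
}

revcomp_chr <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(seq, ""), function(x)
    paste(rev(x), collapse = ""), character(1)))
}

# strand-aware windows in transcript orientation (5'->3'); pos is 0-based
upstream_window <- function(genome, chrom, pos, strand, len) {
  if (strand == "+") {
    genome_window(genome, chrom, pos - len, pos)
  } else {
    revcomp_chr(genome_window(genome, chrom, pos + 1L, pos + 1L + len))
  }
}

downstream_window <- function(genome, chrom, pos, strand, len) {
  if (strand == "+") {
    genome_window(genome, chrom, pos + 1L, pos + 1L + len)
  } else {
    revcomp_chr(genome_window(genome, chrom, pos - len, pos))
  }
}

at_window <- function(genome, chrom, pos, strand, len) {
  if (strand == "+") {
    genome_window(genome, chrom, pos, pos + len)
  } else {
    revcomp_chr(genome_window(genome, chrom, pos - len + 1L, pos + 1L))
  }
}

# positional indicator block for one motif over a window laid out 5'->3'
# toward the end position: feature j = motif starts exactly j nt upstream
motif_offset_block <- function(window_seq, pattern, max_mismatch, window) {
  hits <- scan_motif(window_seq, pattern, max_mismatch)
  v <- integer(window)
  if (length(hits) > 0L) {
    i <- which(hits == 1L)          # 1-based start within the window
    j <- window + 1L - i            # distance of motif start upstream of pos
    v[j[j >= 1L & j <= window]] <- 1L
  }
  v
}

#' Positional promoter-motif features upstream of a TSS peak
#'
#' For each of the three promoter motifs (BREu, TATA-box, BREd) and each of
#' the `window` (default 50) upstream offsets, an indicator of whether the
#' motif starts exactly that many nt upstream of the peak's dominant
#' position, strand-aware and allowing up to `max_mismatch` mismatches.
#' Offset 1 is immediately upstream of the dominant position.
#'
#' @param genome Genome sequence: FASTA path, `DNAStringSet`, or named
#'   character vector of contigs.
#' @param peak One row of a peak tibble (needs `chrom`, `strand`,
#'   `dominant_pos`).
#' @param motifs A [motif_set()].
#' @return A named numeric vector of length `3 * window` (150 by default).
#' @export
tss_motif_features <- function(genome, peak, motifs = motif_set()) {
  genome <- as_genome(genome)
  w <- motifs$window
  u <- upstream_window(genome, peak$chrom, peak$dominant_pos, peak$strand, w)
  blocks <- imap(motifs$tss_motifs, function(pat, nm) {
    setNames(motif_offset_block(u, pat, motifs$max_mismatch, w),
             sprintf("motif_%s_up%02d", nm, seq_len(w)))
  })
  unlist(unname(blocks))
}

#' Positional polyadenylation-signal features upstream of a TES peak
#'
#' For each of the 13 PAS hexamers and each of the `window` (default 50)
#' offsets, an indicator of an exact hexamer match starting that many nt
#' upstream of the cleavage position (strand-aware). The canonical signal
#' typically sits 10-30 nt upstream of cleavage, hence the upstream default;
#' `orientation = "centered"` instead scans the 50 nt centred on the peak.
#'
#' @inheritParams tss_motif_features
#' @param orientation `"upstream"` (default) or `"centered"`.
#' @return A named numeric vector of length `13 * window` (650 by default).
#' @export
tes_motif_features <- function(genome, peak, motifs = motif_set(),
                               orientation = c("upstream", "centered")) {
  orientation <- match.arg(orientation)
  genome <- as_genome(genome)
  w <- motifs$window
  u <- if (orientation == "upstream") {
    upstream_window(genome, peak$chrom, peak$dominant_pos, peak$strand, w)
  } else {
    half <- w %/% 2L
    paste0(
      upstream_window(genome, peak$chrom, peak$dominant_pos, peak$strand, half),
      at_window(genome, peak$chrom, peak$dominant_pos, peak$strand, 1L),
      downstream_window(genome, peak$chrom, peak$dominant_pos, peak$strand,
                        w - half - 1L)
    )
  }
  blocks <- imap(motifs$tes_motifs, function(pat, nm) {
    setNames(motif_offset_block(u, pat, 0L, w),
             sprintf("motif_%s_up%02d", nm, seq_len(w)))
  })
  unlist(unname(blocks))
}

#' Read-distribution features of peaks
#'
#' Raw (pre-normalization) per-peak summaries of the end-read distribution:
#' total and dominant signal, width, number of covered positions, the
#' dominant position's share of the peak signal, the dominant position's
#' relative location within its assigned gene span (0 at the annotated 5'
#' end, 1 at the 3' end, 0.5 when unassigned), and `log10(total + 1)`.
#'
#' @param peaks A peak tibble from [call_peaks()].
#' @param gene_context Optional gene assignment context: a data frame with
#'   `peak_id`, `gene_id`, and the gene's `span_start`, `span_end`,
#'   `gene_strand` (as produced by [assign_peaks()] joined to gene models).
#' @return A tibble of raw distribution features, one row per peak.
#' @export
distribution_features <- function(peaks, gene_context = NULL) {
  rel <- rep(0.5, nrow(peaks))
  if (!is.null(gene_context)) {
    ctx <- gene_context[match(peaks$peak_id, gene_context$peak_id), ]
    has <- !is.na(ctx$gene_id) & !is.na(ctx$span_start)
    span <- pmax(ctx$span_end - ctx$span_start, 1L)
    raw <- (peaks$dominant_pos - ctx$span_start) / span
    raw <- pmin(pmax(raw, 0), 1)
    raw <- ifelse(ctx$gene_strand == "-", 1 - raw, raw)
    rel[has] <- raw[has]
  }
  tibble(
    total_signal = peaks$total_signal,
    dominant_signal = peaks$dominant_signal,
    width = as.numeric(peaks$width),
    n_positions = as.numeric(peaks$n_positions),
    dominant_fraction = ifelse(peaks$total_signal > 0,
                               peaks$dominant_signal / peaks$total_signal, 0),
    gene_rel_pos = rel,
    log_total = log10(peaks$total_signal + 1)
  )
}

#' Artifact-evidence sequence features of peaks
#'
#' Sequence features diagnostic of false-positive ends. For TES peaks:
#' adenine fraction and longest A-run in the 20 nt genomic window downstream
#' of the cleavage site, plus a flag for A-fraction >= 0.6 — the signature
#' of internal priming of the oligo-dT primer at genomic A-rich stretches.
#' For TSS peaks: guanine fraction and a `GGG` flag in the 3 nt at/just
#' downstream of the dominant position plus the cytosine fraction of the 20
#' nt upstream — the signature of spurious internal template switching. All
#' windows are strand-aware; `N` padding at contig edges is excluded from
#' the denominators.
#'
#' @inheritParams tss_motif_features
#' @param peaks A peak tibble.
#' @param end_type `"TSS_5p"` or `"TES_3p"`.
#' @return A tibble of raw artifact features, one row per peak.
#' @export
artifact_features <- function(genome, peaks, end_type = c("TSS_5p", "TES_3p")) {
  end_type <- match.arg(end_type)
  genome <- as_genome(genome)
  if (end_type == "TES_3p") {
    down <- map_chr(seq_len(nrow(peaks)), function(i)
      downstream_window(genome, peaks$chrom[i], peaks$dominant_pos[i],
                        peaks$strand[i], 20L))
    a_frac <- base_fraction(down, "A")
    a_run <- map_int(strsplit(down, ""), longest_run, base = "A")
    tibble(
      down_a_fraction = a_frac,
      down_a_run = as.numeric(a_run),
      internal_priming_flag = as.numeric(a_frac >= 0.6)
    )
  } else {
    at3 <- map_chr(seq_len(nrow(peaks)), function(i)
      at_window(genome, peaks$chrom[i], peaks$dominant_pos[i],
                peaks$strand[i], 3L))
    up <- map_chr(seq_len(nrow(peaks)), function(i)
      upstream_window(genome, peaks$chrom[i], peaks$dominant_pos[i],
                      peaks$strand[i], 20L))
    tibble(
      start_g_fraction = base_fraction(at3, "G"),
      ggg_flag = as.numeric(at3 == "GGG"),
      up_c_fraction = base_fraction(up, "C")
    )
  }
}

base_fraction <- function(seqs, base) {
  counted <- nchar(seqs) - nchar(gsub(base, "", seqs, fixed = TRUE))
  informative <- nchar(gsub("N", "", seqs, fixed = TRUE))
  ifelse(informative > 0, counted / informative, 0)
}

longest_run <- function(chars, base) {
  if (length(chars) == 0L) return(0L)
  r <- rle(chars == base)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 0L else max(runs)
}

#' Assemble the per-peak feature matrix
#'
#' Builds the full feature matrix for a peak set: the read-distribution
#' group (including one total-frequency column per motif), the positional
#' motif group (exactly `3 * window` columns for TSS peaks, `13 * window`
#' for TES peaks), and the artifact group — normalized to `[0, 1]`.
#' Signal-derived columns use quantile (rank) normalization against the
#' assembly data; bounded columns use min-max; binary indicators pass
#' through. The normalization parameters are stored in the result so that a
#' matrix for new peaks can be built on the training scale with
#' `normalization = feature_normalization(trained_matrix)`.
#'
#' @inheritParams tss_motif_features
#' @param peaks A peak tibble with unique `peak_id`s (duplicates are an
#'   error) and a single `end_type`.
#' @param genes Optional gene models (see [gene_models()]) used for the
#'   gene-relative-position feature.
#' @param motifs A [motif_set()].
#' @param tes_orientation Window orientation for PAS scanning, see
#'   [tes_motif_features()].
#' @param normalization Stored normalization parameters from a previous
#'   assembly (default: fit on this data).
#' @return An `rcat_features` tibble (`peak_id` + feature columns) with
#'   attributes `groups` (named character vector, column -> feature group),
#'   `normalization`, and `end_type`.
#' @export
assemble_features <- function(peaks, genome, genes = NULL,
                              motifs = motif_set(),
                              tes_orientation = "upstream",
                              normalization = NULL) {
  stopifnot(nrow(peaks) > 0L)
  if (anyDuplicated(peaks$peak_id)) stop("duplicate peak ids")
  end_type <- unique(peaks$end_type)
  stopifnot(length(end_type) == 1L)
  genome <- as_genome(genome)

  gene_context <- NULL
  if (!is.null(genes)) {
    asg <- assign_peaks(peaks, genes)
    gene_context <- dplyr::left_join(
      asg, dplyr::select(genes, "gene_id", "span_start", "span_end",
                         gene_strand = "strand"),
      by = "gene_id"
    )
  }
  dist_raw <- distribution_features(peaks, gene_context)

  motif_fun <- if (end_type == "TSS_5p") {
    function(p) tss_motif_features(genome, p, motifs)
  } else {
    function(p) tes_motif_features(genome, p, motifs,
                                   orientation = tes_orientation)
  }
  motif_mat <- do.call(rbind, map(seq_len(nrow(peaks)), function(i)
    motif_fun(peaks[i, ])))
  motif_tbl <- as_tibble(as.data.frame(motif_mat))

  # per-motif total frequency joins the distribution group
  motif_names <- names(if (end_type == "TSS_5p") motifs$tss_motifs else motifs$tes_motifs)
  freq_tbl <- as_tibble(setNames(
    map(motif_names, function(nm) {
      cols <- startsWith(names(motif_tbl), paste0("motif_", nm, "_up"))
      rowSums(motif_tbl[, cols, drop = FALSE])
    }),
    paste0("freq_", motif_names)
  ))

  art_raw <- artifact_features(genome, peaks, end_type)

  raw <- dplyr::bind_cols(dist_raw, freq_tbl, motif_tbl, art_raw)
  groups <- c(
    setNames(rep("distribution", ncol(dist_raw) + ncol(freq_tbl)),
             c(names(dist_raw), names(freq_tbl))),
    setNames(rep("motif", ncol(motif_tbl)), names(motif_tbl)),
    setNames(rep("artifact", ncol(art_raw)), names(art_raw))
  )

  if (is.null(normalization)) {
    normalization <- fit_normalization(raw, groups)
  }
  norm <- apply_normalization(raw, normalization)

  out <- dplyr::bind_cols(tibble(peak_id = peaks$peak_id), norm)
  structure(out, groups = groups, normalization = normalization,
            end_type = end_type,
            class = c("rcat_features", class(out)))
}

# quantile normalization for heavy-tailed signal features, min-max for
# bounded ones, identity for binary indicators
fit_normalization <- function(raw, groups) {
  quantile_cols <- intersect(
    c("total_signal", "dominant_signal", "width", "n_positions",
      names(groups)[startsWith(names(groups), "freq_")]),
    names(raw)
  )
  binary_cols <- names(raw)[vapply(raw, function(v)
    all(v %in% c(0, 1)), logical(1))]
  binary_cols <- setdiff(binary_cols, quantile_cols)
  minmax_cols <- setdiff(names(raw), c(quantile_cols, binary_cols))
  norm <- list()
  for (cl in names(raw)) {
    norm[[cl]] <- if (cl %in% quantile_cols) {
      list(type = "quantile", sorted = sort(raw[[cl]]))
    } else if (cl %in% binary_cols) {
      list(type = "identity")
    } else {
      list(type = "minmax", min = min(raw[[cl]]), max = max(raw[[cl]]))
    }
  }
  norm
}

#' Apply stored feature normalization
#'
#' Maps raw feature columns onto the `[0, 1]` training scale using stored
#' parameters: `quantile` columns via the training empirical CDF, `minmax`
#' columns via the training min/max (clamped), `identity` columns untouched.
#'
#' @param raw A data frame of raw feature columns.
#' @param normalization A stored normalization list (see
#'   [feature_normalization()]).
#' @return A tibble of normalized columns in `[0, 1]`.
#' @export
apply_normalization <- function(raw, normalization) {
  stopifnot(all(names(raw) %in% names(normalization)))
  out <- raw
  for (cl in names(raw)) {
    p <- normalization[[cl]]
    out[[cl]] <- switch(
      p$type,
      quantile = findInterval(raw[[cl]], p$sorted) / length(p$sorted),
      minmax = if (p$max > p$min) {
        pmin(pmax((raw[[cl]] - p$min) / (p$max - p$min), 0), 1)
      } else {
        rep(0, nrow(raw))
      },
      identity = raw[[cl]],
      stop("unknown normalization type: ", p$type)
    )
  }
  as_tibble(out)
}

#' Extract the stored normalization of a feature matrix
#' @param features An `rcat_features` object.
#' @return The normalization parameter list stored at assembly time.
#' @export
feature_normalization <- function(features) {
  attr(features, "normalization")
}

#' Extract the column-to-group map of a feature matrix
#' @param features An `rcat_features` object.
#' @return Named character vector mapping feature columns to groups.
#' @export
feature_groups <- function(features) {
  attr(features, "groups")
}
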