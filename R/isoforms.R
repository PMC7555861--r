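#' Build gene models from an annotated-end table
#'
#' @param ends A data frame of annotated isoform ends: `gene_id`, `chrom`,
#'   `strand`, `pos` (0-based), `end_type` (`"TSS_5p"`/`"TES_3p"`).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   list-columns `tss` and `tes` of annotated coordinates, and the gene
#'   span `span_start`, `span_end` (0-based half-open, covering all ends).
#' @export
gene_models <- function(ends) {
  stopifnot(all(c("gene_id", "chrom", "strand", "pos", "end_type") %in% names(ends)))
  ends <- as_tibble(ends)
  bad <- dplyr::summarise(dplyr::group_by(ends, .data$gene_id),
                          n_strand = dplyr::n_distinct(.data$strand),
                          .groups = "drop")
  if (any(bad$n_strand > 1L)) {
    stop("gene(s) with ends on both strands: ",
         paste(bad$gene_id[bad$n_strand > 1L], collapse = ", "))
  }
  dplyr::summarise(
    dplyr::group_by(ends, .data$gene_id, .data$chrom, .data$strand),
    tss = list(sort(.data$pos[.data$end_type == "TSS_5p"])),
    tes = list(sort(.data$pos[.data$end_type == "TES_3p"])),
    span_start = min(.data$pos),
    span_end = max(.data$pos) + 1L,
    .groups = "drop"
  )
}

annotated_end_table <- function(genes) {
  dplyr::bind_rows(
    tidyr::unnest(dplyr::transmute(genes, .data$gene_id, .data$chrom,
                                   .data$strand, end_type = "TSS_5p",
                                   pos = .data$tss), "pos"),
    tidyr::unnest(dplyr::transmute(genes, .data$gene_id, .data$chrom,
                                   .data$strand, end_type = "TES_3p",
                                   pos = .data$tes), "pos")
  )
}

#' Assign peaks to genes with a 2-kb flank rule
#'
#' A peak belongs to a gene when its dominant position lies between 2 kb
#' upstream of the gene's annotated TSSs and 2 kb downstream of its
#' annotated TESs, on the gene's strand. When flanks of neighbouring genes
#' overlap, the tie goes to the gene with the nearest annotated end.
#'
#' @param peaks A peak tibble.
#' @param genes Gene models from [gene_models()].
#' @param flank Flank size in bp (default 2000).
#' @return A tibble `peak_id`, `gene_id` (`NA` when unassigned),
#'   `dist_to_annotated_end` (distance to the nearest annotated end of the
#'   assigned gene).
#' @export
assign_peaks <- function(peaks, genes, flank = 2000L) {
  if (nrow(peaks) == 0L) {
    return(tibble(peak_id = character(), gene_id = character(),
                  dist_to_annotated_end = double()))
  }
  q <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(peaks$dominant_pos + 1L, peaks$dominant_pos + 1L),
    strand = peaks$strand
  )
  s <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$span_start - flank, 0L) + 1L,
                     genes$span_end + flank),
    strand = genes$strand
  )
  hits <- GenomicRanges::findOverlaps(q, s)
  res <- tibble(
    peak = S4Vectors::queryHits(hits),
    gene = S4Vectors::subjectHits(hits)
  )
  if (nrow(res) > 0L) {
    all_ends <- map2(genes$tss, genes$tes, c)
    res$dist <- map_dbl(seq_len(nrow(res)), function(i) {
      min(abs(peaks$dominant_pos[res$peak[i]] - all_ends[[res$gene[i]]]))
    })
    res <- dplyr::slice(dplyr::arrange(dplyr::group_by(res, .data$peak),
                                       .data$dist), 1L)
    res <- dplyr::ungroup(res)
  }
  out <- tibble(peak_id = peaks$peak_id, gene_id = NA_character_,
                dist_to_annotated_end = NA_real_)
  if (nrow(res) > 0L) {
    out$gene_id[res$peak] <- genes$gene_id[res$gene]
    out$dist_to_annotated_end[res$peak] <- res$dist
  }
  out
}

#' Classify peak novelty against the annotation
#'
#' @param assignments Output of [assign_peaks()].
#' @param peaks The peak tibble.
#' @param genes Gene models used for assignment.
#' @param tolerance Distance in bp within which a peak counts as a known
#'   annotated end (default 50).
#' @return A tibble `peak_id`, `gene_id`, `novelty` in
#'   `{known_end, novel_end_known_gene, novel_gene}`.
#' @export
classify_novelty <- function(assignments, peaks, genes, tolerance = 50L) {
  stopifnot(identical(assignments$peak_id, peaks$peak_id))
  dist <- rep(Inf, nrow(peaks))
  assigned <- !is.na(assignments$gene_id)
  if (any(assigned)) {
    gi <- match(assignments$gene_id[assigned], genes$gene_id)
    is_tss <- peaks$end_type[assigned] == "TSS_5p"
    ends <- vector("list", length(gi))
    ends[is_tss] <- genes$tss[gi][is_tss]
    ends[!is_tss] <- genes$tes[gi][!is_tss]
    dist[assigned] <- map_dbl(seq_along(gi), function(i) {
      e <- ends[[i]]
      if (length(e) == 0L) return(Inf)
      min(abs(peaks$dominant_pos[assigned][i] - e))
    })
  }
  tibble(
    peak_id = peaks$peak_id,
    gene_id = assignments$gene_id,
    novelty = dplyr::case_when(
      !assigned ~ "novel_gene",
      dist <= tolerance ~ "known_end",
      TRUE ~ "novel_end_known_gene"
    )
  )
}

#' Quantify peak expression per cell population
#'
#' Counts mapped ends falling inside each peak's span (matching chromosome,
#' strand and end type), per population, either as reads or as distinct
#' `(cell barcode, UMI)` molecules, and normalizes to reads per million
#' (RPM) within each population. Unassigned-end counts per population are
#' attached as the `"unassigned"` attribute, so ends are conserved.
#'
#' @param peaks A peak tibble.
#' @param ends A mapped-ends tibble.
#' @param populations Optional data frame `cell_barcode`, `population`;
#'   default places every end in population `"all"`.
#' @param mode `"reads"` or `"umi"`.
#' @return A tibble `peak_id`, `population`, `count`, `rpm`; per population
#'   RPM sums to one million whenever any end was assigned.
#' @export
quantify_ends <- function(peaks, ends, populations = NULL,
                          mode = c("reads", "umi")) {
  mode <- match.arg(mode)
  ends <- as_tibble(ends)
  ends$population <- if (is.null(populations)) {
    "all"
  } else {
    populations$population[match(ends$cell_barcode, populations$cell_barcode)]
  }
  if (anyNA(ends$population)) {
    stop("populations table does not cover every cell barcode")
  }
  ends$peak_id <- match_ends_to_peaks(ends, peaks)

  assigned <- ends[!is.na(ends$peak_id), , drop = FALSE]
  grouped <- dplyr::group_by(assigned, .data$peak_id, .data$population)
  counts <- if (mode == "umi") {
    dplyr::summarise(grouped,
                     count = dplyr::n_distinct(.data$cell_barcode, .data$umi),
                     .groups = "drop")
  } else {
    dplyr::summarise(grouped, count = dplyr::n(), .groups = "drop")
  }
  counts <- dplyr::group_by(counts, .data$population)
  counts <- dplyr::mutate(counts, rpm = .data$count / sum(.data$count) * 1e6)
  counts <- dplyr::ungroup(counts)
  unassigned <- table(ends$population[is.na(ends$peak_id)])
  attr(counts, "unassigned") <- setNames(as.integer(unassigned),
                                         names(unassigned))
  counts
}

match_ends_to_peaks <- function(ends, peaks) {
  out <- rep(NA_character_, nrow(ends))
  if (nrow(peaks) == 0L || nrow(ends) == 0L) return(out)
  key_e <- paste(ends$chrom, ends$strand, ends$end_type, sep = "\r")
  key_p <- paste(peaks$chrom, peaks$strand, peaks$end_type, sep = "\r")
  for (k in unique(key_e)) {
    pk <- peaks[key_p == k, , drop = FALSE]
    if (nrow(pk) == 0L) next
    o <- order(pk$start)
    pk <- pk[o, , drop = FALSE]
    idx <- which(key_e == k)
    slot <- findInterval(ends$pos[idx], pk$start)
    inside <- slot >= 1L & ends$pos[idx] < pk$end[pmax(slot, 1L)]
    out[idx[inside]] <- pk$peak_id[slot[inside]]
  }
  out
}

#' Call major isoforms per gene and cell population
#'
#' For each gene and population, the major TSS is the assigned TSS peak
#' with maximal RPM and the major TES the assigned TES peak with maximal
#' RPM; the two are paired as the population's major isoform. Ties go to
#' the 5'-most end in transcript orientation. Genes lacking either end type
#' in a population yield no call.
#'
#' @param expr Expression values from [quantify_ends()].
#' @param assignments Peak-to-gene assignments from [assign_peaks()].
#' @param peaks The peak tibble.
#' @return A tibble `gene_id`, `population`, `chrom`, `strand`,
#'   `major_tss`, `major_tes`, `tss_rpm`, `tes_rpm`.
#' @export
call_major_isoforms <- function(expr, assignments, peaks) {
  tab <- dplyr::inner_join(expr, assignments, by = "peak_id")
  tab <- tab[!is.na(tab$gene_id), , drop = FALSE]
  tab <- dplyr::left_join(
    tab,
    dplyr::select(peaks, "peak_id", "chrom", "strand", "dominant_pos",
                  "end_type"),
    by = "peak_id"
  )
  # 5'-most in transcript orientation breaks RPM ties
  tab$tie_ord <- ifelse(tab$strand == "+", tab$dominant_pos, -tab$dominant_pos)
  major <- dplyr::slice(
    dplyr::arrange(
      dplyr::group_by(tab, .data$gene_id, .data$population, .data$end_type),
      dplyr::desc(.data$rpm), .data$tie_ord
    ), 1L)
  major <- dplyr::ungroup(major)
  wide <- tidyr::pivot_wider(
    dplyr::select(major, "gene_id", "population", "chrom", "strand",
                  "end_type", "dominant_pos", "rpm", "count"),
    names_from = "end_type",
    values_from = c("dominant_pos", "rpm", "count")
  )
  need <- c("dominant_pos_TSS_5p", "dominant_pos_TES_3p",
            "rpm_TSS_5p", "rpm_TES_3p", "count_TSS_5p", "count_TES_3p")
  for (nm in setdiff(need, names(wide))) wide[[nm]] <- NA_real_
  out <- dplyr::transmute(
    wide, .data$gene_id, .data$population, .data$chrom, .data$strand,
    major_tss = .data$dominant_pos_TSS_5p,
    major_tes = .data$dominant_pos_TES_3p,
    tss_rpm = .data$rpm_TSS_5p, tes_rpm = .data$rpm_TES_3p,
    tss_count = .data$count_TSS_5p, tes_count = .data$count_TES_3p
  )
  out[!is.na(out$major_tss) & !is.na(out$major_tes), , drop = FALSE]
}

#' Detect alternative-end switching between two cell populations
#'
#' Compares the major isoforms of genes called in both populations: a gene
#' is a TSS switch when the major TES agrees within `same_end_tolerance`
#' but the major TSS differs beyond it (and symmetrically for TES
#' switches). Switch direction is annotated as proximal/distal — whether
#' the switched end moves toward or away from the centre of the gene body
#' (taken as the midpoint of population A's major isoform).
#'
#' @param calls_a,calls_b Major-isoform calls from [call_major_isoforms()]
#'   for the two populations.
#' @param same_end_tolerance Distance in bp under which two majors count as
#'   the same end (default 100).
#' @param min_count Co-expression floor: a gene is compared only when each
#'   major end carries at least this many reads (or UMIs) in both
#'   populations (default 5); calls lacking count columns skip the filter.
#' @return A tibble `gene_id`, `category` in
#'   `{none, TSS_switch, TES_switch, both}`, `tss_shift`, `tes_shift`, and
#'   `direction` (`proximal`/`distal`, `NA` for `none`).
#' @export
detect_switches <- function(calls_a, calls_b, same_end_tolerance = 100L,
                            min_count = 5L) {
  j <- dplyr::inner_join(calls_a, calls_b, by = "gene_id",
                         suffix = c("_a", "_b"))
  cnt_cols <- c("tss_count_a", "tes_count_a", "tss_count_b", "tes_count_b")
  if (all(cnt_cols %in% names(j))) {
    enough <- rowSums(as.matrix(j[, cnt_cols]) >= min_count) == 4L
    j <- j[enough, , drop = FALSE]
  }
  if (nrow(j) == 0L) {
    return(tibble(gene_id = character(), category = character(),
                  tss_shift = double(), tes_shift = double(),
                  direction = character()))
  }
  tss_shift <- abs(j$major_tss_a - j$major_tss_b)
  tes_shift <- abs(j$major_tes_a - j$major_tes_b)
  tss_sw <- tss_shift > same_end_tolerance
  tes_sw <- tes_shift > same_end_tolerance
  category <- dplyr::case_when(
    tss_sw & tes_sw ~ "both",
    tss_sw ~ "TSS_switch",
    tes_sw ~ "TES_switch",
    TRUE ~ "none"
  )
  centre <- (j$major_tss_a + j$major_tes_a) / 2
  moved_a <- ifelse(tss_sw, j$major_tss_a, j$major_tes_a)
  moved_b <- ifelse(tss_sw, j$major_tss_b, j$major_tes_b)
  direction <- ifelse(
    category == "none", NA_character_,
    ifelse(abs(moved_b - centre) < abs(moved_a - centre),
           "proximal", "distal")
  )
  tibble(gene_id = j$gene_id, category = category,
         tss_shift = tss_shift, tes_shift = tes_shift,
         direction = direction)
}

#' Staged log-ratio dynamics of an alternative end pair
#'
#' For genes with an alternative end choice between two populations, pools
#' the cells of each trajectory stage and computes the log-normalized usage
#' ratio of end A (population 1's major) versus end B (population 2's
#' major): `log2((count_A + p) / (count_B + p))` per stage, where ends are
#' counted within `window` bp of each alternative coordinate.
#'
#' @param ends A mapped-ends tibble with cell barcodes.
#' @param stage_labels A data frame `cell_barcode`, `stage` (1..n_stages).
#' @param pairs A data frame of alternative end pairs: `gene_id`, `chrom`,
#'   `strand`, `end_type`, `pos_a`, `pos_b`.
#' @param pseudocount Pseudocount `p` in the log ratio (default 1).
#' @param window Counting window around each alternative end, in bp
#'   (default 10).
#' @param n_stages Number of trajectory stages (default 6).
#' @return A tibble `gene_id`, `stage`, `count_a`, `count_b`, `log_ratio`,
#'   complete over stages `1..n_stages`.
#' @export
stage_ratios <- function(ends, stage_labels, pairs, pseudocount = 1,
                         window = 10L, n_stages = 6L) {
  ends <- as_tibble(ends)
  ends$stage <- stage_labels$stage[match(ends$cell_barcode,
                                         stage_labels$cell_barcode)]
  if (anyNA(ends$stage)) stop("stage labels do not cover every cell barcode")
  res <- map(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    sel <- ends$chrom == pr$chrom & ends$strand == pr$strand &
      ends$end_type == pr$end_type
    e <- ends[sel, , drop = FALSE]
    near_a <- abs(e$pos - pr$pos_a) <= window
    near_b <- abs(e$pos - pr$pos_b) <= window
    tab <- tibble(stage = rep(seq_len(n_stages), 2),
                  which = rep(c("a", "b"), each = n_stages))
    tab$count <- map_int(seq_len(nrow(tab)), function(r) {
      sel2 <- e$stage == tab$stage[r] & (if (tab$which[r] == "a") near_a else near_b)
      sum(sel2)
    })
    wide <- tidyr::pivot_wider(tab, names_from = "which",
                               values_from = "count", names_prefix = "count_")
    tibble(
      gene_id = pr$gene_id, stage = wide$stage,
      count_a = wide$count_a, count_b = wide$count_b,
      log_ratio = log2((wide$count_a + pseudocount) /
                       (wide$count_b + pseudocount))
    )
  })
  dplyr::bind_rows(res)
}

#' Differential isoform expression between two populations
#'
#' Per isoform: the log2 fold change of mean RPM between groups, a
#' two-sided Wilcoxon rank-sum p-value over per-replicate (or per-cell)
#' RPMs, and the Benjamini-Hochberg adjusted q-value.
#'
#' @param expr_a,expr_b Data frames with columns `id` and `rpm`, one row
#'   per replicate/cell measurement of each isoform.
#' @param pseudocount Added to both means in the fold change (default 1).
#' @return A tibble `id`, `mean_a`, `mean_b`, `log2fc`, `p`, `q`.
#' @export
compare_isoform_expression <- function(expr_a, expr_b, pseudocount = 1) {
  ids <- intersect(unique(expr_a$id), unique(expr_b$id))
  res <- map(ids, function(i) {
    a <- expr_a$rpm[expr_a$id == i]
    b <- expr_b$rpm[expr_b$id == i]
    p <- if (length(a) > 0 && length(b) > 0 &&
             (length(unique(c(a, b))) > 1L)) {
      suppressWarnings(wilcox.test(a, b)$p.value)
    } else {
      1
    }
    tibble(id = i, mean_a = mean(a), mean_b = mean(b),
           log2fc = log2((mean(a) + pseudocount) / (mean(b) + pseudocount)),
           p = p)
  })
  out <- dplyr::bind_rows(res)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
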