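#' Configuration of the synthetic end-tag dataset
#'
#' Defines the toy genome, gene/isoform architecture, motif context,
#' artifact rates, cell populations and trajectory stages of the seeded
#' generator. Defaults: a 500-kb genome with 100 genes, two populations of
#' 200 cells with 200 reads per cell (split between 5' and 3' reads),
#' TATA-box planting upstream of 70% of true TSSs, a canonical `AATAAA`
#' 15-30 nt upstream of 90% of true TESs, and artifact rates of 15%
#' internal priming (3' reads), 8% spurious template switching (5' reads)
#' and 5% RNA-degradation ends (5' reads).
#'
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param genome_len Genome length in bp.
#' @param gc GC content of the background sequence.
#' @param n_genes Number of genes.
#' @param p_isoforms Probabilities of a gene having 1, 2 or 3 isoforms.
#' @param min_end_separation Minimum distance in bp between alternative
#'   ends of one gene (kept well above the clustering `max_dist` so that
#'   alternative ends stay distinguishable).
#' @param tss_motif_rate Probability that a true TSS gets a planted
#'   TATA-box 25-35 nt upstream.
#' @param tes_pas_rate Probability that a true TES gets a planted `AATAAA`
#'   15-30 nt upstream.
#' @param switch_fraction Fraction of multi-isoform genes whose major
#'   isoform switches between the two populations (half by TSS, half by
#'   TES choice).
#' @param usage_major Constant major-isoform usage for non-switching genes;
#'   for switching genes usage interpolates linearly from `usage_major` at
#'   stage 1 to `1 - usage_major` at the last stage.
#' @param n_populations,n_cells,n_stages Populations, cells per population,
#'   trajectory stages (population 1 occupies the first half of the
#'   stages, population 2 the second).
#' @param reads_per_cell Reads per cell, split evenly between end types.
#' @param internal_priming_rate,template_switch_rate,degradation_rate
#'   Artifact read rates (fractions of 3', 5', and 5' reads respectively).
#' @param jitter_sd Positional jitter (bp, Gaussian) applied to every read
#'   around its origin — a planted true end or a priming/switch site.
#' @param pcr_duplication_rate Fraction of molecules duplicated once,
#'   replicating their `(barcode, UMI)` pair.
#' @param abundance Optional per-gene abundance weights (e.g. a spike-in
#'   ladder); default log-normal.
#' @param umi_len,barcode_len UMI and cell-barcode widths.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_len = 500000L, gc = 0.45,
                       n_genes = 100L,
                       p_isoforms = c(0.4, 0.4, 0.2),
                       min_end_separation = 200L,
                       tss_motif_rate = 0.7, tes_pas_rate = 0.9,
                       switch_fraction = 0.5, usage_major = 0.9,
                       n_populations = 2L, n_cells = 200L, n_stages = 6L,
                       reads_per_cell = 200L,
                       internal_priming_rate = 0.15,
                       template_switch_rate = 0.08,
                       degradation_rate = 0.05,
                       jitter_sd = 3, pcr_duplication_rate = 0.1,
                       abundance = NULL,
                       umi_len = 8L, barcode_len = 16L) {
  cfg <- as.list(environment())
  rates <- c(tss_motif_rate, tes_pas_rate, switch_fraction, usage_major,
             internal_priming_rate, template_switch_rate, degradation_rate,
             pcr_duplication_rate)
  stopifnot(all(rates >= 0 & rates <= 1), abs(sum(p_isoforms) - 1) < 1e-9,
            n_populations %in% c(1L, 2L))
  structure(cfg, class = "sim_config")
}

#' Simulate a toy genome with gene models and planted ground truth
#'
#' Generates a random-background genome, lays out genes on alternating
#' random strands in regular slots, draws 1-3 isoforms per gene with
#' alternative ends separated by at least `min_end_separation`, writes
#' concrete motif instances into the sequence (a TATA-box upstream of true
#' TSSs, `AATAAA` upstream of true TESs, at the configured planting rates),
#' and plants one internal-priming site (a 14-base A-run inside the gene
#' body) and one internal template-switch site (a genomic `GGG`) per gene.
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (named character vector of contigs), `genes`
#'   (gene models, see [gene_models()]), and `truth` with `isoforms`
#'   (`gene_id`, `isoform_id`, `chrom`, `strand`, `tss`, `tes`,
#'   `switch_type`), `artifact_sites` (`gene_id`, `chrom`, `strand`, `pos`,
#'   `type`), and `abundance`.
#' @export
simulate_genome_and_genes <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$genome_len
  base_p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
              G = config$gc / 2, T = (1 - config$gc) / 2)
  chars <- sample(names(base_p), n, replace = TRUE, prob = base_p)

  slot <- config$genome_len %/% config$n_genes
  margin <- 600L
  sep <- config$min_end_separation

  genes <- map(seq_len(config$n_genes), function(g) {
    slot_start <- (g - 1L) * slot
    strand <- sample(c("+", "-"), 1L)
    n_iso <- sample(1:3, 1L, prob = config$p_isoforms)
    gene_len <- sample(seq(2200L, slot - 2L * margin), 1L)
    g0 <- slot_start + margin + sample(0:100, 1L)
    g1 <- g0 + gene_len - 1L
    switch_type <- "none"
    if (n_iso >= 2L && runif(1) < config$switch_fraction) {
      switch_type <- sample(c("TSS", "TES"), 1L)
    }
    # transcript-oriented end coordinates; isoform 1 is full length and
    # consecutive alternative ends keep at least min_end_separation apart
    left <- g0 + cumsum(c(0L, sep + sample(0:50, n_iso - 1L, replace = TRUE)))
    right <- g1 - cumsum(c(0L, sep + sample(0:50, n_iso - 1L, replace = TRUE)))
    if (strand == "+") {
      tss <- left; tes <- right
    } else {
      tss <- right; tes <- left
    }
    # a switching pair differs in exactly the switched end type
    if (switch_type == "TSS") tes[2] <- tes[1]
    if (switch_type == "TES") tss[2] <- tss[1]
    tibble(gene_id = sprintf("gene%03d", g), isoform_id = seq_len(n_iso),
           chrom = "chr1", strand = strand, tss = as.integer(tss),
           tes = as.integer(tes), switch_type = switch_type,
           span_lo = g0, span_hi = g1)
  })
  iso <- dplyr::bind_rows(genes)

  # plant motifs upstream of true ends (transcript orientation)
  for (i in seq_len(nrow(iso))) {
    if (runif(1) < config$tss_motif_rate) {
      inst <- paste0("TATA", sample(c("A", "T"), 1), "A",
                     sample(c("A", "T"), 1), sample(c("A", "G"), 1))
      chars <- plant_upstream(chars, iso$tss[i], iso$strand[i], inst,
                              sample(25:35, 1L))
    }
    if (runif(1) < config$tes_pas_rate) {
      chars <- plant_upstream(chars, iso$tes[i], iso$strand[i], "AATAAA",
                              sample(15:30, 1L))
    }
  }

  # one internal-priming and one template-switch site per gene body interior
  per_gene <- dplyr::distinct(iso, .data$gene_id, .data$chrom, .data$strand,
                              .data$span_lo, .data$span_hi)
  sites <- map(seq_len(nrow(per_gene)), function(i) {
    # anywhere in the transcript body (mispriming has no positional
    # preference), but clear of every true end so labels stay unambiguous
    cand <- seq(per_gene$span_lo[i] + 100L, per_gene$span_hi[i] - 100L)
    true_ends <- c(iso$tss[iso$gene_id == per_gene$gene_id[i]],
                   iso$tes[iso$gene_id == per_gene$gene_id[i]])
    ok <- cand[vapply(cand, function(p) all(abs(p - true_ends) >= 200L),
                      logical(1))]
    ps <- sort(sample(ok, 2L))
    tibble(gene_id = per_gene$gene_id[i], chrom = per_gene$chrom[i],
           strand = per_gene$strand[i], pos = ps,
           type = c("internal_priming", "template_switch"))
  })
  sites <- dplyr::bind_rows(sites)
  for (i in seq_len(nrow(sites))) {
    if (sites$type[i] == "internal_priming") {
      # oligo-dT mispriming needs a genomic A-run; mispriming sites sit in
      # A-rich context that frequently mimics (noncanonical) PAS hexamers
      chars <- plant_downstream(chars, sites$pos[i], sites$strand[i],
                                strrep("A", sample(8:14, 1L)))
      a_rich <- paste(sample(c("A", "C", "G", "T"), 18L, replace = TRUE,
                             prob = c(0.8, 0.2 / 3, 0.2 / 3, 0.2 / 3)),
                      collapse = "")
      chars <- plant_upstream(chars, sites$pos[i], sites$strand[i], a_rich,
                              sample(22:28, 1L))
    } else {
      chars <- plant_at(chars, sites$pos[i], sites$strand[i], "GGG")
    }
  }

  abundance <- config$abundance %||% stats::rlnorm(config$n_genes, 0, 1.5)
  stopifnot(length(abundance) == config$n_genes)

  ann <- dplyr::bind_rows(
    dplyr::transmute(iso, .data$gene_id, .data$chrom, .data$strand,
                     pos = .data$tss, end_type = "TSS_5p"),
    dplyr::transmute(iso, .data$gene_id, .data$chrom, .data$strand,
                     pos = .data$tes, end_type = "TES_3p")
  )
  list(
    genome = c(chr1 = paste(chars, collapse = "")),
    genes = gene_models(ann),
    truth = list(isoforms = iso, artifact_sites = sites,
                 abundance = abundance)
  )
}

# transcript-orientation sequence planting on a character-per-base genome
plant_upstream <- function(chars, pos, strand, seq, dist) {
  k <- nchar(seq)
  if (strand == "+") {
    idx <- (pos - dist + 1L):(pos - dist + k)       # 1-based genomic
    chars[idx] <- strsplit(seq, "")[[1]]
  } else {
    idx <- (pos + dist - k + 2L):(pos + dist + 1L)
    chars[idx] <- strsplit(revcomp_chr(seq), "")[[1]]
  }
  chars
}

plant_downstream <- function(chars, pos, strand, seq) {
  k <- nchar(seq)
  if (strand == "+") {
    idx <- (pos + 2L):(pos + k + 1L)
    chars[idx] <- strsplit(seq, "")[[1]]
  } else {
    idx <- (pos - k):(pos - 1L) + 1L
    chars[idx] <- strsplit(revcomp_chr(seq), "")[[1]]
  }
  chars
}

plant_at <- function(chars, pos, strand, seq) {
  k <- nchar(seq)
  if (strand == "+") {
    idx <- (pos + 1L):(pos + k)
  } else {
    idx <- (pos - k + 2L):(pos + 1L)
    seq <- revcomp_chr(seq)
  }
  chars[idx] <- strsplit(seq, "")[[1]]
  chars
}

#' Simulate end reads with planted artifacts, cells and stages
#'
#' Draws reads per cell (genes sampled by abundance, isoforms by
#' stage-dependent usage), places true-end reads at the planted ends with
#' Gaussian positional jitter, artifact reads at the planted
#' internal-priming / template-switch sites, degradation reads uniformly
#' inside gene bodies, assigns cell barcodes and per-read UMIs, and
#' appends PCR duplicates replicating `(barcode, UMI)` pairs. Every read
#' has exactly one origin in the returned truth table.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome_and_genes()] for the same config.
#' @return A list: `ends` (mapped-ends tibble, `sample_id` = population),
#'   `origins` (`read_id`, `origin`, `gene_id`, `isoform_id`,
#'   `is_duplicate`), `cells` (`cell_barcode`, `population`, `stage`).
#' @export
simulate_end_reads <- function(config, sim) {
  set.seed(config$seed + 1L)
  iso <- sim$truth$isoforms
  per_gene <- dplyr::summarise(
    dplyr::group_by(iso, .data$gene_id, .data$chrom, .data$strand,
                    .data$switch_type, .data$span_lo, .data$span_hi),
    n_iso = dplyr::n(), .groups = "drop"
  )
  per_gene <- dplyr::arrange(per_gene, .data$gene_id)
  sites <- sim$truth$artifact_sites
  ip_site <- sites$pos[sites$type == "internal_priming"][
    match(per_gene$gene_id, sites$gene_id[sites$type == "internal_priming"])]
  ts_site <- sites$pos[sites$type == "template_switch"][
    match(per_gene$gene_id, sites$gene_id[sites$type == "template_switch"])]

  n_cells_total <- config$n_populations * config$n_cells
  stages_of <- function(popi) {
    if (config$n_populations == 1L) return(seq_len(config$n_stages))
    half <- config$n_stages %/% 2L
    if (popi == 1L) seq_len(half) else (half + 1L):config$n_stages
  }
  cells <- dplyr::bind_rows(map(seq_len(config$n_populations), function(p)
    tibble(population = sprintf("P%d", p),
           stage = sample(stages_of(p), config$n_cells, replace = TRUE))))
  cells$cell_barcode <- unique_kmers(n_cells_total, config$barcode_len)

  reads_per_end <- max(1L, config$reads_per_cell %/% 2L)
  ends_list <- list(); org_list <- list()
  for (et in c("TSS_5p", "TES_3p")) {
    n_reads <- n_cells_total * reads_per_end
    cell_idx <- rep(seq_len(n_cells_total), each = reads_per_end)
    gi <- sample(nrow(per_gene), n_reads, replace = TRUE,
                 prob = sim$truth$abundance)
    stage <- cells$stage[cell_idx]

    # stage-dependent usage of isoform 1 (population 1's major)
    u <- ifelse(per_gene$switch_type[gi] != "none",
                config$usage_major -
                  (2 * config$usage_major - 1) * (stage - 1) / (config$n_stages - 1),
                config$usage_major)
    w3 <- ifelse(per_gene$n_iso[gi] == 3L, 0.1, 0)
    w1 <- ifelse(per_gene$n_iso[gi] == 1L, 1, u * (1 - w3))
    w2 <- ifelse(per_gene$n_iso[gi] >= 2L, (1 - u) * (1 - w3), 0)
    r <- runif(n_reads)
    iso_id <- 1L + (r > w1) + (r > w1 + w2)

    r2 <- runif(n_reads)
    origin <- if (et == "TSS_5p") {
      dplyr::case_when(
        r2 < config$template_switch_rate ~ "template_switch",
        r2 < config$template_switch_rate + config$degradation_rate ~ "degradation",
        TRUE ~ "true_end"
      )
    } else {
      ifelse(r2 < config$internal_priming_rate, "internal_priming", "true_end")
    }

    key <- paste(per_gene$gene_id[gi], iso_id)
    iso_key <- paste(iso$gene_id, iso$isoform_id)
    true_pos <- if (et == "TSS_5p") {
      iso$tss[match(key, iso_key)]
    } else {
      iso$tes[match(key, iso_key)]
    }
    jit <- as.integer(round(rnorm(n_reads, 0, config$jitter_sd)))
    pos <- true_pos + jit
    ts <- origin == "template_switch"
    ip <- origin == "internal_priming"
    pos[ts] <- ts_site[gi[ts]] + jit[ts]
    pos[ip] <- ip_site[gi[ip]] + jit[ip]
    deg <- origin == "degradation"
    if (any(deg)) {
      lo <- per_gene$span_lo[gi[deg]] + 100L
      hi <- per_gene$span_hi[gi[deg]] - 100L
      pos[deg] <- lo + as.integer(floor(runif(sum(deg)) * (hi - lo + 1L)))
    }
    pos <- pmin(pmax(pos, 0L), config$genome_len - 1L)

    ends <- tibble(
      chrom = per_gene$chrom[gi],
      pos = as.integer(pos),
      strand = per_gene$strand[gi],
      end_type = et,
      sample_id = cells$population[cell_idx],
      cell_barcode = cells$cell_barcode[cell_idx],
      umi = random_kmers(n_reads, config$umi_len),
      read_id = sprintf("%s_r%07d", et, seq_len(n_reads))
    )
    orig <- tibble(
      read_id = ends$read_id, origin = origin,
      gene_id = per_gene$gene_id[gi], isoform_id = iso_id,
      is_duplicate = FALSE
    )
    if (config$pcr_duplication_rate > 0) {
      dup <- which(runif(n_reads) < config$pcr_duplication_rate)
      if (length(dup) > 0L) {
        de <- ends[dup, ]; de$read_id <- paste0(de$read_id, "_dup")
        do <- orig[dup, ]; do$read_id <- de$read_id; do$is_duplicate <- TRUE
        ends <- dplyr::bind_rows(ends, de)
        orig <- dplyr::bind_rows(orig, do)
      }
    }
    ends_list[[et]] <- ends
    org_list[[et]] <- orig
  }
  list(
    ends = dplyr::bind_rows(ends_list),
    origins = dplyr::bind_rows(org_list),
    cells = cells
  )
}

#' Emit reference end annotations at a given completeness
#'
#' Samples a `completeness` fraction of the true isoform ends into
#' reference TSS/TES tables emulating incomplete public end catalogs; the
#' remainder are novel ends by construction.
#'
#' @param truth The `truth` element of [simulate_genome_and_genes()].
#' @param completeness Fraction of true ends included (default 0.7).
#' @param seed Seed for the sampling.
#' @return A list of tibbles `reference` and `omitted`, each with
#'   `gene_id`, `chrom`, `strand`, `pos`, `end_type`.
#' @export
make_reference_end_beds <- function(truth, completeness = 0.7, seed = 1L) {
  set.seed(seed)
  iso <- truth$isoforms
  ends <- dplyr::bind_rows(
    dplyr::transmute(iso, .data$gene_id, .data$chrom, .data$strand,
                     pos = .data$tss, end_type = "TSS_5p"),
    dplyr::transmute(iso, .data$gene_id, .data$chrom, .data$strand,
                     pos = .data$tes, end_type = "TES_3p")
  )
  ends <- dplyr::distinct(ends)
  keep <- runif(nrow(ends)) < completeness
  list(reference = ends[keep, , drop = FALSE],
       omitted = ends[!keep, , drop = FALSE])
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [simulate_genome_and_genes()],
#' [simulate_end_reads()] and [make_reference_end_beds()] for one config.
#'
#' @param config A [sim_config()].
#' @param completeness Reference-end completeness (default 1: complete).
#' @return A list with `genome`, `genes`, `truth`, `ends`, `origins`,
#'   `cells`, `reference`, `omitted`.
#' @export
simulate_rcat_dataset <- function(config = sim_config(), completeness = 1) {
  sim <- simulate_genome_and_genes(config)
  reads <- simulate_end_reads(config, sim)
  ref <- make_reference_end_beds(sim$truth, completeness,
                                 seed = config$seed + 2L)
  c(sim, reads, ref)
}

random_kmers <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

unique_kmers <- function(n, k) {
  out <- unique(random_kmers(n * 2L, k))
  while (length(out) < n) out <- unique(c(out, random_kmers(n, k)))
  out[seq_len(n)]
}
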