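mk_genes <- function(tss, tes, gene_id = "g1", strand = "+") {
  gene_models(dplyr::bind_rows(
    tibble::tibble(gene_id = gene_id, chrom = "chr1", strand = strand,
                   pos = as.integer(tss), end_type = "TSS_5p"),
    tibble::tibble(gene_id = gene_id, chrom = "chr1", strand = strand,
                   pos = as.integer(tes), end_type = "TES_3p")
  ))
}

pk_at <- function(pos, end_type = "TSS_5p", strand = "+",
                  id = paste0("pk", seq_along(pos))) {
  tibble::tibble(peak_id = id, chrom = "chr1", strand = strand,
                 start = as.integer(pos), end = as.integer(pos) + 1L,
                 dominant_pos = as.integer(pos), end_type = end_type)
}

test_that("gene models validate strand consistency and cover all ends", {
  g <- mk_genes(10000, 12000)
  expect_equal(g$span_start, 10000L)
  expect_equal(g$span_end, 12001L)
  expect_error(gene_models(tibble::tibble(
    gene_id = "bad", chrom = "chr1", strand = c("+", "-"),
    pos = c(1L, 2L), end_type = "TSS_5p")), "both strands")
})

test_that("the 2-kb flank rule governs peak-to-gene assignment", {
  genes <- mk_genes(10000, 12000)
  near <- assign_peaks(pk_at(8500), genes)      # 1500 bp upstream
  expect_equal(near$gene_id, "g1")
  boundary <- assign_peaks(pk_at(7999), genes)  # 2001 bp upstream
  expect_true(is.na(boundary$gene_id))
  at_edge <- assign_peaks(pk_at(8000), genes)   # exactly 2 kb
  expect_equal(at_edge$gene_id, "g1")
  wrong_strand <- assign_peaks(pk_at(10500, strand = "-"), genes)
  expect_true(is.na(wrong_strand$gene_id))
})

test_that("assignment matches an interval-containment oracle with nearest-end ties", {
  set.seed(61)
  genes <- gene_models(dplyr::bind_rows(lapply(1:8, function(g) {
    lo <- g * 6000L
    tibble::tibble(gene_id = paste0("g", g), chrom = "chr1",
                   strand = sample(c("+", "-"), 1),
                   pos = c(lo, lo + 3000L), end_type = c("TSS_5p", "TES_3p"))
  })))
  peaks <- pk_at(sample(1000:55000, 60),
                 strand = sample(c("+", "-"), 60, replace = TRUE))
  got <- assign_peaks(peaks, genes)
  oracle <- vapply(seq_len(nrow(peaks)), function(i) {
    cand <- which(genes$strand == peaks$strand[i] &
                    genes$span_start - 2000L <= peaks$dominant_pos[i] &
                    peaks$dominant_pos[i] < genes$span_end + 2000L)
    if (length(cand) == 0L) return(NA_character_)
    d <- vapply(cand, function(k)
      min(abs(peaks$dominant_pos[i] - c(genes$tss[[k]], genes$tes[[k]]))),
      double(1))
    genes$gene_id[cand[which.min(d)]]
  }, character(1))
  expect_equal(got$gene_id, oracle)
})

test_that("novelty classification distinguishes known, novel-end and novel-gene", {
  genes <- mk_genes(10000, 12000)
  peaks <- pk_at(c(10003, 10500, 50000), id = c("known", "novel_end", "far"))
  asg <- assign_peaks(peaks, genes)
  nov <- classify_novelty(asg, peaks, genes, tolerance = 50)
  expect_equal(nov$novelty, c("known_end", "novel_end_known_gene",
                              "novel_gene"))
})

test_that("novelty labels equal a nearest-annotated-end oracle on random data", {
  set.seed(62)
  genes <- gene_models(dplyr::bind_rows(lapply(1:6, function(g) {
    lo <- g * 8000L
    tibble::tibble(gene_id = paste0("g", g), chrom = "chr1", strand = "+",
                   pos = c(lo, lo + 4000L), end_type = c("TSS_5p", "TES_3p"))
  })))
  peaks <- pk_at(sample(4000:52000, 50))
  asg <- assign_peaks(peaks, genes)
  nov <- classify_novelty(asg, peaks, genes, tolerance = 50)
  for (i in seq_len(nrow(peaks))) {
    if (is.na(asg$gene_id[i])) {
      expect_equal(nov$novelty[i], "novel_gene")
    } else {
      k <- match(asg$gene_id[i], genes$gene_id)
      d <- min(abs(peaks$dominant_pos[i] - genes$tss[[k]]))
      expect_equal(nov$novelty[i],
                   if (d <= 50) "known_end" else "novel_end_known_gene")
    }
  }
})

test_that("quantification counts reads or distinct UMIs and normalizes to RPM", {
  peaks <- pk_at(c(100, 500), id = c("a", "b"))
  ends <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 100L, 100L, 500L, 900L),
    strand = "+", end_type = "TSS_5p", sample_id = "s1",
    cell_barcode = "BC1", umi = c("u1", "u1", "u2", "u3", "u4")
  )
  reads <- quantify_ends(peaks, ends, mode = "reads")
  expect_equal(reads$count[reads$peak_id == "a"], 3L)
  expect_equal(sum(reads$rpm), 1e6)
  umis <- quantify_ends(peaks, ends, mode = "umi")
  expect_equal(umis$count[umis$peak_id == "a"], 2L)  # duplicate UMI once
  expect_equal(unname(attr(reads, "unassigned")), 1L)
  expect_equal(sum(reads$count) + sum(attr(reads, "unassigned")), nrow(ends))
})

test_that("read and UMI quantification agree without PCR duplication", {
  cfg <- sim_config(seed = 63, genome_len = 100000L, n_genes = 20L,
                    n_populations = 1L, n_cells = 20L, reads_per_cell = 40L,
                    pcr_duplication_rate = 0)
  sim <- simulate_genome_and_genes(cfg)
  reads <- simulate_end_reads(cfg, sim)
  pk <- call_peaks(end_count_track(reads$ends))
  r <- quantify_ends(pk, reads$ends, mode = "reads")
  u <- quantify_ends(pk, reads$ends, mode = "umi")
  j <- dplyr::inner_join(r, u, by = c("peak_id", "population"))
  expect_equal(stats::cor(j$count.x, j$count.y), 1)
})

test_that("major isoforms are the argmax-RPM end pair per gene and population", {
  genes <- mk_genes(c(10000, 10500), 12000)
  peaks <- dplyr::bind_rows(
    pk_at(c(10000, 10500), id = c("t1", "t2")),
    pk_at(12000, end_type = "TES_3p", id = "e1")
  )
  asg <- assign_peaks(peaks, genes)
  expr <- tibble::tibble(peak_id = c("t1", "t2", "e1"), population = "P1",
                         count = c(10L, 30L, 40L),
                         rpm = c(125000, 375000, 500000))
  calls <- call_major_isoforms(expr, asg, peaks)
  expect_equal(calls$major_tss, 10500L)
  expect_equal(calls$major_tes, 12000L)
  expect_equal(calls$tss_rpm, 375000)
})

test_that("major-isoform calls equal an argmax oracle on random expression", {
  set.seed(64)
  genes <- mk_genes(c(10000, 10300, 10600), c(12000, 12400))
  peaks <- dplyr::bind_rows(
    pk_at(c(10000, 10300, 10600), id = paste0("t", 1:3)),
    pk_at(c(12000, 12400), end_type = "TES_3p", id = paste0("e", 1:2))
  )
  asg <- assign_peaks(peaks, genes)
  for (i in 1:10) {
    rpm <- stats::runif(5, 1, 100)
    expr <- tibble::tibble(peak_id = peaks$peak_id, population = "P1",
                           count = 1L, rpm = rpm)
    calls <- call_major_isoforms(expr, asg, peaks)
    expect_equal(calls$major_tss,
                 peaks$dominant_pos[which.max(replace(rpm, 4:5, -Inf))])
    expect_equal(calls$major_tes,
                 peaks$dominant_pos[3L + which.max(rpm[4:5])])
  }
})

test_that("switch categories follow the common-end tolerance rule", {
  base <- tibble::tibble(gene_id = "g1", population = "A", chrom = "chr1",
                         strand = "+", major_tss = 10000L,
                         major_tes = 15000L, tss_rpm = 10, tes_rpm = 10)
  same <- dplyr::mutate(base, population = "B")
  expect_equal(detect_switches(base, same)$category, "none")
  tss_sw <- dplyr::mutate(same, major_tss = 15000L, major_tes = 15040L)
  expect_equal(detect_switches(dplyr::mutate(base, major_tes = 15000L),
                               tss_sw)$category, "TSS_switch")
  both <- dplyr::mutate(same, major_tss = 5000L, major_tes = 20000L)
  expect_equal(detect_switches(base, both)$category, "both")
})

test_that("switch categories equal a direct rule oracle on random calls", {
  set.seed(65)
  for (i in 1:20) {
    a <- tibble::tibble(gene_id = paste0("g", 1:15), population = "A",
                        chrom = "chr1", strand = "+",
                        major_tss = sample(1:20000, 15),
                        major_tes = sample(30000:50000, 15),
                        tss_rpm = 1, tes_rpm = 1)
    b <- dplyr::mutate(a, population = "B",
                       major_tss = .data$major_tss +
                         sample(c(0, 30, 500), 15, replace = TRUE),
                       major_tes = .data$major_tes +
                         sample(c(0, 30, 500), 15, replace = TRUE))
    sw <- detect_switches(a, b, same_end_tolerance = 100)
    tssd <- abs(a$major_tss - b$major_tss) > 100
    tesd <- abs(a$major_tes - b$major_tes) > 100
    oracle <- dplyr::case_when(tssd & tesd ~ "both", tssd ~ "TSS_switch",
                               tesd ~ "TES_switch", TRUE ~ "none")
    expect_equal(sw$category, oracle)
  }
})

test_that("stage log-ratios use the pseudocount and default to six stages", {
  ends <- tibble::tibble(
    chrom = "chr1", pos = rep(c(1000L, 2000L), c(8L, 2L)), strand = "+",
    end_type = "TSS_5p", sample_id = "P1",
    cell_barcode = "BC1", umi = paste0("u", 1:10)
  )
  stages <- tibble::tibble(cell_barcode = "BC1", stage = 1L)
  pairs <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          end_type = "TSS_5p", pos_a = 1000L, pos_b = 2000L)
  sr <- stage_ratios(ends, stages, pairs, pseudocount = 1)
  expect_equal(nrow(sr), 6L)                       # six stages by default
  expect_equal(sr$log_ratio[sr$stage == 1], log2(3))  # (8+1)/(2+1)
  expect_equal(sr$log_ratio[sr$stage == 2], 0)     # empty stage: equal counts
  even <- dplyr::mutate(ends, pos = rep(c(1000L, 2000L), 5L))
  expect_equal(stage_ratios(even, stages, pairs)$log_ratio[1], 0)
})

test_that("differential isoform expression applies Wilcoxon and BH correctly", {
  a <- tibble::tibble(id = rep("i1", 5), rpm = c(1, 2, 3, 4, 5))
  ident <- compare_isoform_expression(a, a)
  expect_equal(ident$log2fc, 0)
  set.seed(66)
  b <- tibble::tibble(id = rep(paste0("i", 1:8), each = 6),
                      rpm = stats::rlnorm(48, 2, 1))
  cc <- tibble::tibble(id = rep(paste0("i", 1:8), each = 6),
                      rpm = stats::rlnorm(48, 2.5, 1))
  res <- compare_isoform_expression(b, cc)
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  # step-up adjustment derived by hand: q_(i) = min_{j >= i} p_(j) * m / j
  m <- nrow(res)
  q_hand <- rev(cummin(rev(res$p[o] * m / seq_len(m))))
  expect_equal(res$q[o], pmin(q_hand, 1))
})
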