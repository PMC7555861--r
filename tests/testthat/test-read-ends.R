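scheme <- primer_scheme()

test_that("primer scheme defaults describe the RT-primer template", {
  expect_equal(scheme$tso_tag, "GTGGTATCAACGCAGAGTACATGGG")
  expect_equal(scheme$tso_trim, "GTGGTATCAACGCAGAGTACAT")
  expect_true(startsWith(scheme$tso_tag, scheme$tso_trim))
  expect_equal(scheme$umi_len, 8L)
  expect_equal(scheme$barcode_len, 16L)
  expect_equal(scheme$polya_min, 10L)
  expect_error(primer_scheme(tso_trim = "AAAA"))
})

test_that("TSO-tagged 5' reads are selected and trimmed, others excluded", {
  res <- select_tss_reads("GTGGTATCAACGCAGAGTACATGGGACGTACGT", scheme)
  expect_equal(nrow(res), 1L)
  expect_equal(res$trimmed_seq, "GGGACGTACGT")   # template-switch GGG kept
  expect_equal(res$end_type, "TSS_5p")

  res2 <- select_tss_reads("GTGGTATCAACGCAGAGTACATGGGACGT", scheme,
                           keep_ggg = FALSE)
  expect_equal(res2$trimmed_seq, "ACGT")

  expect_equal(nrow(select_tss_reads("ACGTACGTACGTACGT", scheme)), 0L)
  expect_equal(nrow(select_tss_reads(character(), scheme)), 0L)
  expect_warning(res3 <- select_tss_reads(c("GTGGTATCAACGCAGAGTACATGGGAC",
                                            "ACXTACGT"), scheme),
                 "skipped")
  expect_equal(nrow(res3), 1L)
})

test_that("tag selection count matches a substring-search oracle", {
  set.seed(11)
  n <- 1000L
  carries <- sample(rep(c(TRUE, FALSE), c(400L, 600L)))
  reads <- vapply(carries, function(ct) {
    if (ct) paste0(random_seq(24), scheme$tso_tag, random_seq(40))
    else random_seq(80)
  }, character(1))
  oracle_n <- sum(vapply(reads, grepl, logical(1),
                         pattern = scheme$tso_tag, fixed = TRUE))
  expect_equal(oracle_n, 400L)
  expect_equal(nrow(select_tss_reads(reads, scheme)), oracle_n)
})

test_that("planted UMI and barcode round-trip through read parsing", {
  set.seed(12)
  n <- 50L
  umi <- vapply(seq_len(n), function(i) random_seq(8), character(1))
  bc <- vapply(seq_len(n), function(i) random_seq(16), character(1))
  tss_reads <- paste0(umi, bc, scheme$tso_tag, vapply(
    seq_len(n), function(i) random_seq(30), character(1)))
  res <- select_tss_reads(tss_reads, scheme)
  expect_equal(res$umi, umi)
  expect_equal(res$cell_barcode, bc)

  r1 <- paste0(scheme$rt_tag, umi, bc, strrep("T", 30))
  r2 <- paste0(vapply(seq_len(n), function(i) random_seq(40), character(1)),
               strrep("A", 12))
  pares <- select_polya_pairs(
    tibble::tibble(read_id = paste0("p", seq_len(n)), r1 = r1, r2 = r2),
    scheme)
  expect_equal(pares$umi, umi)
  expect_equal(pares$cell_barcode, bc)
})

test_that("poly-A pair selection trims the trailing run and is idempotent", {
  r1 <- paste0(scheme$rt_tag, random_seq(8), random_seq(16), strrep("T", 30))
  keep <- select_polya_pairs(
    tibble::tibble(read_id = "a", r1 = r1,
                   r2 = paste0(random_seq(20), "CTG", strrep("A", 10))),
    scheme)
  expect_equal(nrow(keep), 1L)
  expect_true(endsWith(keep$trimmed_seq, "CTG"))
  expect_equal(keep$polya_len, 10L)

  below <- select_polya_pairs(
    tibble::tibble(read_id = "b", r1 = r1,
                   r2 = paste0(random_seq(20), "C", strrep("A", 9))),
    scheme)
  expect_equal(nrow(below), 0L)

  again <- select_polya_pairs(keep, scheme)
  expect_equal(again, keep)
})

test_that("poly-A selection agrees with a run-length oracle on a mixed set", {
  set.seed(13)
  n <- 200L
  runs <- sample(0:20, n, replace = TRUE)
  r1 <- paste0(scheme$rt_tag, vapply(seq_len(n), function(i) random_seq(24),
                                     character(1)), strrep("T", 20))
  body <- vapply(seq_len(n), function(i)
    paste0(random_seq(30), "C"), character(1))  # C stops run extension
  r2 <- paste0(body, strrep("A", runs))
  res <- select_polya_pairs(
    tibble::tibble(read_id = paste0("p", seq_len(n)), r1 = r1, r2 = r2),
    scheme)
  oracle_keep <- which(vapply(r2, function(s) {
    chars <- rev(strsplit(s, "")[[1]])     # brute-force trailing scan
    run <- 0L
    for (ch in chars) { if (ch == "A") run <- run + 1L else break }
    run >= scheme$polya_min
  }, logical(1)))
  expect_equal(res$read_id, paste0("p", oracle_keep))
  expect_equal(res$polya_len, runs[oracle_keep])
})

test_that("single-interruption poly-A bridging only fires when the run resumes", {
  r1 <- paste0(scheme$rt_tag, random_seq(24), strrep("T", 20))
  mk <- function(r2) tibble::tibble(read_id = "x", r1 = r1, r2 = r2)
  bridged <- select_polya_pairs(
    mk(paste0(random_seq(20), "C", strrep("A", 12), "G", strrep("A", 11))),
    scheme, allow_interruption = TRUE)
  expect_equal(bridged$polya_len, 24L)
  strict <- select_polya_pairs(
    mk(paste0(random_seq(20), strrep("A", 5), "G", strrep("A", 11))),
    scheme, allow_interruption = FALSE)
  expect_equal(strict$polya_len, 11L)
})

test_that("mapped-end extraction follows the strand-aware coordinate convention", {
  aln <- tibble::tibble(
    read_id = c("p", "m"), chrom = "chr1", start = c(1000L, 1000L),
    width = 150L, strand = c("+", "-"), n_hits = 1L
  )
  tss <- extract_mapped_ends(aln, "TSS_5p")
  expect_equal(tss$pos, c(1000L, 1149L))
  tes <- extract_mapped_ends(aln, "TES_3p")
  expect_equal(tes$pos, c(1149L, 1000L))
  expect_equal(tss$strand, c("+", "-"))
})

test_that("multimappers and excluded regions are dropped with conservation", {
  set.seed(14)
  n <- 50L
  aln <- tibble::tibble(
    read_id = paste0("r", seq_len(n)), chrom = "chr1",
    start = (seq_len(n) - 1L) * 500L, width = 100L,  # disjoint spans
    strand = sample(c("+", "-"), n, replace = TRUE),
    n_hits = 1L
  )
  aln$n_hits[1:5] <- 3L
  excl <- tibble::tibble(chrom = "chr1", start = aln$start[6:8] + 10L,
                         end = aln$start[6:8] + 20L)
  res <- extract_mapped_ends(aln, "TSS_5p", exclude = excl)
  expect_equal(nrow(res), 42L)
  dropped <- attr(res, "dropped")
  expect_equal(unname(dropped["multimapped"]), 5L)
  expect_true(dropped["excluded"] >= 3L)
  expect_equal(nrow(res) + sum(dropped), n)
})

test_that("alignments on unknown contigs raise an error naming the record", {
  aln <- tibble::tibble(read_id = "bad1", chrom = "chrUn", start = 10L,
                        width = 50L, strand = "+")
  expect_error(extract_mapped_ends(aln, "TSS_5p", contigs = c(chr1 = 1e6)),
               "bad1")
})

test_that("SAM records round-trip through Rsamtools into mapped ends", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t")
  ), sam)
  res <- extract_mapped_ends(sam, "TSS_5p")
  expect_equal(nrow(res), 2L)
  expect_equal(res$pos[res$strand == "+"], 100L)
  expect_equal(res$pos[res$strand == "-"], 249L)  # 1-based 201, 50M, 0-based end
})

test_that("CIGAR reference width honours insertions, deletions and clips", {
  aln <- tibble::tibble(
    read_id = c("a", "b", "c"), chrom = "chr1", start = 0L,
    cigar = c("100M", "20S40M5I35M", "30M10D30M"),
    strand = "+"
  )
  res <- extract_mapped_ends(aln, "TES_3p")
  expect_equal(res$pos, c(99L, 74L, 69L))
})
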