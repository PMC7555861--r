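#' Select and trim template-switch-tagged 5' reads
#'
#' Keeps reads that contain the TSO recognition tag, removes the constant
#' part of the tag, and parses the UMI and cell barcode from the variable
#' segment that precedes it (when present). The `GGG` added during template
#' switching is retained at the start of the trimmed sequence by default, so
#' that soft-clip-aware end calling can anchor the 5' end at the first
#' genome-matching base.
#'
#' @param reads A character vector of read sequences, or a data frame with
#'   columns `read_id` and `seq`.
#' @param scheme A [primer_scheme()].
#' @param max_mismatch Mismatches tolerated when locating the TSO tag
#'   (0 or 1; default 0).
#' @param keep_ggg Keep the template-switch `GGG` at the start of the trimmed
#'   sequence (default `TRUE`); if `FALSE` the full `tso_tag` is removed.
#'
#' @return A tibble with one row per selected read: `read_id`, `end_type`
#'   (`"TSS_5p"`), `cell_barcode`, `umi` (both `NA` when the read does not
#'   carry the fields), and `trimmed_seq`.
#' @examples
#' select_tss_reads(c("GTGGTATCAACGCAGAGTACATGGGACGTACGT", "ACGTACGTACGT"))
#' @export
select_tss_reads <- function(reads, scheme = primer_scheme(),
                             max_mismatch = 0L, keep_ggg = TRUE) {
  reads <- as_read_table(reads)
  if (nrow(reads) == 0L) {
    return(empty_end_reads())
  }
  seqs <- toupper(reads$seq)
  ok <- valid_nucleotides(seqs)
  if (any(!ok)) {
    warning(sum(!ok), " read(s) with non-nucleotide characters skipped")
  }
  reads <- reads[ok, , drop = FALSE]
  seqs <- seqs[ok]

  hit <- find_tag(seqs, scheme$tso_tag, max_mismatch)
  keep <- !is.na(hit)
  reads <- reads[keep, , drop = FALSE]
  seqs <- seqs[keep]
  hit <- hit[keep]

  trim_at <- if (keep_ggg) hit + nchar(scheme$tso_trim) else hit + nchar(scheme$tso_tag)
  trimmed <- substr(seqs, trim_at, nchar(seqs))

  field_w <- scheme$umi_len + scheme$barcode_len
  pre <- substr(seqs, 1L, hit - 1L)
  has_fields <- nchar(pre) >= field_w
  tag_seg <- substr(pre, nchar(pre) - field_w + 1L, nchar(pre))
  umi <- ifelse(has_fields, substr(tag_seg, 1L, scheme$umi_len), NA_character_)
  barcode <- ifelse(has_fields & scheme$barcode_len > 0L,
                    substr(tag_seg, scheme$umi_len + 1L, field_w),
                    NA_character_)

  tibble(
    read_id = reads$read_id,
    end_type = "TSS_5p",
    cell_barcode = barcode,
    umi = umi,
    trimmed_seq = trimmed
  )
}

#' Select poly-A-evidence 3' read pairs and trim the poly-A tail
#'
#' Keeps pairs where R1 carries the 3' tag (the RT-primer constant followed
#' by UMI and cell barcode) and R2 ends in a poly-A run of at least
#' `polya_min` bases. The trailing run is removed from R2 and the UMI and
#' barcode are parsed from R1. The removed run length is recorded in
#' `polya_len`, so re-running the selection on its own output is a no-op.
#'
#' @param pairs A data frame with columns `read_id`, `r1`, `r2` — or the
#'   output of a previous call (recognised by its `trimmed_seq` and
#'   `polya_len` columns).
#' @param scheme A [primer_scheme()].
#' @param allow_interruption Tolerate a single non-A base inside the trailing
#'   run, provided the run resumes for at least `polya_min` more bases
#'   (default `FALSE`: strict uninterrupted run).
#'
#' @return A tibble with `read_id`, `end_type` (`"TES_3p"`), `cell_barcode`,
#'   `umi`, `trimmed_seq` (R2 minus the trailing run), `polya_len`, and the
#'   original `r1`.
#' @export
select_polya_pairs <- function(pairs, scheme = primer_scheme(),
                               allow_interruption = FALSE) {
  stopifnot(is.data.frame(pairs))
  if (all(c("trimmed_seq", "polya_len") %in% names(pairs)) &&
      !("r2" %in% names(pairs))) {
    pairs <- dplyr::rename(pairs, r2 = "trimmed_seq")
    prior_run <- pairs$polya_len
  } else {
    prior_run <- rep(0L, nrow(pairs))
  }
  stopifnot(all(c("read_id", "r1", "r2") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(empty_end_reads(polya = TRUE))
  }
  r1 <- toupper(pairs$r1)
  r2 <- toupper(pairs$r2)
  ok <- valid_nucleotides(r1) & valid_nucleotides(r2)
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) with non-nucleotide characters skipped")
  }
  pairs <- pairs[ok, , drop = FALSE]
  r1 <- r1[ok]; r2 <- r2[ok]; prior_run <- prior_run[ok]

  run <- trailing_a_run(r2, scheme$polya_min, allow_interruption)
  tag_at <- find_tag(r1, scheme$rt_tag, 0L)
  field_w <- scheme$umi_len + scheme$barcode_len
  field_start <- tag_at + nchar(scheme$rt_tag)
  has_fields <- !is.na(tag_at) & nchar(r1) >= field_start + field_w - 1L

  keep <- has_fields & (run >= scheme$polya_min | prior_run >= scheme$polya_min)
  if (!any(keep)) {
    return(empty_end_reads(polya = TRUE))
  }
  pairs <- pairs[keep, , drop = FALSE]
  r1 <- r1[keep]; r2 <- r2[keep]
  run <- run[keep]; prior_run <- prior_run[keep]
  field_start <- field_start[keep]

  umi <- substr(r1, field_start, field_start + scheme$umi_len - 1L)
  barcode <- if (scheme$barcode_len > 0L) {
    substr(r1, field_start + scheme$umi_len,
           field_start + scheme$umi_len + scheme$barcode_len - 1L)
  } else {
    NA_character_
  }

  trim_run <- ifelse(run >= scheme$polya_min, run, 0L)
  tibble(
    read_id = pairs$read_id,
    end_type = "TES_3p",
    cell_barcode = barcode,
    umi = umi,
    trimmed_seq = substr(r2, 1L, nchar(r2) - trim_run),
    polya_len = as.integer(trim_run + prior_run),
    r1 = pairs$r1
  )
}

#' Convert alignment records to strand-aware single-base end positions
#'
#' Converts retained alignments into one genomic end position each: for 5'
#' reads the 5'-most aligned base in transcript orientation, for 3' reads
#' the 3'-most aligned base (the last templated base before the poly-A
#' tail). Multimapped alignments and alignments overlapping an exclusion
#' region set (e.g. an rRNA surrogate BED) are dropped; per-category drop
#' counts are attached as the `"dropped"` attribute so that input records
#' are always conserved.
#'
#' @param alignments A data frame with columns `chrom`, `start` (0-based
#'   leftmost aligned base), `strand` (`"+"`/`"-"`, transcript orientation),
#'   and either `width` (reference span) or `cigar`; optional columns
#'   `read_id`, `n_hits` (1 = unique), `mapq`, `sample_id`, `cell_barcode`,
#'   `umi` are carried through. Alternatively a path to a BAM (or SAM) file,
#'   read via Rsamtools.
#' @param end_type `"TSS_5p"` or `"TES_3p"`.
#' @param exclude Optional exclusion regions: a data frame with `chrom`,
#'   `start`, `end` (0-based half-open), or a BED file path.
#' @param contigs Optional named vector of contig lengths; alignments on a
#'   contig absent from it raise an error naming the offending record.
#' @param min_mapq Minimum mapping quality when `n_hits` is unavailable
#'   (default 20).
#' @param sample_id Sample label used when the input has no `sample_id`
#'   column.
#'
#' @return A tibble of mapped ends: `chrom`, `pos` (0-based single terminal
#'   base), `strand`, `end_type`, `sample_id`, `cell_barcode`, `umi`.
#' @export
extract_mapped_ends <- function(alignments, end_type = c("TSS_5p", "TES_3p"),
                                exclude = NULL, contigs = NULL,
                                min_mapq = 20L, sample_id = "sample1") {
  end_type <- match.arg(end_type)
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments(alignments)
  }
  stopifnot(is.data.frame(alignments),
            all(c("chrom", "start", "strand") %in% names(alignments)))
  aln <- as_tibble(alignments)
  n_in <- nrow(aln)
  dropped <- c(multimapped = 0L, excluded = 0L)
  if (n_in == 0L) {
    out <- empty_mapped_ends()
    attr(out, "dropped") <- dropped
    return(out)
  }
  if (!is.null(contigs)) {
    bad <- !(aln$chrom %in% names(contigs))
    if (any(bad)) {
      id <- if ("read_id" %in% names(aln)) aln$read_id[which(bad)[1]] else which(bad)[1]
      stop("alignment record '", id, "' on unknown contig '",
           aln$chrom[which(bad)[1]], "'")
    }
  }
  if (!("width" %in% names(aln))) {
    if (!("cigar" %in% names(aln))) {
      stop("alignments need either a 'width' or a 'cigar' column")
    }
    aln$width <- cigar_ref_width(aln$cigar)
  }
  stopifnot(all(aln$start >= 0), all(aln$width >= 1))

  unique_ok <- if ("n_hits" %in% names(aln)) {
    aln$n_hits == 1L
  } else if ("mapq" %in% names(aln)) {
    aln$mapq >= min_mapq
  } else {
    rep(TRUE, nrow(aln))
  }
  dropped["multimapped"] <- sum(!unique_ok)
  aln <- aln[unique_ok, , drop = FALSE]

  if (!is.null(exclude) && nrow(aln) > 0L) {
    if (is.character(exclude)) exclude <- read_bed(exclude)
    hit <- overlaps_regions(aln$chrom, aln$start, aln$start + aln$width, exclude)
    dropped["excluded"] <- sum(hit)
    aln <- aln[!hit, , drop = FALSE]
  }

  left <- aln$start
  right <- aln$start + aln$width - 1L
  # transcript 5' end: leftmost base on +, rightmost on -; 3' end mirrors it
  pos <- if (end_type == "TSS_5p") {
    ifelse(aln$strand == "+", left, right)
  } else {
    ifelse(aln$strand == "+", right, left)
  }

  out <- tibble(
    chrom = aln$chrom,
    pos = as.integer(pos),
    strand = aln$strand,
    end_type = end_type,
    sample_id = if ("sample_id" %in% names(aln)) aln$sample_id else sample_id,
    cell_barcode = if ("cell_barcode" %in% names(aln)) aln$cell_barcode else NA_character_,
    umi = if ("umi" %in% names(aln)) aln$umi else NA_character_
  )
  attr(out, "dropped") <- dropped
  out
}

# ---- internal helpers -------------------------------------------------------

as_read_table <- function(reads) {
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)), seq = reads)
  }
  stopifnot(is.data.frame(reads))
  if (!("seq" %in% names(reads)) && "trimmed_seq" %in% names(reads)) {
    reads$seq <- reads$trimmed_seq
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  as_tibble(reads)
}

valid_nucleotides <- function(seqs) {
  !grepl("[^ACGTN]", seqs)
}

# first-occurrence tag search; mm = 0 uses fixed matching, mm >= 1 a
# sliding Hamming comparison (tags are short constants, reads are short)
find_tag <- function(seqs, tag, max_mismatch = 0L) {
  if (max_mismatch == 0L) {
    hit <- regexpr(tag, seqs, fixed = TRUE)
    return(ifelse(hit > 0L, as.integer(hit), NA_integer_))
  }
  k <- nchar(tag)
  tag_chars <- strsplit(tag, "")[[1]]
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(NA_integer_)
    sc <- strsplit(s, "")[[1]]
    for (i in seq_len(n - k + 1L)) {
      if (sum(sc[i:(i + k - 1L)] != tag_chars) <= max_mismatch) return(i)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

# length of the trailing poly-A run; optionally bridges one non-A base when
# the run on its far side is itself >= polya_min
trailing_a_run <- function(seqs, polya_min, allow_interruption = FALSE) {
  run <- nchar(seqs) - nchar(sub("A*$", "", seqs))
  if (allow_interruption) {
    rest <- substr(seqs, 1L, nchar(seqs) - run - 1L)  # drop one non-A base
    inner <- nchar(rest) - nchar(sub("A*$", "", rest))
    bridged <- run > 0L & inner >= polya_min & nchar(seqs) > run
    run <- ifelse(bridged, run + 1L + inner, run)
  }
  as.integer(run)
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L) stop("malformed CIGAR: ", cg)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    w <- 0L
    for (t in toks) {
      op <- substr(t, nchar(t), nchar(t))
      if (op %in% c("M", "D", "N", "=", "X")) {
        w <- w + as.integer(substr(t, 1L, nchar(t) - 1L))
      }
    }
    w
  }, integer(1), USE.NAMES = FALSE)
}

overlaps_regions <- function(chrom, start, end, regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  IRanges::overlapsAny(q, s)
}

empty_end_reads <- function(polya = FALSE) {
  out <- tibble(
    read_id = character(), end_type = character(),
    cell_barcode = character(), umi = character(),
    trimmed_seq = character()
  )
  if (polya) {
    out$polya_len <- integer()
    out$r1 <- character()
  }
  out
}

empty_mapped_ends <- function() {
  tibble(
    chrom = character(), pos = integer(), strand = character(),
    end_type = character(), sample_id = character(),
    cell_barcode = character(), umi = character()
  )
}

read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "mapq", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  tibble(
    read_id = b$qname,
    chrom = as.character(b$rname),
    start = as.integer(b$pos) - 1L,
    strand = as.character(b$strand),
    cigar = b$cigar,
    mapq = as.integer(b$mapq)
  )
}
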