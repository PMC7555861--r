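#' Promoter and polyadenylation-signal motif sets
#'
#' The three core-promoter motifs scanned upstream of candidate TSSs —
#' BREu (`SSRCGCC`), TATA-box (`TATAWAWR`), BREd (`RTDKKKK`) — and the 13
#' polyadenylation-signal (PAS) hexamers scanned upstream of candidate
#' cleavage sites: the two canonical signals `AATAAA` and `ATTAAA` plus 11
#' non-canonical variants. Promoter motifs are matched with up to
#' `max_mismatch` mismatches (default 2); PAS hexamers are matched exactly.
#'
#' @param max_mismatch Mismatch tolerance for the TSS (promoter) motifs.
#' @param window Scan window, in nt upstream of the end position.
#' @return A `motif_set` list with `tss_motifs`, `tes_motifs`,
#'   `max_mismatch`, `window`.
#' @export
motif_set <- function(max_mismatch = 2L, window = 50L) {
  structure(
    list(
      tss_motifs = c(BREu = "SSRCGCC", TATA = "TATAWAWR", BREd = "RTDKKKK"),
      tes_motifs = setNames(
        c("AATAAA", "ATTAAA", "AAGAAA", "AATAGA", "AATACA", "AATATA",
          "AATGAA", "AGTAAA", "ACTAAA", "GATAAA", "CATAAA", "TATAAA",
          "TTTAAA"),
        c("AATAAA", "ATTAAA", "AAGAAA", "AATAGA", "AATACA", "AATATA",
          "AATGAA", "AGTAAA", "ACTAAA", "GATAAA", "CATAAA", "TATAAA",
          "TTTAAA")
      ),
      max_mismatch = as.integer(max_mismatch),
      window = as.integer(window)
    ),
    class = "motif_set"
  )
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Scan a sequence for a degenerate motif with mismatches
#'
#' Slides an IUPAC pattern along a nucleotide sequence and reports, at every
#' offset, whether the number of positions violating the pattern's base sets
#' is at most `max_mismatch`. An `N` in the sequence never satisfies a
#' pattern position (it always counts as a mismatch), so window padding at
#' contig edges cannot create matches.
#'
#' @param seq A single nucleotide string (`ACGTN`).
#' @param pattern An IUPAC pattern string; an invalid IUPAC character is an
#'   error.
#' @param max_mismatch Allowed mismatches.
#' @return An integer 0/1 vector with one element per offset
#'   `1 .. nchar(seq) - nchar(pattern) + 1` (empty when the sequence is
#'   shorter than the pattern).
#' @examples
#' scan_motif("TATAAAAG", "TATAWAWR", 0)
#' @export
scan_motif <- function(seq, pattern, max_mismatch = 0L) {
  stopifnot(length(seq) == 1L, length(pattern) == 1L)
  seq <- toupper(seq)
  pattern <- toupper(pattern)
  pat <- strsplit(pattern, "")[[1]]
  if (!all(pat %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC character in pattern: ",
         paste(setdiff(pat, names(IUPAC_SETS)), collapse = ", "))
  }
  n <- nchar(seq)
  k <- length(pat)
  if (n < k) return(integer(0))
  s <- strsplit(seq, "")[[1]]
  n_off <- n - k + 1L
  mism <- integer(n_off)
  for (j in seq_len(k)) {
    allowed <- IUPAC_SETS[[pat[j]]]
    mism <- mism + !(s[j:(j + n_off - 1L)] %in% allowed)
  }
  as.integer(mism <= max_mismatch)
}
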