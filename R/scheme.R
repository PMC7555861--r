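#' Primer scheme describing the end-tag library chemistry
#'
#' Describes the constant sequences and field widths of the tagging chemistry
#' so that reads can be selected, trimmed, and parsed into UMI and cell
#' barcode. The defaults correspond to a template-switching RT primer of the
#' form `AAGCAGTGGTATCAACGCAGAGT-N8-[16 bp cell barcode]-T30VN`: 5' reads are
#' recognised by the template-switching oligo (TSO) tag ending in `GGG`, 3'
#' reads by the shared RT constant followed by an 8-nt UMI and a 16-nt cell
#' barcode, with the transcript's poly-A tail providing 3'-end evidence.
#'
#' @param tso_tag Full TSO recognition sequence a 5'-end read must contain.
#' @param tso_trim Prefix of `tso_tag` removed from selected 5' reads; the
#'   trailing `GGG` of the tag (added during template switching) is retained
#'   by default so that downstream end calling can treat it as soft clip.
#' @param rt_tag Constant RT-primer segment that precedes the UMI in 3'-tag
#'   (R1) reads; used to locate the UMI/barcode fields.
#' @param umi_len UMI width in bases (immediately after `rt_tag`).
#' @param barcode_len Cell-barcode width in bases (after the UMI).
#' @param polya_min Minimum trailing poly-A run length, in bases, for a read
#'   pair to count as 3'-end evidence.
#'
#' @return An object of class `primer_scheme` (a named list).
#' @examples
#' primer_scheme()
#' @export
primer_scheme <- function(tso_tag = "GTGGTATCAACGCAGAGTACATGGG",
                          tso_trim = "GTGGTATCAACGCAGAGTACAT",
                          rt_tag = "GTGGTATCAACGCAGAGT",
                          umi_len = 8L,
                          barcode_len = 16L,
                          polya_min = 10L) {
  umi_len <- as.integer(umi_len)
  barcode_len <- as.integer(barcode_len)
  polya_min <- as.integer(polya_min)
  stopifnot(
    is.character(tso_tag), length(tso_tag) == 1L,
    is.character(tso_trim), length(tso_trim) == 1L,
    startsWith(tso_tag, tso_trim),
    umi_len > 0L, barcode_len >= 0L, polya_min >= 1L
  )
  structure(
    list(
      tso_tag = toupper(tso_tag),
      tso_trim = toupper(tso_trim),
      rt_tag = toupper(rt_tag),
      umi_len = umi_len,
      barcode_len = barcode_len,
      polya_min = polya_min
    ),
    class = "primer_scheme"
  )
}

#' @export
print.primer_scheme <- function(x, ...) {
  cat("<primer_scheme>\n")
  cat("  TSO tag:     ", x$tso_tag, "\n")
  cat("  TSO trim:    ", x$tso_trim, "\n")
  cat("  RT constant: ", x$rt_tag, "\n")
  cat("  UMI: ", x$umi_len, " nt; barcode: ", x$barcode_len,
      " nt; poly-A min: ", x$polya_min, " nt\n", sep = "")
  invisible(x)
}
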