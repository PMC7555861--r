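# brute-force reference implementations used as independent oracles

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# exhaustive per-offset, per-position Hamming scan
oracle_motif_scan <- function(seq, pattern, mm) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); k <- length(p)
  if (n < k) return(integer(0))
  out <- integer(n - k + 1L)
  for (i in seq_len(n - k + 1L)) {
    d <- 0L
    for (j in seq_len(k)) {
      if (!(s[i + j - 1L] %in% oracle_iupac[[p[j]]])) d <- d + 1L
    }
    out[i] <- as.integer(d <= mm)
  }
  out
}

# O(n^2) transitive-merge clusterer over seed positions; count-threshold
# semantics (threshold_is_tpm = FALSE, nr_pass_threshold = 1)
oracle_clusters <- function(track, threshold, max_dist) {
  out <- list()
  for (str in unique(track$strand)) {
    d <- track[track$strand == str, , drop = FALSE]
    pooled <- tapply(d$count, d$pos, sum)
    pos <- as.integer(names(pooled))
    pass <- tapply(d$count >= threshold, d$pos, any)
    seeds <- pos[pass[as.character(pos)]]
    if (length(seeds) == 0L) next
    grp <- seq_along(seeds)
    repeat {
      changed <- FALSE
      for (i in seq_along(seeds)) {
        for (j in seq_along(seeds)) {
          if (abs(seeds[i] - seeds[j]) <= max_dist && grp[i] != grp[j]) {
            g <- min(grp[i], grp[j])
            grp[grp == grp[i] | grp == grp[j]] <- g
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (g in unique(grp)) {
      sd_pos <- seeds[grp == g]
      lo <- min(sd_pos); hi <- max(sd_pos)
      member <- pos >= lo & pos <= hi
      mp <- pos[member]; mv <- as.numeric(pooled[member])
      top <- mp[mv == max(mv)]
      dom <- if (str == "-") max(top) else min(top)
      out[[length(out) + 1L]] <- tibble::tibble(
        strand = str, start = lo, end = hi + 1L, dominant_pos = dom,
        total_signal = sum(mv), n_positions = length(mp),
        n_seeds = length(sd_pos)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(strand = character(), start = integer(),
                          end = integer(), dominant_pos = integer(),
                          total_signal = double(), n_positions = integer(),
                          n_seeds = integer()))
  }
  dplyr::arrange(res, .data$strand, .data$start)
}

random_seq <- function(k) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

# random single-chromosome count track (sorted), 1-2 samples
random_track <- function(n_pos = 30, max_coord = 300, n_samples = 1) {
  pos <- sort(sample(seq_len(max_coord), n_pos))
  dplyr::bind_rows(lapply(seq_len(n_samples), function(s) {
    tibble::tibble(
      chrom = "chr1",
      strand = sample(c("+", "-"), n_pos, replace = TRUE),
      pos = pos,
      end_type = "TSS_5p",
      sample_id = paste0("s", s),
      count = sample(0:5, n_pos, replace = TRUE)
    )
  })) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
}

# small hand-made feature matrix with rcat_features attributes
fake_features <- function(x, groups, end_type = "TSS_5p") {
  stopifnot(is.data.frame(x), "peak_id" %in% names(x))
  cols <- setdiff(names(x), "peak_id")
  norm <- lapply(cols, function(cl) list(type = "identity"))
  names(norm) <- cols
  structure(tibble::as_tibble(x),
            groups = stats::setNames(groups, cols),
            normalization = norm, end_type = end_type,
            class = c("rcat_features", class(tibble::tibble())))
}
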