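# Triplet-periodicity significance: windows that look protein-coding
# (strong period-3 structure) are flagged so the scanner can skip them.

#' Triplet-periodicity statistic Z
#'
#' Builds the 4 x 3 table of base counts by position mod 3 (frames counted
#' from the first base of the window; N bases are excluded), computes the
#' mutual information I (nats) between base identity and frame, and forms
#' the statistic 2NI, asymptotically chi-square with df = (4-1)(3-1) = 6
#' when the window has no triplet structure.  Z is the normalized form
#'
#'   Z = (2NI - 6) / sqrt(12)
#'
#' so Z > 3 flags a window as protein-coding-like.  I is invariant under
#' base relabeling and under frame shifts, so no reading-frame search is
#' needed.
#'
#' @param S DNA string (>= 30 bases, not all N).
#' @return a `triplet_stats`: list with `counts` (4 x 3), `I` (nats),
#'   `Z`, and `n_bases` (counted residues).
#' @export
triplet_z <- function(S) {
  codes <- if (is.character(S)) encode_dna(S) else as.integer(S)
  if (length(codes) < 30L) stop("triplet statistic needs at least 30 bases")
  keep <- codes > 0L
  if (!any(keep)) stop("sequence contains no A/C/G/T bases")
  frame <- ((seq_along(codes) - 1L) %% 3L) + 1L
  counts <- matrix(0L, nrow = 4, ncol = 3,
                   dimnames = list(BASES, paste0("frame", 1:3)))
  tb <- table(factor(codes[keep], levels = 1:4),
              factor(frame[keep], levels = 1:3))
  counts[] <- as.integer(tb)
  N <- sum(counts)
  I <- (sum(xlogx(counts)) - sum(xlogx(rowSums(counts))) -
          sum(xlogx(colSums(counts))) + xlogx(N)) / N
  Z <- (2 * N * I - 6) / sqrt(12)
  structure(list(counts = counts, I = I, Z = Z, n_bases = N),
            class = "triplet_stats")
}

#' @export
print.triplet_stats <- function(x, ...) {
  cat(sprintf("triplet_stats: N = %d, I = %.5f nats, Z = %.3f\n",
              x$n_bases, x$I, x$Z))
  invisible(x)
}
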