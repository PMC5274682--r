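# Position weight matrices over period columns: the GA's "organism".

#' Construct a period weight matrix
#'
#' A weight matrix is a 4 x n real matrix m(i, j): the weight of base i
#' (rows A, C, G, T) at period position j (columns 1..n).  All scoring in
#' the package assumes the normalized scale in which every column has
#' base-weight mean 0 and (population) variance 1, so the expected
#' per-base score on a uniform random sequence is 0.
#'
#' @param m numeric matrix with 4 rows and n >= 2 columns.
#' @param normalize normalize columns on construction (default TRUE).
#' @return a `weight_matrix` (a numeric matrix with rownames A,C,G,T).
#' @seealso [normalize_weight_matrix()], [random_weight_matrix()]
#' @export
weight_matrix <- function(m, normalize = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) != 4L) stop("weight matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 2L) stop("period length must be at least 2")
  if (!all(is.finite(m))) stop("weight matrix entries must be finite")
  storage.mode(m) <- "double"
  rownames(m) <- BASES
  colnames(m) <- NULL
  if (normalize) m <- .normalize_columns(m)
  structure(m, class = c("weight_matrix", "matrix", "array"))
}

.normalize_columns <- function(m) {
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  s <- sqrt(colMeans(ctr^2))            # population sd over the 4 bases
  flat <- s < 1e-12
  s[flat] <- 1
  out <- sweep(ctr, 2, s, "/")
  out[, flat] <- 0                      # all-equal columns carry no signal
  out
}

#' Normalize a weight matrix column-wise
#'
#' Each column is shifted and scaled to base-weight mean 0 and population
#' variance 1.  Columns whose four weights are (numerically) all equal are
#' set to all zero: they cannot prefer any base.  Idempotent.
#'
#' @param M a [weight_matrix()] or 4 x n numeric matrix.
#' @return normalized `weight_matrix`.
#' @export
normalize_weight_matrix <- function(M) weight_matrix(M, normalize = TRUE)

#' Random normalized weight matrix
#'
#' Initial GA organisms: i.i.d. standard normal weights, column-normalized.
#'
#' @param n period length (2..100).
#' @param seed optional integer seed.
#' @return a `weight_matrix`.
#' @export
random_weight_matrix <- function(n, seed = NULL) {
  stopifnot(n >= 2, n <= 100)
  draw <- function() weight_matrix(matrix(rnorm(4 * n), nrow = 4))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Weight matrix preferring a fixed consensus
#'
#' Convenience constructor: +1 on the consensus base of each column, -1
#' elsewhere, then normalized.  Useful for constructing known-signal
#' matrices in examples and tests.
#'
#' @param consensus character string over A/C/G/T; its length is the period.
#' @return a `weight_matrix`.
#' @export
consensus_weight_matrix <- function(consensus) {
  codes <- encode_dna(consensus)
  if (any(codes == 0L)) stop("consensus may not contain N")
  m <- matrix(-1, nrow = 4, ncol = length(codes))
  m[cbind(codes, seq_along(codes))] <- 1
  weight_matrix(m)
}

#' Write / read a weight matrix as TSV
#'
#' Four header-labeled rows (A, C, G, T) by n columns of floats.
#'
#' @param M a `weight_matrix`.
#' @param path file path.
#' @return `read_weight_matrix` returns a `weight_matrix` (not
#'   re-normalized: the file is trusted to be on the normalized scale).
#' @export
write_weight_matrix <- function(M, path) {
  df <- data.frame(base = rownames(M), unclass(M), check.names = FALSE)
  colnames(df) <- c("base", paste0("p", seq_len(ncol(M))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), BASES)) stop("expected rows A, C, G, T")
  weight_matrix(m, normalize = FALSE)
}
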