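# Information distance between period frequency matrices, its normal
# transform, and cross-genome unique-repeat counting.

#' Construct a frequency matrix
#'
#' 4 x n non-negative counts f(i, j) of each base i at period position j,
#' extracted from a detected region's alignment (see
#' [frequency_matrix_from_region()]).  The sum of all elements equals the
#' number of matched (non-gap) bases in the alignment.
#'
#' @param counts numeric matrix, 4 rows by n columns, non-negative.
#' @return a `frequency_matrix`.
#' @export
frequency_matrix <- function(counts) {
  if (inherits(counts, "frequency_matrix")) return(counts)
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("frequency matrix must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop("frequency matrix counts must be non-negative")
  storage.mode(counts) <- "double"
  rownames(counts) <- BASES
  colnames(counts) <- NULL
  structure(counts, class = c("frequency_matrix", "matrix", "array"))
}

#' Information distance between two frequency matrices
#'
#' For matrices of equal period length n with counts f_k, f_l and column
#' sums s_k(j), s_l(j):
#'
#'   I = sum f_k ln f_k + sum f_l ln f_l - sum (f_k + f_l) ln(f_k + f_l)
#'     + sum_j [ (s_k + s_l) ln(s_k + s_l) - s_k ln s_k - s_l ln s_l ]
#'
#' with the 0 ln 0 = 0 convention.  I >= 0, I = 0 when the matrices agree,
#' and I is symmetric.  2I is asymptotically chi-square with
#' df = 3(n - 1) when the two matrices come from shuffles of sequences
#' with a common base composition (the shuffle null fixes each matrix's
#' composition, which removes the 3 composition degrees of freedom; an
#' unconstrained per-column multinomial null instead gives df = 3n).
#'
#' @param F_k,F_l [frequency_matrix()] objects of equal period length.
#' @return the distance I (nats, >= 0).
#' @seealso [distance_to_normal()], [matrix_normal_distance()]
#' @export
matrix_distance <- function(F_k, F_l) {
  F_k <- frequency_matrix(F_k)
  F_l <- frequency_matrix(F_l)
  if (ncol(F_k) != ncol(F_l))
    stop("matrices must have equal period length")
  sk <- colSums(F_k)
  sl <- colSums(F_l)
  I <- sum(xlogx(F_k)) + sum(xlogx(F_l)) - sum(xlogx(F_k + F_l)) +
    sum(xlogx(sk + sl) - xlogx(sk) - xlogx(sl))
  max(I, 0)
}

#' Normal approximation of the matrix distance
#'
#' Root transform of the chi-square statistic 2I with df = 3(n - 1):
#'
#'   X = sqrt(4 I) - sqrt(2 df - 1)
#'
#' which is approximately N(0, 1) under the shuffle null (if Y ~ chi^2_k
#' then sqrt(2 Y) is approximately N(sqrt(2k - 1), 1)).
#'
#' @param I distance from [matrix_distance()] (>= 0).
#' @param n period length (>= 2).
#' @return the standard-normal-scale value X.
#' @export
distance_to_normal <- function(I, n) {
  if (n < 2) stop("period length must be at least 2")
  stopifnot(all(I >= 0))
  df <- 3 * (n - 1)
  sqrt(4 * I) - sqrt(2 * df - 1)
}

# cyclic left shift of matrix columns by k
.shift_columns <- function(m, k) {
  n <- ncol(m)
  k <- k %% n
  if (k == 0) return(m)
  m[, c((k + 1):n, 1:k), drop = FALSE]
}

#' Phase-invariant normal distance between two matrices
#'
#' Periods carry arbitrary phase, so the pairwise comparison minimizes the
#' distance over the n cyclic column shifts of the second matrix.
#'
#' @param F_k,F_l [frequency_matrix()] objects of equal period length.
#' @param shifts minimize over cyclic shifts (default TRUE).
#' @return minimal X over the considered alignments of phases.
#' @export
matrix_normal_distance <- function(F_k, F_l, shifts = TRUE) {
  F_k <- frequency_matrix(F_k)
  F_l <- frequency_matrix(F_l)
  n <- ncol(F_k)
  ks <- if (shifts) 0:(n - 1) else 0L
  I_min <- min(vapply(ks, function(k)
    matrix_distance(F_k, .shift_columns(F_l, k)), 0))
  distance_to_normal(I_min, n)
}

#' Randomize a frequency matrix under the shuffle null
#'
#' Emulates "randomly mixing" the underlying periodicity sequence: the
#' matrix's base multiset (total count of each base) is kept fixed and
#' redistributed at random over the period positions, preserving the
#' column sums.  This is the null model under which 2I is chi-square with
#' df = 3(n - 1).
#'
#' @param F a [frequency_matrix()] with integer-valued counts.
#' @param seed optional integer seed.
#' @return a randomized `frequency_matrix` with the same row totals
#'   (base composition) and column sums.
#' @export
randomize_frequency_matrix <- function(F, seed = NULL) {
  F <- frequency_matrix(F)
  draw <- function() {
    bases <- rep.int(1:4, round(rowSums(F)))
    bases <- sample(bases)
    sizes <- round(colSums(F))
    if (sum(sizes) != length(bases))
      stop("column sums and row sums disagree (non-integer counts?)")
    out <- matrix(0, 4, ncol(F))
    at <- 1L
    for (j in seq_len(ncol(F))) {
      if (sizes[j] > 0) {
        chunk <- bases[at:(at + sizes[j] - 1L)]
        out[, j] <- tabulate(chunk, nbins = 4)
        at <- at + sizes[j]
      }
    }
    frequency_matrix(out)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Cross-genome unique-repeat counting
#'
#' For each frequency matrix of set A, computes the phase-invariant
#' normal-scale distance X to every matrix of set B with the same period
#' and keeps the minimum X_k^min.  The survival curve F_k(x) counts
#' A-matrices with X_k^min > x; the null curve Fr_k(x) is built the same
#' way from shuffle-randomized copies of both sets (one per real matrix).
#' The threshold x0 is the smallest grid value where
#' F_k(x0) / Fr_k(x0) > ratio; F_k(x0) is the number of repeats unique to
#' set A (far from everything in B beyond what the null explains).
#'
#' @param matrices_A,matrices_B lists of [frequency_matrix()] objects.
#' @param ratio real/null survival ratio defining x0 (default 20).
#' @param bin grid bin width on the X scale (default 0.05).
#' @param shifts minimize distances over cyclic phase shifts.
#' @param seed integer seed for the null randomization.
#' @return a `uniqueness_report`: list with `x_min` (data.frame of per-A
#'   matrix X_k^min), `null_x_min`, `grid` (x, F_k, Fr_k, ratio), `x0`,
#'   `unique_count`, `found` (FALSE when no grid point satisfies the
#'   ratio; then `unique_count` is 0).
#' @export
unique_repeat_count <- function(matrices_A, matrices_B, ratio = 20,
                                bin = 0.05, shifts = TRUE, seed = 1) {
  stopifnot(length(matrices_A) > 0, length(matrices_B) > 0)
  matrices_A <- lapply(matrices_A, frequency_matrix)
  matrices_B <- lapply(matrices_B, frequency_matrix)
  min_x <- function(A, B) {
    nB <- vapply(B, ncol, 0L)
    vapply(seq_along(A), function(k) {
      partners <- B[nB == ncol(A[[k]])]
      if (!length(partners)) return(NA_real_)
      min(vapply(partners, function(b)
        matrix_normal_distance(A[[k]], b, shifts = shifts), 0))
    }, 0)
  }
  x_min <- min_x(matrices_A, matrices_B)
  if (anyNA(x_min))
    warning(sum(is.na(x_min)),
            " matrices in A have no same-period partner in B; excluded")
  null_A <- lapply(seq_along(matrices_A), function(k)
    randomize_frequency_matrix(matrices_A[[k]], seed = mix_seed(seed, k)))
  null_B <- lapply(seq_along(matrices_B), function(k)
    randomize_frequency_matrix(matrices_B[[k]],
                               seed = mix_seed(seed, 10000 + k)))
  null_x_min <- min_x(null_A, null_B)
  xs_all <- c(x_min, null_x_min)
  xs_all <- xs_all[is.finite(xs_all)]
  grid_x <- seq(floor(min(xs_all) / bin) * bin,
                ceiling(max(xs_all) / bin) * bin, by = bin)
  surv <- function(v, x) sum(v > x, na.rm = TRUE)
  Fk <- vapply(grid_x, function(x) surv(x_min, x), 0)
  Frk <- vapply(grid_x, function(x) surv(null_x_min, x), 0)
  ok <- (Frk > 0 & Fk / Frk > ratio) | (Frk == 0 & Fk > 0)
  found <- any(ok)
  x0 <- if (found) grid_x[which(ok)[1]] else NA_real_
  unique_count <- if (found) Fk[which(ok)[1]] else 0
  structure(list(
    x_min = data.frame(index = seq_along(x_min),
                       n = vapply(matrices_A, ncol, 0L),
                       X_min = x_min),
    null_x_min = null_x_min,
    grid = data.frame(x = grid_x, F_k = Fk, Fr_k = Frk,
                      ratio = ifelse(Frk > 0, Fk / Frk, Inf)),
    x0 = x0, unique_count = unique_count, ratio = ratio, found = found),
    class = "uniqueness_report")
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf(
    "uniqueness_report: %d A-matrices, x0 = %s, unique_count = %d (ratio > %.1f)\n",
    nrow(x$x_min), ifelse(x$found, sprintf("%.2f", x$x0), "not reached"),
    as.integer(x$unique_count), x$ratio))
  invisible(x)
}
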