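# Internal helpers: base coding, seeded evaluation, small numerics.

BASES <- c("A", "C", "G", "T")

# byte -> code lookup; A,C,G,T -> 1..4, N -> 0
.code_lut <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 0L
  lut
})

#' Encode a DNA string as integer base codes
#'
#' A, C, G, T map to 1..4; N maps to 0 (masked: scores zero against every
#' profile column).  Any other symbol is an error; use [read_fasta()] to
#' sanitize arbitrary FASTA alphabets first.
#'
#' @param x single character string over A/C/G/T/N (uppercase).
#' @return integer vector of codes, length `nchar(x)`.
#' @export
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(integer(0))
  codes <- .code_lut[as.integer(charToRaw(x))]
  if (anyNA(codes))
    stop("sequence contains symbols outside A/C/G/T/N")
  codes
}

#' Decode integer base codes back to a DNA string
#' @param codes integer vector (1..4 bases, 0 = N).
#' @return character string.
#' @export
decode_dna <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(c("N", BASES)[codes + 1L], collapse = "")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit child seed from (seed, k); keeps derived seeds
# reproducible across platforms without hashing dependencies.
mix_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 0
  v <- (s * 48271 + as.numeric(k) * 69621 + 1) %% 2147483647
  as.integer(v)
}

# x * log(x) with the 0 log 0 = 0 convention
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Generate a random DNA sequence
#'
#' @param length number of bases.
#' @param composition numeric vector of 4 base frequencies (A,C,G,T);
#'   defaults to uniform.  Normalized internally.
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return character string of `length` bases.
#' @export
random_dna <- function(length, composition = rep(0.25, 4), seed = NULL) {
  stopifnot(length >= 0, length(composition) == 4, all(composition >= 0),
            sum(composition) > 0)
  draw <- function() paste(sample(BASES, length, replace = TRUE,
                                  prob = composition / sum(composition)),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
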