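# Indel-tolerant local alignment of a DNA sequence against the cyclic
# profile of period columns 1..n (the artificial periodic index sequence
# 1,2,...,n,1,2,...,n,... is represented implicitly by the column index
# running modulo n).

#' Affine gap penalties
#'
#' Penalties are on the normalized score scale of [weight_matrix()] (column
#' mean 0, variance 1, so one consensus match is worth about +1.7 on a
#' sharply preferring column).  The defaults were calibrated once for
#' detection power in the latent regime the package targets (about one
#' substitution per base plus a few percent indels): the opening cost is
#' high enough that an alignment tracking the wrong period length - which
#' must gap once per period to stay in register - is suppressed, while the
#' true period's real indels (roughly one per two or three periods at a 5
#' percent indel rate) remain affordable.  See
#' [mean_null_alignment_length()] for the null alignment-length
#' diagnostic.
#'
#' @param gap_open cost of opening a gap (>= 0).
#' @param gap_extend cost of each additional gapped base (>= 0,
#'   <= `gap_open`).
#' @return a `gap_params` list.
#' @export
gap_params <- function(gap_open = 6, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  structure(list(gap_open = gap_open, gap_extend = gap_extend),
            class = "gap_params")
}

#' Local alignment against a cyclic period profile
#'
#' Computes the maximum-score local alignment between a DNA sequence and
#' the cyclic 4 x n profile given by a weight matrix, allowing insertions
#' and deletions with affine penalties (Smith-Waterman-style recurrence
#' with the profile column index running modulo n; the score is floored at
#' 0).  Alignments begin and end with a match step; N bases score 0
#' against every column and never start or end an alignment.
#'
#' @param S character string over A/C/G/T/N, or an integer code vector
#'   from [encode_dna()].
#' @param M a [weight_matrix()] (normalized; plain matrices are
#'   normalized on the way in).
#' @param gaps a [gap_params()].
#' @return a `periodic_alignment`: list with `score` (F_max, >= 0),
#'   `seq_start`/`seq_end` (1-based inclusive, 0 when empty), `phase`
#'   (period column aligned to `seq_start`), `n`, and `path`, a data.frame
#'   with columns `op` ("match", "insertion", "deletion"), `seq_pos`, and
#'   `col` (period column).
#' @seealso [score_periodic()] for the score-only fast path.
#' @export
local_align_periodic <- function(S, M, gaps = gap_params()) {
  codes <- if (is.character(S)) encode_dna(S) else as.integer(S)
  M <- weight_matrix(M)
  res <- cpp_align_periodic(codes, unclass(M), gaps$gap_open, gaps$gap_extend)
  ops <- c("match", "insertion", "deletion")[res$op]
  path <- data.frame(op = ops, seq_pos = res$seq_pos, col = res$col,
                     stringsAsFactors = FALSE)
  mi <- which(path$op == "match")
  structure(list(
    score = res$score,
    seq_start = if (length(mi)) path$seq_pos[mi[1]] else 0L,
    seq_end = if (length(mi)) path$seq_pos[mi[length(mi)]] else 0L,
    phase = if (length(mi)) path$col[mi[1]] else NA_integer_,
    n = ncol(M),
    path = path
  ), class = "periodic_alignment")
}

#' Score-only cyclic-profile alignment
#'
#' Same dynamic program as [local_align_periodic()] without traceback;
#' this is the genetic algorithm's fitness function.
#'
#' @inheritParams local_align_periodic
#' @return the maximum local alignment score F_max (>= 0).
#' @export
score_periodic <- function(S, M, gaps = gap_params()) {
  codes <- if (is.character(S)) encode_dna(S) else as.integer(S)
  cpp_score_periodic(codes, unclass(M), gaps$gap_open, gaps$gap_extend)
}

#' Recompute an alignment score from its path
#'
#' Walks the path, summing matched cell weights and subtracting affine gap
#' costs per maximal insertion/deletion run.  Used to verify that a
#' returned path reproduces `score`.
#'
#' @param aln a `periodic_alignment`.
#' @param S the aligned sequence (string or codes).
#' @param M the weight matrix used.
#' @param gaps the gap penalties used.
#' @return numeric score.
#' @export
rescore_alignment <- function(aln, S, M, gaps = gap_params()) {
  codes <- if (is.character(S)) encode_dna(S) else as.integer(S)
  M <- weight_matrix(M)
  p <- aln$path
  if (nrow(p) == 0L) return(0)
  total <- 0
  run <- ""                                # current gap run type
  for (k in seq_len(nrow(p))) {
    op <- p$op[k]
    if (op == "match") {
      b <- codes[p$seq_pos[k]]
      if (b > 0L) total <- total + M[b, p$col[k]]
      run <- ""
    } else {
      total <- total - if (op == run) gaps$gap_extend else gaps$gap_open
      run <- op
    }
  }
  as.numeric(total)
}

#' @export
print.periodic_alignment <- function(x, ...) {
  cat(sprintf(
    "periodic_alignment: F_max = %.3f, seq [%d, %d], period n = %d, phase %s, %d steps\n",
    x$score, x$seq_start, x$seq_end, x$n,
    ifelse(is.na(x$phase), "NA", x$phase), nrow(x$path)))
  invisible(x)
}

#' Plain-text alignment dump
#'
#' Three-line blocks: sequence characters (gaps as "-"), match bars, and
#' the period column index of each step (mod 10), mirroring a classic
#' alignment-against-periodicity listing.
#'
#' @param aln a `periodic_alignment`.
#' @param S the aligned sequence.
#' @param width characters per block line.
#' @return character vector of lines.
#' @export
format_alignment <- function(aln, S, width = 60) {
  codes <- if (is.character(S)) encode_dna(S) else as.integer(S)
  p <- aln$path
  if (nrow(p) == 0L) return(character(0))
  seq_ch <- ifelse(p$op == "deletion", "-",
                   substring(decode_dna(codes), p$seq_pos, p$seq_pos))
  bar_ch <- ifelse(p$op == "match", "|", " ")
  col_ch <- ifelse(p$op == "insertion", "-", as.character(p$col %% 10))
  out <- character(0)
  for (s in seq(1, nrow(p), by = width)) {
    e <- min(s + width - 1, nrow(p))
    out <- c(out,
             paste0("S  ", paste(seq_ch[s:e], collapse = "")),
             paste0("   ", paste(bar_ch[s:e], collapse = "")),
             paste0("S1 ", paste(col_ch[s:e], collapse = "")),
             "")
  }
  out
}

#' Consensus string from a frequency matrix
#'
#' Per column, the majority base; when the runner-up base exceeds
#' `two_base_fraction` of the column total the two-base ambiguity form
#' "(X/Y)" is emitted, majority base first.  All-zero columns emit "N".
#'
#' @param F a [frequency_matrix()] (4 x n counts).
#' @param two_base_fraction runner-up fraction triggering the ambiguity
#'   form (default 1/3).
#' @return consensus string, e.g. `"CACAGTCTCAA(T/G)"`.
#' @export
consensus_from_matrix <- function(F, two_base_fraction = 1/3) {
  F <- frequency_matrix(F)
  out <- character(ncol(F))
  for (j in seq_len(ncol(F))) {
    cj <- F[, j]
    tot <- sum(cj)
    if (tot == 0) { out[j] <- "N"; next }
    ord <- order(cj, decreasing = TRUE)
    if (cj[ord[2]] > two_base_fraction * tot)
      out[j] <- sprintf("(%s/%s)", BASES[ord[1]], BASES[ord[2]])
    else out[j] <- BASES[ord[1]]
  }
  paste(out, collapse = "")
}
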