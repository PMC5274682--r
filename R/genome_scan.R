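# Sliding-window scanning protocol: windowing, triplet filtering,
# spectrum search, thresholding, overlap resolution, and region-set
# comparison by fractional overlap.

#' Scanning configuration
#'
#' Defaults follow the scanning protocol: 600-nt windows shifted by
#' 200 bp, period lengths 2..50, triplet skip threshold Z > 3.0, and a
#' score threshold F0.  The shipped F0 default of 390.0 is meaningful
#' only on the score scale it was calibrated on; calibrate your own with
#' [calibrate_threshold()] for the package's normalized scale.
#'
#' @param window window length in bases.
#' @param step window shift in bases (<= window).
#' @param n_min,n_max tested period lengths.
#' @param F0 score threshold for emitting a region.
#' @param z_skip windows with triplet Z above this are skipped.
#' @param ga a [ga_config()].
#' @param gaps a [gap_params()].
#' @return a `scan_config` list.
#' @export
scan_config <- function(window = 600, step = 200, n_min = 2, n_max = 50,
                        F0 = 390.0, z_skip = 3.0, ga = ga_config(),
                        gaps = gap_params()) {
  stopifnot(window >= 1, step >= 1, step <= window,
            n_min >= 2, n_min <= n_max, n_max <= window)
  structure(list(window = as.integer(window), step = as.integer(step),
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 F0 = F0, z_skip = z_skip, ga = ga, gaps = gaps),
            class = "scan_config")
}

#' Enumerate scan windows
#'
#' Full-length windows only, starting at 1, 1 + step, ...; a sequence
#' shorter than one window yields none.
#'
#' @param S DNA string, or an integer sequence length.
#' @param cfg a [scan_config()].
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @export
iter_windows <- function(S, cfg = scan_config()) {
  N <- if (is.character(S)) nchar(S) else as.integer(S)
  if (N < cfg$window)
    return(data.frame(start = integer(0), end = integer(0)))
  k <- (N - cfg$window) %/% cfg$step + 1L
  start <- 1L + (seq_len(k) - 1L) * cfg$step
  data.frame(start = start, end = start + cfg$window - 1L)
}

#' Scan sequences for periodic regions
#'
#' For every window of every record: windows with triplet-periodicity
#' Z > `z_skip` are skipped (protein-coding-like); otherwise the
#' periodicity spectrum over `n_min..n_max` is computed and windows whose
#' spectrum maximum reaches `F0` yield a candidate region.  A candidate's
#' coordinates are the local-alignment span mapped to the genome (regions
#' are usually shorter than the window); its period is the spectrum
#' argmax.  Intersecting candidates are resolved by
#' [merge_overlapping()].  All randomness derives from `seed`, so
#' identical inputs give identical region lists.
#'
#' @param sequences named character vector of DNA strings (see
#'   [read_fasta()]), or a single string.
#' @param cfg a [scan_config()].
#' @param seed integer master seed (default `cfg$ga$seed`).
#' @return a `periodic_regions` object: a list of regions, each carrying
#'   `seq_id`, `start`, `end`, `n`, `mF_max`, `triplet_Z`, `matrix`,
#'   `freq`, `consensus`, `alignment` (window-local coordinates),
#'   `window_start`, and `seq` (the window's sequence).  Coerce with
#'   `as.data.frame()`.
#' @export
scan_periodicity <- function(sequences, cfg = scan_config(),
                             seed = cfg$ga$seed) {
  if (is.null(names(sequences)))
    names(sequences) <- if (length(sequences) == 1L) "seq1"
      else paste0("seq", seq_along(sequences))
  all_regions <- list()
  for (si in seq_along(sequences)) {
    id <- names(sequences)[si]
    S <- sequences[[si]]
    if (nchar(S) == 0L) {
      warning("skipping zero-length record '", id, "'")
      next
    }
    wins <- iter_windows(S, cfg)
    candidates <- list()
    for (w in seq_len(nrow(wins))) {
      win_seq <- substr(S, wins$start[w], wins$end[w])
      tz <- if (nchar(win_seq) >= 30L) triplet_z(win_seq)
            else list(Z = NA_real_)     # too short for the triplet model
      if (!is.na(tz$Z) && tz$Z > cfg$z_skip) next
      cfg_w <- cfg$ga
      cfg_w$seed <- mix_seed(seed, si * 131071 + w)
      spec <- periodicity_spectrum(win_seq, cfg$n_min, cfg$n_max,
                                   cfg = cfg_w, gaps = cfg$gaps)
      if (is.na(spectrum_max(spec)) || spectrum_max(spec) < cfg$F0) next
      best <- spec$results[[as.character(spectrum_argmax(spec))]]
      aln <- best$alignment
      if (aln$seq_end == 0L) next
      freq <- frequency_matrix_from_alignment(aln, win_seq)
      candidates[[length(candidates) + 1L]] <- structure(list(
        seq_id = id,
        start = wins$start[w] + aln$seq_start - 1L,
        end = wins$start[w] + aln$seq_end - 1L,
        n = best$n,
        mF_max = best$mF_max,
        triplet_Z = tz$Z,
        matrix = best$matrix,
        freq = freq,
        consensus = consensus_from_matrix(freq),
        alignment = aln,
        window_start = wins$start[w],
        seq = win_seq), class = "periodic_region")
    }
    all_regions <- c(all_regions, merge_overlapping(candidates))
  }
  structure(all_regions, class = "periodic_regions")
}

#' Resolve intersecting candidate regions
#'
#' Among any set of mutually intersecting candidates (>= 1 shared base on
#' the same record) the kept set is chosen greedily by descending mF_max;
#' ties prefer the smaller start, then the smaller period.
#'
#' @param candidates list of `periodic_region` objects.
#' @return list of pairwise non-intersecting regions, sorted by
#'   (seq_id, start).
#' @export
merge_overlapping <- function(candidates) {
  if (length(candidates) <= 1L) return(candidates)
  f <- vapply(candidates, `[[`, 0, "mF_max")
  s <- vapply(candidates, function(r) as.numeric(r$start), 0)
  e <- vapply(candidates, function(r) as.numeric(r$end), 0)
  n <- vapply(candidates, function(r) as.numeric(r$n), 0)
  id <- vapply(candidates, `[[`, "", "seq_id")
  ord <- order(-f, s, n)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(id[kept] == id[i] & s[kept] <= e[i] & e[kept] >= s[i])
    if (!clash) kept <- c(kept, i)
  }
  kept <- kept[order(id[kept], s[kept])]
  candidates[kept]
}

#' Frequency matrix from an alignment
#'
#' Tallies each matched base of the alignment into its period column;
#' insertion and deletion steps (and masked N matches) contribute
#' nothing, so the total count equals the number of matched A/C/G/T
#' bases: the aligned length minus the bases inside indel regions.
#'
#' @param aln a `periodic_alignment`.
#' @param S the sequence the alignment was computed on.
#' @return a [frequency_matrix()] of size 4 x n.
#' @export
frequency_matrix_from_alignment <- function(aln, S) {
  codes <- if (is.character(S)) encode_dna(S) else as.integer(S)
  counts <- matrix(0, 4, aln$n)
  p <- aln$path
  if (nrow(p)) {
    m <- p[p$op == "match", , drop = FALSE]
    b <- codes[m$seq_pos]
    keep <- b > 0L
    if (any(keep))
      for (k in which(keep))
        counts[b[k], m$col[k]] <- counts[b[k], m$col[k]] + 1
  }
  frequency_matrix(counts)
}

#' @rdname frequency_matrix_from_alignment
#' @param region a `periodic_region` from [scan_periodicity()].
#' @export
frequency_matrix_from_region <- function(region) {
  frequency_matrix_from_alignment(region$alignment, region$seq)
}

#' @method as.data.frame periodic_regions
#' @export
as.data.frame.periodic_regions <- function(x, ...) {
  if (!length(x))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      mF_max = numeric(0), triplet_Z = numeric(0),
                      consensus = character(0)))
  data.frame(
    seq_id = vapply(x, `[[`, "", "seq_id"),
    start = vapply(x, function(r) as.integer(r$start), 0L),
    end = vapply(x, function(r) as.integer(r$end), 0L),
    period = vapply(x, function(r) as.integer(r$n), 0L),
    mF_max = vapply(x, `[[`, 0, "mF_max"),
    triplet_Z = vapply(x, `[[`, 0, "triplet_Z"),
    consensus = vapply(x, `[[`, "", "consensus"),
    stringsAsFactors = FALSE)
}

#' @export
print.periodic_regions <- function(x, ...) {
  cat(sprintf("periodic_regions: %d regions\n", length(x)))
  if (length(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Compare two region sets by fractional overlap
#'
#' A region `a` of set A is matched when some region of set B on the same
#' record overlaps it by at least `min_fraction` of a's own length
#' (inclusive at the boundary); period lengths are ignored.  Counts are
#' returned in both directions.
#'
#' @param set_A,set_B `periodic_regions` objects or data.frames with
#'   columns `seq_id`, `start`, `end` (1-based inclusive).
#' @param min_fraction minimum overlap fraction (default 0.3).
#' @return a `comparison_counts`: list with `matched_A`, `total_A`,
#'   `matched_B`, `total_B`, `min_overlap_fraction`.
#' @export
overlap_compare <- function(set_A, set_B, min_fraction = 0.3) {
  A <- if (is.data.frame(set_A)) set_A else as.data.frame(set_A)
  B <- if (is.data.frame(set_B)) set_B else as.data.frame(set_B)
  if (nrow(A) && nrow(B) &&
      !length(intersect(unique(A$seq_id), unique(B$seq_id))))
    warning("region sets share no seq_id; zero matches")
  matched <- function(Q, T) {
    if (!nrow(Q)) return(0L)
    sum(vapply(seq_len(nrow(Q)), function(i) {
      t <- T[T$seq_id == Q$seq_id[i], , drop = FALSE]
      if (!nrow(t)) return(FALSE)
      ov <- pmin(t$end, Q$end[i]) - pmax(t$start, Q$start[i]) + 1
      any(ov >= min_fraction * (Q$end[i] - Q$start[i] + 1))
    }, NA))
  }
  structure(list(matched_A = matched(A, B), total_A = nrow(A),
                 matched_B = matched(B, A), total_B = nrow(B),
                 min_overlap_fraction = min_fraction),
            class = "comparison_counts")
}

#' @export
print.comparison_counts <- function(x, ...) {
  cat(sprintf(
    "comparison_counts: A %d/%d matched, B %d/%d matched (>= %.0f%% overlap)\n",
    x$matched_A, x$total_A, x$matched_B, x$total_B,
    100 * x$min_overlap_fraction))
  invisible(x)
}
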