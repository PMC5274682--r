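# Chromosomal density of periodicity scores: sum of mF_max per fixed-size
# bin along a sequence.

#' Density profile of summed periodicity scores
#'
#' Partitions `[1, seq_length]` into bins of `bin_size` bases and sums the
#' mF_max of the profiled regions per bin.  By default a region
#' contributes its full score to the bin containing its start coordinate;
#' `method = "split"` instead distributes the score over the bins the
#' region covers, proportionally to the covered length.  Either way the
#' bin totals conserve the summed mF_max.
#'
#' @param regions a `periodic_regions` object or data.frame with columns
#'   `seq_id`, `start`, `end`, `mF_max`.
#' @param bin_size bin width in bases (default 1e5).
#' @param seq_length length of the profiled sequence; regions beyond it
#'   are an error.
#' @param seq_id record to profile; defaults to the single record present.
#' @param method `"start"` (default) or `"split"`.
#' @return a `density_profile`: data.frame with columns `bin`, `start`,
#'   `end`, `sum_fmax`, with the bin size and seq_id as attributes.
#' @export
sum_fmax_profile <- function(regions, bin_size = 1e5, seq_length,
                             seq_id = NULL, method = c("start", "split")) {
  method <- match.arg(method)
  df <- if (is.data.frame(regions)) regions else as.data.frame(regions)
  stopifnot(bin_size > 0, seq_length >= 1)
  if (is.null(seq_id)) {
    ids <- unique(df$seq_id)
    if (length(ids) > 1)
      stop("regions span several records; pass seq_id explicitly")
    seq_id <- if (length(ids)) ids else "seq1"
  }
  df <- df[df$seq_id == seq_id, , drop = FALSE]
  if (nrow(df) && (any(df$start < 1) || any(df$end > seq_length)))
    stop("region coordinates fall outside [1, seq_length]")
  nb <- as.integer(ceiling(seq_length / bin_size))
  totals <- numeric(nb)
  if (nrow(df)) {
    if (method == "start") {
      b <- (df$start - 1) %/% bin_size + 1
      for (i in seq_len(nrow(df))) totals[b[i]] <- totals[b[i]] + df$mF_max[i]
    } else {
      for (i in seq_len(nrow(df))) {
        len <- df$end[i] - df$start[i] + 1
        b1 <- (df$start[i] - 1) %/% bin_size + 1
        b2 <- (df$end[i] - 1) %/% bin_size + 1
        for (b in b1:b2) {
          lo <- max(df$start[i], (b - 1) * bin_size + 1)
          hi <- min(df$end[i], b * bin_size)
          totals[b] <- totals[b] + df$mF_max[i] * (hi - lo + 1) / len
        }
      }
    }
  }
  out <- data.frame(bin = seq_len(nb),
                    start = (seq_len(nb) - 1) * bin_size + 1,
                    end = pmin(seq_len(nb) * bin_size, seq_length),
                    sum_fmax = totals)
  structure(out, class = c("density_profile", "data.frame"),
            bin_size = bin_size, seq_id = seq_id)
}

#' Write a density profile as bedGraph
#'
#' 0-based half-open intervals, one line per bin.
#'
#' @param profile a `density_profile`.
#' @param path output file.
#' @export
write_bedgraph <- function(profile, path) {
  lines <- sprintf("%s\t%d\t%d\t%g", attr(profile, "seq_id"),
                   profile$start - 1L, profile$end, profile$sum_fmax)
  writeLines(lines, path)
  invisible(path)
}
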