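# Simulator of latent tandem periodicity: a consensus repeated in tandem,
# degraded by substitutions (possibly > 1 per base, so identity to the
# consensus saturates toward 25%) and by short insertions/deletions, then
# embedded in random background at a known position.

#' Specification of a latent-periodicity implant
#'
#' @param consensus period consensus string over A/C/G/T (its length is
#'   the true period).
#' @param copies number of tandem copies (>= 1).
#' @param substitution_rate expected substitution events per nucleotide of
#'   the array.  Events are applied in sequence to random positions, so a
#'   base can mutate more than once; at rate 1.0 the array is in the
#'   latent regime where no two periods retain significant pairwise
#'   similarity.
#' @param indel_rate expected indel events per nucleotide.
#' @param indel_max_len maximal indel length; event lengths are uniform on
#'   1..indel_max_len (default 3).
#' @param background_length total length of the emitted sequence; the
#'   mutated array overwrites a random interval of the background and
#'   must fit inside it.
#' @param background_composition base frequencies of the background.
#' @param seed integer seed; the simulation is fully reproducible.
#' @return an `implant_spec` list.
#' @export
implant_spec <- function(consensus, copies, substitution_rate = 1.0,
                         indel_rate = 0.05, indel_max_len = 3,
                         background_length = NULL,
                         background_composition = rep(0.25, 4), seed = 1) {
  codes <- encode_dna(consensus)
  if (any(codes == 0L)) stop("consensus may not contain N")
  stopifnot(copies >= 1, substitution_rate >= 0, indel_rate >= 0,
            indel_max_len >= 1)
  if (is.null(background_length))
    background_length <- length(codes) * copies + 200L
  structure(list(consensus = consensus, copies = as.integer(copies),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_max_len = as.integer(indel_max_len),
                 background_length = as.integer(background_length),
                 background_composition = background_composition,
                 seed = as.integer(seed)),
            class = "implant_spec")
}

#' Simulate a latent periodic sequence with known truth
#'
#' Builds consensus x copies, applies Poisson(rate x length) substitution
#' events (each replaces the current base at a uniformly chosen position
#' with a uniformly chosen different base), then Poisson(indel_rate x
#' length) indel events (insertion or deletion equiprobable, length
#' uniform on 1..indel_max_len; insertions draw background bases), and
#' embeds the result at a seeded random offset inside random background.
#'
#' @param spec an [implant_spec()].
#' @return list with `sequence` (the emitted DNA string) and `truth`, a
#'   list with `implant_start`, `implant_end` (1-based inclusive),
#'   `true_period`, `implant_length`, and realized `substitutions`,
#'   `insertions`, `deletions` (event counts).
#' @export
simulate_latent_periodic <- function(spec) {
  stopifnot(inherits(spec, "implant_spec"))
  with_seed(spec$seed, {
    unit <- encode_dna(spec$consensus)
    arr <- rep.int(unit, spec$copies)
    L0 <- length(arr)
    n_sub <- rpois(1, spec$substitution_rate * L0)
    if (n_sub > 0) {
      pos <- sample.int(L0, n_sub, replace = TRUE)
      for (p in pos) {
        others <- setdiff(1:4, arr[p])
        arr[p] <- others[sample.int(3L, 1)]
      }
    }
    n_ind <- rpois(1, spec$indel_rate * L0)
    n_ins <- 0L; n_del <- 0L
    comp <- spec$background_composition / sum(spec$background_composition)
    if (n_ind > 0) for (k in seq_len(n_ind)) {
      len <- sample.int(spec$indel_max_len, 1)
      if (runif(1) < 0.5) {             # insertion
        at <- sample.int(length(arr) + 1L, 1)
        ins <- sample.int(4L, len, replace = TRUE, prob = comp)
        arr <- append(arr, ins, after = at - 1L)
        n_ins <- n_ins + 1L
      } else {                          # deletion
        if (length(arr) <= len) next
        at <- sample.int(length(arr) - len + 1L, 1)
        arr <- arr[-(at:(at + len - 1L))]
        n_del <- n_del + 1L
      }
    }
    L <- length(arr)
    if (spec$background_length < L)
      stop("background shorter than the (mutated) implant")
    bg <- sample.int(4L, spec$background_length, replace = TRUE, prob = comp)
    offset <- sample.int(spec$background_length - L + 1L, 1) - 1L
    bg[(offset + 1L):(offset + L)] <- arr
    list(sequence = decode_dna(bg),
         truth = list(implant_start = offset + 1L,
                      implant_end = offset + L,
                      true_period = length(unit),
                      implant_length = L,
                      substitutions = n_sub,
                      insertions = n_ins,
                      deletions = n_del))
  })
}

#' Write a benchmark fixture set
#'
#' Simulates one record per (spec row, seed), writing a multi-record
#' FASTA, a truth BED (0-based half-open, name = the true period) and a
#' manifest TSV holding the full grid plus realized event counts and
#' coordinates.  Deterministic per master seed.
#'
#' @param grid data.frame with columns `consensus` (or `period`, in which
#'   case a random consensus of that length is drawn per row), `copies`,
#'   `substitution_rate`, `indel_rate`; optional `indel_max_len`,
#'   `background_length`.
#' @param out_dir output directory (created).
#' @param n_seeds replicate seeds per grid row.
#' @param seed master seed.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) list with `fasta`, `bed`, `manifest` paths and the
#'   manifest data.frame.
#' @export
make_benchmark <- function(grid, out_dir, n_seeds = 3, seed = 1,
                           overwrite = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  paths <- file.path(out_dir, c("benchmark.fasta", "truth.bed",
                                "manifest.tsv"))
  if (any(file.exists(paths)) && !overwrite)
    stop("benchmark files exist in '", out_dir, "'; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); seqs <- character(0); beds <- character(0)
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(n_seeds)) {
      rec_seed <- mix_seed(seed, g * 1000 + r)
      consensus <- if ("consensus" %in% names(grid) &&
                       !is.na(grid$consensus[g])) grid$consensus[g]
        else random_dna(grid$period[g], seed = mix_seed(rec_seed, 7))
      sp <- implant_spec(
        consensus = consensus,
        copies = grid$copies[g],
        substitution_rate = grid$substitution_rate[g],
        indel_rate = grid$indel_rate[g],
        indel_max_len = if ("indel_max_len" %in% names(grid))
          grid$indel_max_len[g] else 3,
        background_length = if ("background_length" %in% names(grid))
          grid$background_length[g] else NULL,
        seed = rec_seed)
      sim <- simulate_latent_periodic(sp)
      id <- sprintf("implant_g%d_r%d_p%d", g, r, nchar(consensus))
      seqs[id] <- sim$sequence
      tr <- sim$truth
      beds <- c(beds, sprintf("%s\t%d\t%d\t%d\t0\t+", id,
                              tr$implant_start - 1L, tr$implant_end,
                              tr$true_period))
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, grid_row = g, replicate = r, seed = rec_seed,
        consensus = consensus, period = nchar(consensus),
        copies = grid$copies[g],
        substitution_rate = grid$substitution_rate[g],
        indel_rate = grid$indel_rate[g],
        implant_start = tr$implant_start, implant_end = tr$implant_end,
        implant_length = tr$implant_length,
        substitutions = tr$substitutions, insertions = tr$insertions,
        deletions = tr$deletions,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_fasta(seqs, paths[1])
  writeLines(beds, paths[2])
  write.table(manifest, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(fasta = paths[1], bed = paths[2], manifest = paths[3],
                 manifest_df = manifest))
}

#' Read a benchmark manifest
#' @param path manifest TSV written by [make_benchmark()].
#' @return data.frame.
#' @export
read_benchmark_manifest <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
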