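# Genetic-algorithm optimization of the period weight matrix.  Organisms
# are normalized 4 x n weight matrices; fitness is the cyclic-profile
# local alignment score F_max of the sequence under the organism.

#' Genetic algorithm configuration
#'
#' @param population_size organisms per generation (>= 2).
#' @param elite_fraction fraction carried over unchanged each generation
#'   (at least one organism).
#' @param crossover_rate probability a child is produced by column-block
#'   exchange between two parents (otherwise it is a copy of one parent).
#' @param mutation_rate per-cell probability of a Gaussian perturbation.
#' @param mutation_sigma standard deviation of the perturbation.
#' @param plateau_generations stop after this many generations without
#'   improvement of the best fitness.
#' @param max_generations hard cap on generations.
#' @param restarts independent GA runs; the best result is kept.
#' @param refine inject one profile re-estimation candidate per
#'   generation: the normalized frequency matrix of the current best
#'   organism's own alignment.  This matrix-from-alignment reinforcement
#'   accelerates convergence sharply at true periods (default TRUE).
#' @param seed integer seed; every stage of the search derives its
#'   randomness from it, so identical inputs give identical results.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 40, elite_fraction = 0.1,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      mutation_sigma = 0.5, plateau_generations = 30,
                      max_generations = 500, restarts = 1, refine = TRUE,
                      seed = 1) {
  stopifnot(population_size >= 2,
            elite_fraction > 0, elite_fraction < 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_sigma >= 0,
            plateau_generations >= 1, max_generations >= 1, restarts >= 1)
  structure(list(population_size = as.integer(population_size),
                 elite_fraction = elite_fraction,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sigma = mutation_sigma,
                 plateau_generations = as.integer(plateau_generations),
                 max_generations = as.integer(max_generations),
                 restarts = as.integer(restarts),
                 refine = isTRUE(refine),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# one seeded GA run; codes already encoded, returns best matrix/fitness/trace
.ga_run <- function(codes, n, cfg, gaps) {
  ps <- cfg$population_size
  elite_k <- max(1L, as.integer(round(cfg$elite_fraction * ps)))
  score1 <- function(M) cpp_score_periodic(codes, M, gaps$gap_open,
                                           gaps$gap_extend)
  pop <- lapply(seq_len(ps), function(i)
    unclass(weight_matrix(matrix(rnorm(4 * n), nrow = 4))))
  fit <- vapply(pop, score1, 0)
  best_i <- which.max(fit)
  best_fit <- fit[best_i]
  best_mat <- pop[[best_i]]
  trace <- numeric(0)
  stall <- 0L
  gen <- 0L
  while (gen < cfg$max_generations) {
    gen <- gen + 1L
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(elite_k)]]
    newfit <- fit[ord[seq_len(elite_k)]]
    while (length(newpop) < ps) {
      # binary tournament selection
      pick <- function() {
        c2 <- sample.int(ps, 2)
        pop[[c2[which.max(fit[c2])]]]
      }
      child <- pick()
      if (runif(1) < cfg$crossover_rate && n >= 2) {
        other <- pick()
        cut <- sample.int(n - 1L, 1)
        child <- cbind(child[, seq_len(cut), drop = FALSE],
                       other[, (cut + 1L):n, drop = FALSE])
      }
      mask <- runif(4 * n) < cfg$mutation_rate
      if (any(mask))
        child[mask] <- child[mask] + rnorm(sum(mask), 0, cfg$mutation_sigma)
      child <- unclass(weight_matrix(child))
      newpop[[length(newpop) + 1L]] <- child
      newfit <- c(newfit, score1(child))
    }
    pop <- newpop
    fit <- newfit
    if (cfg$refine) {
      # profile re-estimation: matrix -> alignment -> frequency -> matrix
      tb <- cpp_align_periodic(codes, best_mat, gaps$gap_open,
                               gaps$gap_extend)
      mm <- tb$op == 1L
      if (any(mm)) {
        b <- codes[tb$seq_pos[mm]]
        cl <- tb$col[mm]
        keep <- b > 0L
        fm <- matrix(0, 4, n)
        if (any(keep)) {
          idx <- cbind(b[keep], cl[keep])
          for (k in seq_len(nrow(idx)))
            fm[idx[k, 1], idx[k, 2]] <- fm[idx[k, 1], idx[k, 2]] + 1
          cand <- unclass(weight_matrix(fm))
          wi <- which.min(fit)
          pop[[wi]] <- cand
          fit[wi] <- score1(cand)
        }
      }
    }
    gi <- which.max(fit)
    if (fit[gi] > best_fit + 1e-9) {
      best_fit <- fit[gi]
      best_mat <- pop[[gi]]
      stall <- 0L
    } else stall <- stall + 1L
    trace <- c(trace, best_fit)
    if (stall >= cfg$plateau_generations) break
  }
  list(matrix = best_mat, fitness = best_fit, trace = trace,
       generations = gen)
}

#' Optimize the weight matrix for one period length
#'
#' Runs the genetic algorithm for period `n` on sequence `S`: random
#' normalized matrices, fitness by [score_periodic()], elitist selection
#' with binary tournaments, single-cut column-block crossover, per-cell
#' Gaussian mutation followed by re-normalization, stopping on a fitness
#' plateau.  The best organism ever seen is returned together with its
#' full traceback alignment.
#'
#' @param S DNA string or integer codes.
#' @param n period length, `2 <= n <= min(100, nchar(S))`.
#' @param cfg a [ga_config()].
#' @param gaps a [gap_params()].
#' @return an `optimization_result`: list with `n`, `matrix` (the optimal
#'   [weight_matrix()] M0), `mF_max`, `alignment` (a
#'   `periodic_alignment`), `fitness_trace` (best fitness per generation,
#'   non-decreasing), and `generations`.
#' @export
ga_optimize <- function(S, n, cfg = ga_config(), gaps = gap_params()) {
  codes <- if (is.character(S)) encode_dna(S) else as.integer(S)
  n <- as.integer(n)
  if (n < 2L || n > 100L) stop("period length n must be in 2..100")
  if (n > length(codes)) stop("period length n exceeds sequence length")
  if (all(codes == 0L)) {
    empty <- local_align_periodic(integer(0), random_weight_matrix(n, seed = 0),
                                  gaps)
    return(structure(list(n = n, matrix = random_weight_matrix(n, seed = 0),
                          mF_max = 0, alignment = empty,
                          fitness_trace = 0, generations = 0L),
                     class = "optimization_result"))
  }
  runs <- lapply(seq_len(cfg$restarts), function(r)
    with_seed(mix_seed(cfg$seed, 1000 + r), .ga_run(codes, n, cfg, gaps)))
  best <- runs[[which.max(vapply(runs, `[[`, 0, "fitness"))]]
  M0 <- weight_matrix(best$matrix, normalize = FALSE)
  aln <- local_align_periodic(codes, M0, gaps)
  structure(list(n = n, matrix = M0, mF_max = best$fitness,
                 alignment = aln, fitness_trace = best$trace,
                 generations = best$generations),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("optimization_result: n = %d, mF_max = %.3f (%d generations)\n",
              x$n, x$mF_max, x$generations))
  invisible(x)
}

#' Periodicity spectrum mF_max(n)
#'
#' One independent, deterministically re-seeded [ga_optimize()] per tested
#' period length.  Failures for individual periods are recorded in the
#' table rather than aborting the sweep.
#'
#' @param S DNA string or integer codes.
#' @param n_min,n_max period range (defaults 2 and 50).
#' @param cfg a [ga_config()]; the per-period seed is derived from
#'   `cfg$seed` and `n`.
#' @param gaps a [gap_params()].
#' @param periods explicit period set overriding `n_min:n_max`.
#' @return a `periodicity_spectrum`: list with `results` (named list of
#'   `optimization_result`s) and `table` (data.frame n, mF_max,
#'   generations, seed, error).
#' @export
periodicity_spectrum <- function(S, n_min = 2, n_max = 50,
                                 cfg = ga_config(), gaps = gap_params(),
                                 periods = NULL) {
  if (is.null(periods)) {
    stopifnot(n_min >= 2, n_min <= n_max)
    periods <- seq.int(n_min, n_max)
  }
  periods <- as.integer(periods)
  results <- vector("list", length(periods))
  names(results) <- as.character(periods)
  tab <- data.frame(n = periods, mF_max = NA_real_,
                    generations = NA_integer_, seed = NA_integer_,
                    error = NA_character_)
  for (k in seq_along(periods)) {
    n <- periods[k]
    cfg_n <- cfg
    cfg_n$seed <- mix_seed(cfg$seed, n)
    tab$seed[k] <- cfg_n$seed
    res <- tryCatch(ga_optimize(S, n, cfg_n, gaps), error = identity)
    if (inherits(res, "error")) {
      tab$error[k] <- conditionMessage(res)
    } else {
      results[[k]] <- res
      tab$mF_max[k] <- res$mF_max
      tab$generations[k] <- res$generations
    }
  }
  structure(list(results = results, table = tab),
            class = "periodicity_spectrum")
}

#' @method as.data.frame periodicity_spectrum
#' @export
as.data.frame.periodicity_spectrum <- function(x, ...) x$table

#' @export
print.periodicity_spectrum <- function(x, ...) {
  ok <- !is.na(x$table$mF_max)
  cat(sprintf("periodicity_spectrum: %d periods", nrow(x$table)))
  if (any(ok)) {
    k <- spectrum_argmax(x)
    cat(sprintf(", max mF_max = %.3f at n = %d",
                max(x$table$mF_max[ok]), k))
  }
  cat("\n")
  invisible(x)
}

#' Period attaining the spectrum maximum
#'
#' @param spectrum a `periodicity_spectrum`.
#' @return integer period; ties resolved toward the smaller period.
#' @export
spectrum_argmax <- function(spectrum) {
  tab <- spectrum$table
  ok <- !is.na(tab$mF_max)
  if (!any(ok)) return(NA_integer_)
  tab <- tab[ok, ]
  tab$n[which.max(tab$mF_max)]
}

#' Spectrum maximum score
#' @param spectrum a `periodicity_spectrum`.
#' @return maximum mF_max over tested periods.
#' @export
spectrum_max <- function(spectrum) {
  v <- spectrum$table$mF_max
  if (all(is.na(v))) return(NA_real_)
  max(v, na.rm = TRUE)
}

#' Write a periodicity spectrum as TSV
#' @param spectrum a `periodicity_spectrum`.
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(spectrum$table[, c("n", "mF_max", "generations", "seed")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
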