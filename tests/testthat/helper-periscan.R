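# Shared test fixtures: a small GA configuration sized for test runtime,
# an independent alignment oracle, and the synthetic benchmark harness.

# GA budget used throughout the tests; convergence checks in the suite
# use these sizes, documented in the methods vignette.
fast_cfg <- function(seed = 1, restarts = 1)
  ga_config(population_size = 20, elite_fraction = 0.1,
            plateau_generations = 8, max_generations = 50,
            restarts = restarts, seed = seed)

# Independent oracle for the cyclic-profile DP: textbook affine-gap
# Smith-Waterman over an explicitly unrolled periodic profile.  The
# profile is unrolled to (N + 2) * n columns: a local alignment may start
# at any column (covering every phase) and between consecutive matches a
# useful deletion run is shorter than n, so N * n + n columns bound any
# optimal path.
sw_unrolled <- function(codes, M, open, ext) {
  N <- length(codes)
  if (N == 0) return(0)
  n <- ncol(M)
  L <- (N + 2) * n
  prof <- M[, ((seq_len(L) - 1) %% n) + 1, drop = FALSE]
  H <- matrix(-Inf, N + 1, L + 1); E <- H; F <- H
  best <- 0
  for (i in 1:N) for (j in 1:L) {
    sc <- if (codes[i] > 0) prof[codes[i], j] else 0
    H[i + 1, j + 1] <- sc + max(0, H[i, j], E[i, j], F[i, j])
    E[i + 1, j + 1] <- max(H[i, j + 1] - open, E[i, j + 1] - ext)
    F[i + 1, j + 1] <- max(H[i + 1, j] - open, F[i + 1, j] - ext)
    if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
  }
  best
}

# One cell of the latent-periodicity recovery benchmark: simulate an
# implant at the study conditions (1.0 substitutions per base, 5% indel
# events per base), identify its period by shuffle-null significance,
# and score success as "true period or an integer multiple or divisor".
bench_recovery_run <- function(i, period) {
  copies <- if (period <= 12) round(1320 / period) else 40L
  sp <- implant_spec(random_dna(period, seed = 100 + i), copies = copies,
                     substitution_rate = 1.0, indel_rate = 0.05,
                     background_length = period * copies + 100,
                     seed = 200 + i)
  sim <- simulate_latent_periodic(sp)
  periods <- if (period <= 12) 2:14 else 2:40
  sel <- select_period(sim$sequence, periods,
                       cfg = fast_cfg(seed = 300 + i, restarts = 2),
                       null_reps = 4)
  found <- sel$period
  list(found = found,
       ok = (found %% period == 0) || (period %% found == 0))
}

# frequency matrix filled from explicit per-column counts (A,C,G,T rows)
fmat <- function(...) frequency_matrix(cbind(...))
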