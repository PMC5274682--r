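# Shuffle-null significance: null score distribution F_r, normal-model
# p-values, and false-positive-rate calibration of the score threshold F0.

#' Shuffle a sequence
#'
#' Uniform random permutation of the residues ("randomly mixed" sequence):
#' base composition and length are preserved.
#'
#' @param S DNA string.
#' @param seed optional integer seed for a reproducible permutation.
#' @return shuffled DNA string.
#' @export
shuffle_sequence <- function(S, seed = NULL) {
  codes <- encode_dna(S)
  if (length(codes) < 1L) stop("cannot shuffle an empty sequence")
  draw <- function() decode_dna(sample(codes))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Null statistics of the optimized score on shuffled sequences
#'
#' Runs the full matrix optimization ([ga_optimize()]) at period `n` on
#' `n_shuffles` independent seeded shuffles of `S` and summarizes the
#' resulting null scores F_r: these are the mean and sigma behind the
#' normal-model p-value of an observed mF_max.
#'
#' @param S DNA string.
#' @param n period length.
#' @param n_shuffles number of shuffles (>= 2).
#' @param cfg a [ga_config()]; shuffle and GA seeds derive from `cfg$seed`.
#' @param gaps a [gap_params()].
#' @return a `shuffle_stats`: list with `n`, `n_shuffles`, `mean_Fr`,
#'   `sigma_Fr`, `samples`, `source_length`.
#' @export
null_stats <- function(S, n, n_shuffles = 100, cfg = ga_config(),
                       gaps = gap_params()) {
  if (n_shuffles < 2) stop("need at least 2 shuffles (sigma undefined)")
  samples <- vapply(seq_len(n_shuffles), function(k) {
    Sr <- shuffle_sequence(S, seed = mix_seed(cfg$seed, 50000 + k))
    cfg_k <- cfg
    cfg_k$seed <- mix_seed(cfg$seed, 60000 + k)
    ga_optimize(Sr, n, cfg_k, gaps)$mF_max
  }, 0)
  structure(list(n = as.integer(n), n_shuffles = as.integer(n_shuffles),
                 mean_Fr = mean(samples), sigma_Fr = sd(samples),
                 samples = samples, source_length = nchar(S)),
            class = "shuffle_stats")
}

#' @export
print.shuffle_stats <- function(x, ...) {
  cat(sprintf(
    "shuffle_stats: n = %d, %d shuffles, mean F_r = %.2f, sigma = %.2f\n",
    x$n, x$n_shuffles, x$mean_Fr, x$sigma_Fr))
  invisible(x)
}

#' Normal-model upper-tail probability of a score
#'
#' P(F_r > F) under N(mean_Fr, sigma_Fr^2).  Extreme tails are available
#' on the log10 scale so they do not underflow.
#'
#' @param F observed score (mF_max).
#' @param stats a `shuffle_stats` from [null_stats()], or any list with
#'   `mean_Fr` and `sigma_Fr`.
#' @param log10 return log10(p) instead of p.
#' @return probability (or its log10).
#' @export
p_value <- function(F, stats, log10 = FALSE) {
  mu <- stats$mean_Fr
  sg <- stats$sigma_Fr
  if (sg == 0) {
    p <- as.numeric(F < mu)              # degenerate null: all mass at mu
    return(if (log10) base::log10(p) else p)
  }
  lp <- pnorm(F, mean = mu, sd = sg, lower.tail = FALSE, log.p = TRUE)
  if (log10) lp / log(10) else exp(lp)
}

#' Calibrate the detection threshold F0 for a target false-positive rate
#'
#' Draws `n_windows` random windows of the given length and base
#' composition, computes each window's spectrum maximum over the tested
#' periods (family-wise over periods, exactly as real windows are scored),
#' and returns the smallest threshold whose exceedance fraction has a
#' one-sided binomial (Clopper-Pearson) upper confidence bound at or below
#' `target_fpr`.  The confidence step makes the calibrated F0 an upper
#' bound on the false-positive ratio rather than a point estimate, so a
#' held-out null batch stays at or below the target with high probability.
#'
#' @param window_length window size in bases (default 600).
#' @param n_windows number of null windows (>= 20).
#' @param periods period set scored per window.
#' @param target_fpr target false-positive fraction in (0, 1).
#' @param cfg a [ga_config()]; all window and GA seeds derive from
#'   `cfg$seed`.
#' @param gaps a [gap_params()].
#' @param composition base frequencies of the null windows (default
#'   uniform; pass observed genome frequencies for a composition-matched
#'   null).
#' @param confidence one-sided confidence level of the exceedance bound.
#' @return a `score_calibration`: list with `F0`, `scores` (null spectrum
#'   maxima), `curve` (data.frame threshold / exceed_fraction), plus the
#'   calibration settings.
#' @export
calibrate_threshold <- function(window_length = 600, n_windows = 100,
                                periods = 2:50, target_fpr = 0.05,
                                cfg = ga_config(), gaps = gap_params(),
                                composition = rep(0.25, 4),
                                confidence = 0.9) {
  if (target_fpr <= 0 || target_fpr >= 1)
    stop("target_fpr must be in (0, 1)")
  if (n_windows < 20) stop("need at least 20 calibration windows")
  scores <- vapply(seq_len(n_windows), function(w) {
    Sw <- random_dna(window_length, composition,
                     seed = mix_seed(cfg$seed, 70000 + w))
    cfg_w <- cfg
    cfg_w$seed <- mix_seed(cfg$seed, 80000 + w)
    spectrum_max(periodicity_spectrum(Sw, cfg = cfg_w, gaps = gaps,
                                      periods = periods))
  }, 0)
  sorted <- sort(scores, decreasing = TRUE)
  m <- length(sorted)
  # largest exceedance count k whose CP upper bound stays within target
  upper <- function(k) qbeta(confidence, k + 1, m - k)
  k_star <- 0L
  while (k_star + 1 < m && upper(k_star + 1) <= target_fpr)
    k_star <- k_star + 1L
  if (k_star >= 1L) {
    F0 <- sorted[k_star]                 # count(scores >= F0) = k_star
    while (sum(scores >= F0) > k_star && F0 < sorted[1])
      F0 <- min(sorted[sorted > F0])     # tie guard
    if (sum(scores >= F0) > k_star) F0 <- sorted[1] + 1e-9
  } else F0 <- sorted[1] + 1e-9          # even one exceedance too many
  thresholds <- sort(unique(scores))
  curve <- data.frame(threshold = thresholds,
                      exceed_fraction = vapply(thresholds,
                                               function(t) mean(scores >= t), 0))
  structure(list(F0 = F0, target_fpr = target_fpr, confidence = confidence,
                 scores = scores, curve = curve,
                 n_windows = m, window_length = window_length,
                 periods = periods),
            class = "score_calibration")
}

#' @export
print.score_calibration <- function(x, ...) {
  cat(sprintf(
    "score_calibration: F0 = %.3f at target FPR %.3f (%d windows of %d nt, empirical FPR %.3f)\n",
    x$F0, x$target_fpr, x$n_windows, x$window_length,
    mean(x$scores >= x$F0)))
  invisible(x)
}

#' Empirical exceedance fraction at a threshold
#' @param scores numeric null scores (or a `score_calibration`).
#' @param F0 threshold.
#' @return fraction of scores >= F0.
#' @export
empirical_fpr <- function(scores, F0) {
  if (inherits(scores, "score_calibration")) scores <- scores$scores
  mean(scores >= F0)
}

#' Identify the most significant period of a sequence
#'
#' Computes the periodicity spectrum of `S` and of `null_reps` seeded
#' shuffles of `S`, and selects the period whose score stands out most
#' from its shuffle null: z(n) = (mF_max(n) - null mean(n)) / sigma(n).
#' Period selection uses significance rather than the raw score because
#' the raw optimized score drifts upward with the period length (a 4 x n
#' matrix has more freedom to fit noise) and with base-composition bias,
#' both of which the composition-preserving shuffle null absorbs.  The
#' per-period null sigma is shrunk halfway toward the average sigma over
#' periods to stabilize it at small `null_reps`.
#'
#' @param S DNA string.
#' @param periods period lengths to test.
#' @param cfg a [ga_config()]; shuffle seeds and all GA seeds derive from
#'   `cfg$seed`.
#' @param gaps a [gap_params()].
#' @param null_reps number of sequence shuffles for the baseline.
#' @return a `period_selection`: list with `period` (the selected length),
#'   `table` (data.frame n, mF_max, null_mean, null_sd, z) and the
#'   underlying `spectrum`.
#' @export
select_period <- function(S, periods, cfg = ga_config(),
                          gaps = gap_params(), null_reps = 3) {
  stopifnot(null_reps >= 2)
  spec <- periodicity_spectrum(S, cfg = cfg, gaps = gaps, periods = periods)
  nullmf <- vapply(seq_len(null_reps), function(r) {
    Sr <- shuffle_sequence(S, seed = mix_seed(cfg$seed, 40000 + r))
    cfg_r <- cfg
    cfg_r$seed <- mix_seed(cfg$seed, 41000 + r)
    cfg_r$restarts <- 1L                 # a uniform bias cancels in ranking
    periodicity_spectrum(Sr, cfg = cfg_r, gaps = gaps,
                         periods = periods)$table$mF_max
  }, numeric(length(periods)))
  nullmf <- matrix(nullmf, nrow = length(periods))
  mu <- rowMeans(nullmf)
  sd_n <- apply(nullmf, 1, sd)
  sig <- pmax((sd_n + mean(sd_n)) / 2, 1)
  z <- (spec$table$mF_max - mu) / sig
  tab <- data.frame(n = periods, mF_max = spec$table$mF_max,
                    null_mean = mu, null_sd = sig, z = z)
  structure(list(period = periods[which.max(z)], table = tab,
                 spectrum = spec),
            class = "period_selection")
}

#' @export
print.period_selection <- function(x, ...) {
  k <- which.max(x$table$z)
  cat(sprintf(
    "period_selection: period %d (mF_max = %.1f, z = %.2f over %d tested periods)\n",
    x$period, x$table$mF_max[k], x$table$z[k], nrow(x$table)))
  invisible(x)
}

#' Mean GA-optimal local-alignment length on random windows
#'
#' Diagnostic used to calibrate the gap penalties: the mean alignment
#' length (seq_end - seq_start + 1) of optimized alignments on uniform
#' random windows.  The package's defaults target a mean around 200 bases
#' on 600-nt windows.
#'
#' @param window_length window size in bases.
#' @param reps number of random windows.
#' @param periods periods optimized per window (the mean pools all runs).
#' @param cfg a [ga_config()].
#' @param gaps the [gap_params()] under calibration.
#' @param composition base frequencies of the windows.
#' @return mean alignment length in bases.
#' @export
mean_null_alignment_length <- function(window_length = 600, reps = 10,
                                       periods = c(5, 10, 20),
                                       cfg = ga_config(),
                                       gaps = gap_params(),
                                       composition = rep(0.25, 4)) {
  lens <- unlist(lapply(seq_len(reps), function(w) {
    Sw <- random_dna(window_length, composition,
                     seed = mix_seed(cfg$seed, 90000 + w))
    vapply(periods, function(n) {
      cfg_n <- cfg
      cfg_n$seed <- mix_seed(cfg$seed, 91000 + 100 * w + n)
      a <- ga_optimize(Sw, n, cfg_n, gaps)$alignment
      if (a$seq_end >= a$seq_start && a$seq_end > 0)
        a$seq_end - a$seq_start + 1 else 0
    }, 0)
  }))
  mean(lens)
}
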