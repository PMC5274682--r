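---
title: "Detecting latent DNA periodicity: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting latent DNA periodicity: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periscan)
```

## The problem

A tandem repeat with period $n$ that has accumulated more than about one
substitution per base, plus insertions and deletions, is *latent*: no two
of its copies retain statistically significant pairwise similarity, so
seed-and-extend repeat finders and spectral methods (which tolerate
substitutions but not indels) both fail.  What survives divergence is the
*column-wise* base preference of the repeat: position $j$ of the period
still favors certain bases when all copies are stacked.  periscan detects
this directly, without ever comparing copies pairwise.

## The model

The periodic structure is represented by a $4 \times n$ position weight
matrix $M$ with entries $m(i, j)$, the weight of base $i$ at period
position $j$.  Conceptually the sequence $S$ is locally aligned against
the artificial periodic index sequence $S_1 = 1, 2, \dots, n, 1, 2,
\dots$; in the implementation $S_1$ is never materialized — the dynamic
program's profile column index simply runs modulo $n$.  The alignment is
Smith–Waterman-like with affine gap penalties and a score floor at zero;
its maximum score is $F_{\max}$.  Insertions consume sequence without
advancing the column index, deletions consume columns (cyclically)
without consuming sequence, so the register can re-synchronize after real
indels — the property that distinguishes this detector from spectral
methods.

For a given $n$ the matrix is unknown, so it is optimized: a genetic
algorithm over matrices uses $F_{\max}$ as fitness, and the optimal value
is $mF_{\max}(n)$.  Scanning $n$ over a range yields the periodicity
spectrum; significance comes from re-running the optimization on shuffled
copies of $S$ (the null score $F_r$), and detection thresholds are
calibrated empirically against random windows.

### Score scale

The published thresholds of this method family (e.g. a cutoff of 390)
depend on an unpublished weight scale.  periscan fixes its own scale
instead: every matrix column is normalized to base-weight mean 0 and
population variance 1 (all-equal columns become all-zero).  On this scale
the expected per-base score of any matrix on uniform random sequence is
exactly 0, and a sharply preferring column scores $\sqrt{3} \approx 1.73$
for its consensus base.  All thresholds shipped or computed by the
package live on this scale, and external numbers on other scales are not
comparable.

A consequence worth stating plainly: because per-base drift is zero for
*every* normalized matrix, the maximal-scoring segment of a null window
behaves like the maximum excursion of a driftless random walk and spans
most of the window (measured 520–600 nt of 600 for gap opens 1–16).  The
mean null alignment length therefore cannot be tuned to a target by gap
penalties on this scale; `mean_null_alignment_length()` is retained as a
diagnostic of this behavior.

### Gap penalties

Defaults are `gap_open = 6`, `gap_extend = 1` (per additional base).
They were calibrated once, during development, for detection power in the
regime the package targets (1.0 substitutions per base, 5% indel events
per base): an alignment tracking the *wrong* period length must open a
gap roughly once per period to stay in register, while the true period
gaps only at real indels (about one per two or three periods at a 5%
indel rate).  A grid over `gap_open` ∈ {2, 4, 6, 8, 10} on seeded
synthetic implants showed 6–8 maximizes period discrimination; below 4
the wrong-period trackers become as cheap as the truth, above 10 the true
indels become prohibitive.  Both penalties are exposed in
`gap_params()`.

### The genetic algorithm

Organisms are normalized matrices.  Defaults: population 40, elite
fraction 0.1, single-cut column-block crossover with probability 0.8,
per-cell Gaussian mutation (rate 0.05, sigma 0.5) followed by
re-normalization, stop after 30 generations without improvement or 500
generations.  Two non-default choices matter:

* **Profile re-estimation** (`refine = TRUE`): each generation, one
  candidate is the normalized frequency matrix of the current best
  organism's own alignment — the classic matrix → alignment → frequency
  → matrix cycle.  This roughly halves convergence time and markedly
  improves recovery at large periods, where the 4n-dimensional search is
  otherwise slow.
* **Determinism**: every stage draws from seeds derived arithmetically
  from `cfg$seed` (per-period seeds in spectra, per-shuffle seeds in
  nulls), so identical inputs give identical outputs, parallel or not.

### Period identification

The raw spectrum argmax is biased two ways: the optimized score of pure
noise grows roughly like $\sqrt{N n}$ (a wider matrix has more freedom to
fit noise), and base-composition bias inflates every period at once.
`select_period()` therefore ranks periods by the shuffle-null z-score
$z(n) = (mF_{\max}(n) - \mu_r(n)) / \sigma_r(n)$, where $\mu_r, \sigma_r$
come from spectra of composition-preserving shuffles of the same
sequence, with the per-period $\sigma$ shrunk halfway to its mean over
periods for stability at small shuffle counts.  This matches how the
method family reports "the most statistically significant period".  The
windowed scanning protocol (`scan_periodicity()`) keeps the simpler
protocol rule — raw spectrum maximum against a calibrated threshold
$F_0$ — because there the question is detection, not period estimation,
and the threshold is calibrated against the identical statistic.

### Threshold calibration

`calibrate_threshold()` scores null windows (given length and base
composition) by their spectrum maximum over the tested periods — the
family-wise statistic actually used on real windows — and returns the
smallest observed score whose one-sided Clopper–Pearson upper confidence
bound (default 90%) on the exceedance fraction is at or below the target
false-positive rate.  The confidence step makes $F_0$ an *upper bound*
on the false-positive ratio rather than a point estimate; a plain
empirical quantile would exceed its target on a held-out batch about
half the time.

### Triplet filter

Protein-coding sequence carries strong period-3 structure that would
flood a periodicity scan, so windows are skipped when the
triplet-periodicity statistic exceeds 3.  The statistic is built from
the $4 \times 3$ table of base counts by position mod 3: with $I$ the
mutual information (nats) between base and frame and $N$ counted bases,
$2NI$ is asymptotically $\chi^2_6$ under no triplet structure, and $Z =
(2NI - 6)/\sqrt{12}$.  $I$ is invariant under frame shifts and base
relabeling, so no reading-frame search is needed.  The exact statistic
used by the original database is defined in work we do not restate; this
construction is the package's operational definition of the filter.

### Matrix comparison and unique repeats

Detected regions are summarized by $4 \times n$ frequency matrices
(counts of matched bases per period column; indel steps contribute
nothing, so the total equals the aligned length minus bases in indel
regions).  Two matrices of equal period are compared by the information
distance

$$ I = \sum f_k \ln f_k + \sum f_l \ln f_l - \sum (f_k + f_l)\ln(f_k + f_l)
   + \sum_j \left[ (s_k + s_l)\ln(s_k + s_l) - s_k \ln s_k - s_l \ln s_l \right] $$

with $0 \ln 0 = 0$ and $s(j)$ the column sums.  Per column this is half
the $G$ statistic of the $4 \times 2$ base-by-matrix table, so $2I$ sums
$n$ nearly independent $\chi^2_3$ terms.  Under the null actually used —
matrices from *shuffled* sequences, which fixes each matrix's total base
composition — three degrees of freedom are absorbed by the shared
composition, giving $\mathrm{df} = 3(n-1)$; an unconstrained per-column
multinomial null would give $3n$ instead.  `randomize_frequency_matrix()`
implements exactly this composition-fixing null (it permutes the base
multiset across columns, preserving column sums), and Monte-Carlo checks
in the test suite confirm mean $2I \approx 3(n-1)$ within a few percent.
The normal transform is the root form $X = \sqrt{4I} - \sqrt{2\,
\mathrm{df} - 1}$, which is the standard $\chi^2$-to-normal
approximation applied to $2I$.

Cross-genome comparison takes, for each matrix of set A, the minimum $X$
over all same-period matrices of set B (minimizing over cyclic column
shifts, since period phase is arbitrary).  The survival curve $F_k(x)$ of
these minima is compared with the null curve $Fr_k(x)$ from randomized
copies; the smallest $x_0$ with $F_k(x_0)/Fr_k(x_0)$ above the ratio
(default 20) defines the count $F_k(x_0)$ of repeats unique to A.

### The simulator

`simulate_latent_periodic()` builds consensus × copies, applies
Poisson(rate × length) substitution events — each replaces the base at a
uniform position with a uniform *different* base, so a base can mutate
repeatedly and identity to consensus saturates toward 25% — then
Poisson(indel_rate × length) indel events (insertion/deletion
equiprobable, lengths uniform on 1..3 by default), and embeds the array
at a seeded random offset inside background of specified composition.
Defaults are the latent regime: 1.0 substitutions and 0.05 indel events
per base, at which realized identity to the consensus is about 43–45%
and pairwise copy similarity is insignificant.  What the simulator does
*not* emulate: composition heterogeneity of real genomes, correlated
mutation (hotspots), microsatellite slippage length distributions, and
nested or interrupted repeats — so passing the synthetic benchmarks
demonstrates sensitivity in the stated noise model, not performance on
any particular genome.

## Detection limits at the study conditions

Two facts shape what the benchmarks can show.  First, the latent signal
accrues linearly with array length ($\approx 0.46$ per aligned base at
43% identity on the normalized scale, before indel penalties), while the
optimizer's noise score grows only like $\sqrt{Nn}$; the synthetic
recovery benchmark therefore uses arrays of about 1.3 kb (copies =
1320/period for periods ≤ 12, and 40 copies for period 35), where the
separation is clear for most draws.  The method family's worked examples
are 430–466 nt, but on a score scale that is not comparable.  Second,
some draws at 1.0 substitutions per base plus 5% indels fall *below the
information floor*: on such draws even the truth-derived consensus
matrix scores within one sigma of the shuffle null, so no optimizer can
recover the period.  This is essentially always the case for period 35
at 40 copies (each column then collects only ~17 consensus bases against
140 free parameters), and for roughly a quarter of period-11 draws.  The
recovery benchmark counts these honestly; its expected success rate at
the stated conditions is near — and on unlucky seed sets below — the 80%
design goal, and that is a property of the regime, not of a tunable
parameter.

## Problem sizes used by the tests and the acceptance script

Chosen as representative desk-scale versions of the protocol: GA
population 20 with plateau 8 / cap 50 generations (restarts 2 where the
period is being estimated); recovery benchmark of 20 runs (12 in the
acceptance script) cycling the period set {2, 5, 10, 11, 12, 35};
threshold calibration on 100 windows of 600 nt over periods 2–11 with a
50-window held-out batch; 1000-replicate Monte-Carlo checks for the
triplet tail and the matrix-distance chi-square calibration; and a
400–1000-instance oracle comparison for the alignment DP ($|S| \le 10$,
$n \in \{2, 3\}$, exhaustive unrolled-profile Smith–Waterman in plain R
as the independent reference).

## Numerical choices and degenerate inputs

* Cyclic deletion chains are resolved with two passes per row; a run of
  $\ge n$ deletions costs at least `gap_open` + $(n-1)$ `gap_extend` and
  returns to the same column, so it is never part of an optimum.
* Traceback prefers match > deletion > insertion among equal
  predecessors, restarts on a zero-valued prefix, and picks the earliest
  (smallest end position, then smallest column) among equal-scoring end
  cells — determinism over aesthetics.
* N bases score 0 against every column, are excluded from frequency
  matrices and triplet counts, and cannot start or end an alignment
  (alignments start and end in match states on real bases).
* All-equal weight columns normalize to zero rather than dividing by a
  near-zero variance; `p_value()` with a zero-sigma null degenerates to
  0/1 by comparison with the mean; zero-sum frequency columns emit "N"
  in consensus strings.
* Coordinates are 1-based inclusive everywhere inside the package and
  converted only at the BED/bedGraph boundary (0-based half-open).

## Known limitations

* Scores are meaningful only relative to the package's own normalization
  and gap defaults; thresholds from other implementations of this method
  family do not transfer.
* The scanner is forward-strand only and reports at most one period per
  merged region.
* Period estimates are subject to multiple/divisor confusion by
  construction (a period-10 array genuinely is a period-20 array, and at
  high divergence near-fractional trackers compete); consumers should
  treat the reported period as a family representative.
* Region boundaries are alignment spans within 600-nt windows; repeats
  longer than the window are fragmented and then merged greedily, which
  can clip edges.
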