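---
title: "Methods behind tunemut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind tunemut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunemut)
```

tunemut analyzes evolution experiments in *E. coli* strains whose point
mutation rate is set externally, by inducing the mismatch-repair proteins
MutH and MutL to chosen levels. This vignette explains each model the
package implements, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generators emulate, and the
known limitations.

## Fluctuation-assay inference

A fluctuation assay grows many small parallel cultures under
non-selective conditions and plates each on selective (rifampicin)
medium. Because a resistant mutant arising early in a culture's growth
leaves exponentially many descendants, the count distribution is heavily
right-skewed ("jackpots"), and that skew identifies the expected number
of mutational events per culture, *m*, separately from the plating noise.

The package computes the Luria–Delbrück count distribution with the
Ma–Sandri–Sarkar recursion

$$p_0 = e^{-m},\qquad p_r = \frac{m}{r}\sum_{i=0}^{r-1}\frac{p_i}{r-i+1},$$

which is the compound-Poisson distribution whose clone sizes follow
$P(S=s)=1/(s(s+1))$ (deterministic exponential growth of neutral
mutants). `fit_mutation_number()` maximizes the resulting likelihood by
bounded one-dimensional search:

* **Count cap** `r_cap = 150` (default). The recursion is $O(r^2)$ and a
  jackpot of 5,000 colonies says little about *m* beyond "large", so
  counts above the cap contribute the log upper-tail mass
  $\log(1 - \mathrm{CDF}(r_\mathrm{cap}))$ instead of an individual pmf
  term.
* **Starting value** from the P0 method, $m_0=-\ln f_0$ with $f_0$ the
  zero-count fraction, when $f_0\in(0,1)$; otherwise from the
  Lea–Coulson median relation $\tilde r/m - \ln m = 1.24$. The search
  bracket is centered on $m_0$ and widened automatically if the optimum
  lands on an edge; tolerance is $10^{-6}$ on *m*. The likelihood was
  unimodal in every simulated dataset we scanned densely, and a test
  asserts agreement between the optimizer and a dense grid argmax.
* **Confidence interval.** Stewart's large-sample result for the SD of
  $\ln\hat m$, $\sigma = 1.225\,\hat m^{-0.315}/\sqrt{C}$ with $C$
  cultures, with symmetric limits $\exp(\ln\hat m \pm 1.96\sigma)$. A
  refinement making the limits slightly asymmetric exists in the
  literature; we implement the symmetric form, and simulation (200
  assays, $C=60$, $m=2$; run in the test suite) shows ~95% coverage, so
  the refinement is not needed at these sample sizes.
* **Boundary case.** All-zero counts put the MLE at $m=0$; the estimate
  is flagged and a one-sided $\alpha=0.05$ upper bound $-\ln(0.05)/C$ is
  reported as metadata rather than a CI.
* **Per-division rate.** $\mu=\hat m/N_t$: a culture grown from a small
  inoculum to $N_t$ cells underwent $N_t-N_0\approx N_t$ divisions. A
  factor-of-two convention ($2N_t$ effective divisions) exists; we adopt
  $m/N_t$, which reproduces wildtype rifampicin-resistance magnitudes
  ($\sim10^{-9}$–$10^{-8}$ per division).
* **Plating.** Essentially the whole culture (249/250 by default) is
  assumed plated; no partial-plating correction is implemented, and a
  warning fires below a plating fraction of 0.9, where that assumption
  starts to bias $\hat m$ low.

`compare_count_distributions()` applies the two-sample
Kolmogorov–Smirnov test to the per-culture counts themselves (not to
derived rate estimates): counts are the raw observable, and the KS test
on them is sensitive to any distributional change. Ties among discrete
counts make the asymptotic p-value conservative; the suite verifies a
null rejection rate at or below nominal.

## Hill-plus-shift dose response

Expression vs inducer and mutation rate vs inducer are both described by

$$y(x) = \frac{A}{1+(k_a/x)^n} + C,$$

with baseline $C=y(0)$, asymptote $A+C$, half-response at $k_a$
(concentration units: ng/ml aTc or µM IPTG), and Hill coefficient $n$
(dimensionless). $A<0$ gives a decreasing response — the mutation rate
falls as repair induction rises. At $x=0$ the implementation returns $C$
exactly rather than plugging in an epsilon.

Fitting is Levenberg–Marquardt least squares (via minpack.lm) with
starting values from the data extremes and bounds $k_a\in(0,10^4]$,
$n\in(0,10]$ to keep the optimizer off absurd plateaus. Two objectives
are offered because the original fitting scale of such data is usually
unreported:

* linear scale (default for expression data);
* squared error of $\ln y$ (default for rate data, which spans orders of
  magnitude — linear least squares would ignore the low-rate regime
  entirely). The log objective is also the statistically matched choice
  when noise is multiplicative, and under 10% multiplicative noise it
  recovers $k_a$ within ±25% in over 90% of simulated series, which the
  linear objective does not.

A constant series is returned as $A=0$, $C=\bar y$ with a `degenerate`
flag ($k_a$, $n$ unidentifiable); fewer than four distinct
concentrations is an error. Uncertainty weights are available but off by
default. `compose_rate_vs_expression()` pairs the two fitted curves over
an inducer grid to give mutation rate as a function of repair-protein
expression; when the expression fit increases and the rate fit
decreases, the composed curve is monotone non-increasing, which a test
asserts.

## Growth-curve phenotypes

Each well-day trace (one OD600 reading per 10 minutes) is reduced to
three phenotypes after blank correction (per-timepoint mean of the blank
wells subtracted; corrections below −0.05 OD are flagged):

* **Early exponential rate** (hr⁻¹): OLS slope of $\ln$ OD vs time,
  restricted to OD ∈ [0.03, 0.16]. The 0.16 ceiling is where these
  cultures leave log-linear growth; the 0.03 floor excludes the regime
  where plate readers are too noisy to measure growth well (instruments
  differ, so the floor is configurable). Fewer than four in-window
  points yields a missing value rather than a noisy estimate. Rate
  estimation needs no smoothing because it is a regression; the 3-point
  moving average exists only for the diagnostic derivative-vs-OD curve.
* **Time to leave exponential phase** (hr): first crossing of OD 0.16,
  linearly interpolated between the bracketing samples. Interpolating in
  OD rather than ln OD changes the answer by well under a minute at
  10-minute sampling.
* **Saturating OD**: mean over the final 60 minutes of the day — a
  windowed mean rather than the daily maximum so one spiky sample cannot
  set the value.

A trace is **flagged erratic** when it shows a single-step drop
exceeding 30% of the current OD while above OD 0.05, or a negative
excursion beyond five local noise SDs that later recovers. These
thresholds are operational definitions of a qualitative phenomenon
(transient reader errors, a few traces per thousand) and are
configurable; flagged wells are excluded from summaries and counted
separately. Per condition and day, `condition_summary()` reports the
mean and the coefficient of variation (sample SD over mean) of each
phenotype — the CV is the natural scale-free measure of how far
replicate wells have diverged from one another.

`population_fold_change(rate, dt) = exp(rate * dt)` converts an advance
in threshold-crossing time into the implied effective-inoculum increase
at fixed growth rate: at 0.85 hr⁻¹, half an hour is ≈1.5× and a full
hour slightly more than a doubling.

## Variant filtering and cumulative SNP curves

Mutation calls arrive in breseq's GenomeDiff format; the reader consumes
the four mutation line types (SNP, DEL, INS, MOB), takes `frequency=`
when present (1.0 otherwise), keeps 1-based positions, and skips
evidence lines. Two filters isolate de novo mutations:

* **Ancestral filter**: any (type, position, allele) present in the
  ancestor — at any frequency — is removed everywhere.
* **Shared-well filter**: any identity observed in more than one well is
  removed, because independent recurrence at the same base and allele
  across replicate wells is far less likely than low-frequency standing
  variation inherited from the ancestor. The two sequenced timepoints of
  one well count as a single well, so within-well persistence across
  days is retained. Mutation identity deliberately excludes frequency.

Both filters are idempotent and commute (asserted as properties).
Frequencies below 5% are outside the data's calling range (~50×
coverage) and the cumulative curve never counts them:
`cumulative_snp_curve()` counts, for each value of a descending grid of
200 evenly spaced frequencies from 1.0 to 0.05 (finer than the data
resolution; the grid density is not load-bearing), the sample's SNPs at
or above that frequency. Curves are averaged per condition with a
pointwise SEM = sample SD/√n band. Curves are computed per timepoint and
averaged within condition-day, keeping the two sequencing days separate.

Gene annotation takes GFF3 (via ape) or BED (converted to 1-based
inclusive); a record is assigned to every gene whose interval its span
overlaps, so a deletion crossing several genes is annotated with each —
and counts once per covered gene for per-gene tallies, once in total
genome-wide.

## The cluster scan statistic

To ask whether k mutations in one gene of length w signal selection, the
package computes the probability that *any* window of w consecutive
bases contains at least k of N uniformly placed mutations on a G-bp
chromosome. Scanning all windows is itself the multiple-comparison
correction for having searched the genome.

Monte-Carlo estimation draws N positions uniformly with replacement on
{1..G} (coincident draws occur with probability ~N²/2G and count as
distinct — the simplest faithful null), sorts them, and declares success
when some k consecutive order statistics span at most w−1 bases (a
window of w bases, ends inclusive). The compiled core uses R's RNG, so
`set.seed()` gives bit-identical success counts. For large N on a linear
genome the positions are first bucketed into width-w cells: a window of
length w intersects at most two adjacent cells, so the full sort is only
run when some adjacent cell pair holds ≥ k points — rare under the null,
which makes each replicate O(N). A plain-R brute-force oracle checks
both code paths in the test suite. The genome is treated as linear by
default; circular mode (wrap-around windows) is provided and matches the
closed form 2w/G for two points on a circle, but at gene-scale w/G the
difference between linear and circular is far below Monte-Carlo
resolution. Exact shortcuts: k = 1 gives p = 1, k > N gives p = 0,
w ≥ G gives p = 1.

An analytic cross-check accompanies every Monte-Carlo value: the
expected number of k-subsets with range ≤ w is

$$E = \binom{N}{k}\left[kq^{k-1}-(k-1)q^k\right],\quad q=w/G,$$

(the bracket is the exact range distribution of k uniforms) and the
reported approximation is $1-e^{-E}$. Two caveats, both documented on
the function: it requires $q\ll1$, and when the per-window intensity
$Nw/G$ is appreciable it overshoots the scan probability, because a
window that does contain a cluster tends to contain extra points, each
of which multiplies the subset count — at $Nw/G\approx0.3$ the
approximation runs roughly 1.4× above the simulation, still within the
factor-of-2 agreement the tests assert for small p. The Monte-Carlo
value is the primary number; the analytic value is corroboration.

`gene_cluster_report()` applies the scan to every gene (or user-supplied
region, e.g. an operon span) with at least two distinct mutations of a
type, taking N as the genome-wide distinct count of that type. A
conservative analyst may round N up: `round_up_N = TRUE` rounds to one
significant figure (35 → 40), and `n_total` overrides N per type for any
other convention (e.g. promoting ~800 observed substitutions to a round
1000, which lowers no one's p-value unfairly — it only makes clusters
harder to call significant). With N fixed by that choice, defaults of
10⁶ replicates resolve p-values down to ~10⁻⁵; for smaller targets raise
`reps` or lean on the analytic value.

## Synthetic data: what it emulates, and what it does not

Every generator takes a seed and is bit-reproducible.

* `simulate_fluctuation()` is a mechanistic forward model: K ~
  Binomial(D, µ) mutational events over the D = nₜ−n₀ wildtype
  divisions, each attached to a uniformly chosen division, with the
  clone then growing deterministically at the wildtype rate to
  ⌊nₜ/n⌋ cells. Attaching events to individual divisions (rather than
  to whole generations of simultaneous doubling) matters: the
  division-resolved model reproduces the Luria–Delbrück clone-size law
  exactly, whereas a generation-chunked model concentrates clone sizes
  on powers of two and its count distribution sits at total-variation
  distance ~0.1 from the MSS pmf. The test suite asserts TV ≤ 0.02
  between simulator and recursion at m ∈ {0.5, 1, 2} with 10⁵ cultures.
  Mutants are exactly neutral, matching the estimator's assumption.
* `simulate_growth_plate()` produces two-phase traces: exponential
  growth from `od0` (default 10⁻³, the OD equivalent of a few million
  CFU in 500 µl) at 0.85 hr⁻¹ to a transition OD of 0.2 (between the
  0.16 and 0.3 landmarks), then exponential relaxation toward `od_max`
  (default 0.45) at `beta` = 0.4 hr⁻¹; additive Gaussian reader noise
  (SD 0.003 OD, a typical plate-reader floor), a blank offset of 0.04,
  10-minute sampling over a 23-hour day, and a 0.005 per-well artifact
  probability (a single-sample 50% drop at measurable OD), matching an
  observed rate of a few erratic traces per thousand.
* `simulate_mutation_tables()` plants the exact structure the filters
  and scan assume: per-sample Poisson background at study-scale
  intensities (≈20 substitutions, ≈1 deletion per sample, rarer
  insertions/mobile elements), uniform positions, frequencies from a
  mixture (80% U(0.05, 0.3), 20% U(0.3, 1)) floored at the 5% calling
  cutoff, plus optional planted gene clusters, ancestral calls and
  cross-well duplicates, with the ground truth returned for exact
  recovery tests.
* `simulate_dose_response()` applies multiplicative Gaussian noise to a
  Hill curve.

What passing tests on these generators shows is that the estimators are
correct *under their own assumptions*: neutral mutants and complete
plating (fluctuation), clean two-phase kinetics with additive noise
(growth), uniform background mutation (scan). Real data violate these in
known ways — differential mutant fitness and phenotypic lag bias
fluctuation estimates; real growth curves have lag phases, drift and
condition-dependent saturation shapes; real mutational spectra have
hotspots and GC biases that make the uniform null generous. The
generators make no attempt to emulate selection dynamics (no
Wright–Fisher or clonal-interference machinery) or read-level sequencing
error.

## Problem sizes and runtime choices

The shipped test suite runs the full chain at reduced scale, chosen so
the statistical assertions have comfortable margins: 10⁵-culture
distributional checks, 200-assay coverage simulations, 10⁴–10⁶-replicate
scans, and an end-to-end synthetic study of five conditions × nine wells
over three sampled days with per-condition SNP intensities and one
planted cluster. The acceptance script uses 5×10⁶ replicates for the
eight-of-1000 scan (Monte-Carlo SE ≈ 3×10⁻⁶) and 10⁶ for the
three-of-40 scan.

## Known limitations

* No partial-plating or differential-mutant-growth corrections in the
  fluctuation module; the MSS estimator family assumes complete plating
  and neutral mutants.
* The Stewart interval is symmetric on the log scale; at very small C or
  very small m its coverage degrades.
* Lag-phase duration is not estimated: at inoculation ODs far below the
  reader floor, a shorter lag and a larger inoculum are
  indistinguishable in these traces.
* The scan's uniform null ignores mutational spectrum structure; a
  hotspot-aware null would be stricter for some genes.
* Rare variants below 5% frequency are invisible to the filters, so
  ancestral standing variation under that frequency cannot be fully
  removed.
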