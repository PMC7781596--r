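---
title: "Models and methods behind flexgoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flexgoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flexgoal)
```

# The scientific setting

flexgoal implements the analysis battery used to search for working-memory
representations of a remembered goal in prefrontal population activity
recorded during a multi-start, multi-goal, multi-route (MSMGMR) spatial
task. On each trial a rat samples one of three goal locations, returns to
the center, finds the correct one of three start ports, holds a nose poke
through a 3 s (3.2 s in one configuration) delay, and then navigates to the
remembered goal over one of three bridges. The delay period is the analysis
window of interest: the animal is stationary, its future route is unknown,
and anything decodable about the goal must be held internally.

The battery asks the same question at several levels: population-vector
(PV) correlations and a correlation-based template decoder; a single-cell
Kruskal-Wallis selectivity screen; supervised population decoding with four
classifier families under leave-one-out cross-validation (LOO-CV); LFP
phase-of-firing statistics; and jitter-corrected spike cross-covariance
("activity-silent" codes carried by fast synchrony rather than rate). A
ground-truth synthetic session generator makes every stage testable without
access to recorded data.

# The synthetic session generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study's task conditions; everything it emulates (and does not) is
listed here so that passing tests are read correctly.

**Trial design.** There are 27 combinations of start, goal, and test
bridge. Each 27-trial block is a permutation of all 27 such that every
9-trial subblock contains each start, goal and bridge exactly three times,
no goal repeats on more than two consecutive trials (enforced across block
boundaries), and within a subblock each goal sees each sample route once.
Subblock membership is drawn from a randomly relabelled mod-3 Latin
design, which satisfies the marginals by construction; orderings are then
rejection-sampled against the goal-run rule with bounded retries. This does
not sample uniformly from all legal sequences -- it samples uniformly from
a large constructive subfamily -- which is sufficient for every analysis
here, all of which depend on the constraints, not on the sequence measure.

**Accuracy model.** Correctness is Bernoulli per trial (default
p = 0.77, the study's overall behavioral accuracy scale); errors choose a
wrong goal uniformly. Maze-rotation sessions drop accuracy to a floor
(default 0.35) with an exponential relearning ramp (tau = 15 trials).

**Spiking.** Spike trains are inhomogeneous Poisson, sampled by thinning.
The per-cell rate is a baseline (default 2 Hz, optionally drifting
linearly) multiplied by a `gain` factor (default 3) during the delay when
the trial's label matches the cell's preferred label. Exclusive
selectivity classes: start, allocentric goal, egocentric goal
(`(goal - start) mod 3`, mapped to behind/left/right by a configurable
convention -- the task names the classes but not the geometry), start x goal
conjunction, and within-delay sequence cells (Gaussian bump, SD 0.25 s, at
a cell-specific latency). Goal cells are additionally elevated while the
animal is at their preferred goal in the sample and test phases: the goal
code is spatial at the goal and mnemonic in the delay, which is what makes
goal-arrival template decoding and "modulation at the sample goal" cell
selection meaningful. Sync pairs receive shared excess delay spikes at a
common event rate, each member jittered independently (Gaussian, default
2 ms), optionally only in preferred-goal trials. Phase-locked cells
multiply their delay rate by a von Mises factor of the instantaneous band
phase, so their empirical resultant length converges to the Bessel ratio
I1(k)/I0(k).

**LFP and tracking.** LFP is the sum of three oscillators (3.5, 8, 22 Hz,
one per elevated band) whose amplitude is gated up during delays, plus
1/f-like noise, duplicated across channels with small per-channel delays.
Tracking (30 Hz, two LEDs 4 cm apart along the head axis) follows
piecewise-linear paths between task locations and is stationary during
each nose poke up to sensor noise (default SD 0.08 cm per coordinate,
within the design target that delay-period head speed stays below 1 cm/s
at the VTE screen's 330 ms window). Not emulated: realistic path
curvature, head-direction dynamics decoupled from motion, biophysical LFP
or spike waveforms, probe geometry beyond a channel index. Passing tests
therefore certify the statistical machinery, not robustness to real-data
artifacts.

**Reproducibility.** One named RNG stream per component (trials, cell
assignment, spikes, LFP, tracking) is derived from the master seed, so a
stage can be regenerated without replaying the others.

# Preprocessing filters

Three stability criteria select analysis cells, in fixed order after
optional initial-trial trimming (3-20 trials in recorded sessions;
session-specific, configurable):

1. **Session rate stability** -- firing rate in 10 s bins, standardized
   over bins; an OLS line over bin index must move by at most 1 (in SD
   units) between first and last bin. All-equal bins (SD 0) pass with
   statistic 0: a perfectly flat cell is maximally stable.
2. **Delay rate stability** -- OLS on raw per-delay spike counts against
   delay index; fitted first-to-last difference at most 1.4 spikes. Counts
   are raw, not standardized: the 1.4-spike threshold only has meaning on
   the count scale. Because goals are pseudorandomly interleaved, a
   stationary goal-selective cell passes with high probability (its goal
   preference contributes variance, not trend).
3. **Delay activity minimum** -- at least one spike in at least one-sixth
   of delays, boundary inclusive ("at least" is read inclusively).

Putative fast-spiking interneurons are then removed by the conjunction of
waveform width below `width_max` and mean rate above `rate_min`. The
defaults (0.4 ms, 10 Hz) are package defaults, not published values; both
are parameters.

# Correlation decoding

Goal templates are mean PVs over the 3 s after sample-phase goal arrival
(correct trials by default). Each delay is cut into bins of the chosen
width (canonical grids 0.375/0.75/1.5/3 s, or 0.4/0.8/1.6/3.2 s for 3.2 s
delays); each bin PV is Pearson-correlated with each template; the winner
is the class with the highest bin-averaged correlation ("mean" mode) or
the most per-bin wins ("majority" mode). For the start target, templates
are full-delay PVs averaged per start with the decoded trial excluded from
its own template. Numerical policies: zero-variance bin PVs produce
undefined correlations and cast no vote (recorded as missing, never forced
to 0, so silent bins cannot dominate sparse data); ties break to the
lowest class index and are counted; a delay with no valid bins yields a
missing prediction, excluded from accuracy with its count reported.

# Single-cell screen and supervised decoding

The screen bins delay spikes at several widths (default grid doubling from
0.1 s to the full delay), treats each cell x bin as one feature, compares
its distribution across classes with the tie-corrected Kruskal-Wallis test
(H = 0, p = 1 when all observations are equal), and applies
Benjamini-Hochberg step-up FDR separately within each binwidth -- the FDR
family is all cell x bin tests of one scheme at one width.

Supervised decoding concatenates cell x bin counts per trial,
standardizes each feature over trials (SD-0 features set to all-0), and
runs LOO-CV with per-fold class balancing by subsampling larger classes to
the smallest count (per-fold seeded). Reported accuracy is the mean of
per-class accuracies. The four classifier bundles are fixed: L2 logistic
regression (ridge, glmnet; a short descending lambda path ending at the
target value is fitted because single-value paths are numerically
brittle); RBF-kernel SVM with kernel coefficient 0.001; a 1000-tree random
forest whose number of candidate split features is n, the total feature
count, taken literally (the conventional default would be sqrt(n); a
`mtry_frac` override exists); Gaussian naive Bayes on the 10% of features
with the highest H-scores, selected inside each training fold.

**Standardization leakage.** The source analyses standardized over all
trials; that is the default (`standardize_policy = "global"`), with a
strictly per-fold alternative (`"fold"`) and a no-op (`"none"`) behind the
same flag, all tested. The choice is exposed rather than silently
"improved" because the fidelity-vs-best-practice tension is real.

**A LOO caveat that matters for the controls.** When features carry no
information about the label but perfectly identify a nuisance variable
(the start port, for stationary tracking during the delay), leave-one-out
training inherits a small anti-correlated label-count imbalance -- the
left-out trial's (start, goal) cell is underrepresented -- and accuracy
falls *below* chance rather than to it. This is the well-known LOO
anti-bias, not information. The tracking control therefore asserts the
one-sided claim (no window above the chance band during the delay; near-1
accuracy once trajectories diverge), which is also the only claim the
original observation supports.

# Phase-of-firing analyses

Channel QC removes channels whose SD is below 1/4 or above 4x the mean
channel SD. A unit's reference trace averages 10 channels at least 8 sites
away (5 per side where possible, shifted near array edges). The reference
is band-passed (2.5-5, 5-12 or 15-30 Hz) with a zero-phase FIR filter
(Hamming-window design, order about three cycles of the low band edge,
applied forward-backward), with 3 s of context around each delay; phase is
the angle of the FFT-based analytic signal. Within each peak-to-peak
interval, any phase regression invalidates the whole interval; valid
duration is tracked per delay and reported. Resultant vector lengths are
computed per cell (and per goal class); overall locking uses the Rayleigh
test (the package's choice; no test is named in the source). The
goal-shuffle test compares observed per-(cell, goal) resultant lengths to
pooled label-shuffled ones with a two-sample KS test (again the package's
choice of distribution comparison). Phase-bin decoding divides spike
phases into 2, 6 or 12 bins (the Methods' list; a figure legend lists
2/4/6 -- the Methods win, and the list is configurable), with bins centered
so that for 2 bins one bin spans -90..90 degrees, normalizes counts by the
delay's valid duration, standardizes per feature and decodes with LR
LOO-CV.

# Jitter-corrected covariance and CCSI

Cells significantly modulated across goals at the sample goal location
(Kruskal-Wallis at 0.05; the test is the package's choice) with the same
preferred goal (argmax mean rate, ties to the lowest index and counted)
form candidate pairs. Spikes are binned at 10 ms; surrogates permute bins
independently per cell within 50 ms blocks; the mean surrogate
cross-covariance (1000 surrogates canonically) is subtracted per trial,
removing co-modulation slower than the block. The zero-lag scalar is the
mean of the three lag bins around zero; covariance is biased-normalized
(divide by the bin count), unscaled by SDs -- it is a covariance, not a
correlation. The inner loop is compiled (Rcpp) with an R reference
implementation kept as the test oracle.

A pair is excitatory/inhibitory when the mean corrected zero-lag scalar
has the same sign in preferred and non-preferred trials, and discarded
otherwise. The CCSI is the mean preferred-minus-non-preferred difference
over a sign class, with trial counts matched by subsampling the larger
set. One design point deserves emphasis: the matched subsample is drawn
once per pair (seeded) and used for *both* the sign classification and the
difference. Classifying the sign on the full non-preferred set while
differencing a matched subsample looks harmless but biases the
class-conditioned index upward under exchangeable trials, because the sign
condition is less noisy on the larger set; with the consistent subsample
the exchangeable null is exactly unbiased (verified by simulation in the
acceptance suite). Confidence intervals are percentile bootstraps over
pairs; note that percentile bootstraps over ~10-20 pairs have true
coverage near 92%, which the calibration tests account for explicitly.
Time-resolved CCSI slides a 1 s window in 50 ms steps over -2..5 s around
delay onset, with signs classified once from the extended window.

# Embedding and reports

Task-location PVs (delay, labelled by start; 3 s after sample goal
arrival, labelled by goal; bridge crossing, labelled by test route; one
implementation of `population_vector()` is shared with every other stage)
are standardized per cell (a flag disables this; the source is silent) and
embedded with t-SNE at perplexity 35, learning rate 100, 10 restarts,
keeping the run with the lowest final KL divergence. `session_report()`
collates all stage outputs into one stable-schema JSON with seeds and a
config hash.

# Numerical conventions

All times are seconds from recording start, rates are Hz. Bin edges are
half-open `[a, b)`: a spike exactly at a bin's right edge belongs to the
next bin and a spike at a window's end is excluded; a binwidth that does
not tile a window drops the final partial bin and never analyzes a partial
one. Half-open conventions, tie-breaks (lowest index, counted) and SD-0
policies are asserted by tests rather than left implicit.

# Problem sizes used by the test suite

Simulation sizes in the test and acceptance suites are the package's
choices: the correlation-decoder calibration runs 20 sessions of 90 cells
and 108 trials over five binwidths; the four-classifier calibration runs
pooled sessions of 20 cells and 54 trials (a 1000-tree forest with all
features considered at each split is expensive at 2700 features, and
chance-level calibration does not depend on the population size); CCSI
constructions use 50 pairs, 54 trials and 100-200 surrogates per pair;
the trial-design constraints are checked exhaustively over 1000 seeds.
The acceptance script (`scripts/acceptance.R`) regenerates everything it
reports from scratch under the seed it is given.

# Known limitations

The generator's delay code is stationary within a trial unless sequence
cells are configured; drifting codes, theta-sequence-like structure and
cross-frequency coupling are out of scope. The LFP model is a gated
oscillator bank, adequate for phase-extraction and spectral bookkeeping
tests but making no quantitative spectral claims. Loading recorded
sessions is supported through the documented CSV/binary formats, but all
acceptance evidence comes from synthetic ground truth; conclusions about
real recordings require the real data.
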