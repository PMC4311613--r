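---
title: "Methods: from spike trains to a trilinear synchrony decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spike trains to a trilinear synchrony decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Multi-electrode recordings of cortical spiking activity produce one spike
train per electrode, per stimulus condition, per trial. Pairwise
synchrony — coincident firing beyond what the firing rates alone
predict — is a candidate signature of functional coupling between the
recorded neuron groups, and how that synchrony reorganizes across
stimuli and across experimental epochs (here: reversible thermal
deactivation of a feedback source between two baseline epochs) is the
scientific question. With over a hundred electrode pairs, eight stimuli
and dozens of repetitions, the synchrony estimates form a three-way
array that is hard to read directly; `trisync` decomposes it with a
trilinear (PARAFAC / canonical polyadic) model whose per-mode loading
profiles are directly interpretable: which pairs, which stimuli, which
repetitions.

## Synchrony statistics

Spike trains are binned at 2 ms into binary vectors (bin `k` covers
`[k*delta, (k+1)*delta)`; multiple events per bin clip to 1). For two
binned trains `x`, `y` the raw cross-correlogram is the lagged
coincidence count `lambda_raw(tau) = sum_t x(t) y(t + tau)` over integer
lags `-L..L` (default `L = 50` bins, i.e. +/-100 ms; the source analysis
never states its span, so it is configurable).

Chance coincidences driven by firing rates are estimated by the jitter
method in its convolution form: both trains are convolved with a
homogeneous kernel of length `round(t_jitter / delta)` (default 6 ms,
i.e. a 3-tap kernel of 1/3s) and the correlogram of the convolved trains
is subtracted. This is equivalent in expectation to re-drawing each
spike time uniformly within its jitter window, at a fraction of the
cost, and removes any structure slower than `t_jitter` (including
rate co-modulation) while preserving fine-timescale synchrony. The
kernel acts at the 2 ms binned resolution; convolution uses zero-padded
edges and same-length output. The normalized correlogram is
`lambda = lambda_raw - lambda_jitter`, elementwise.

Two scalar statistics summarize a normalized correlogram:

* `kappa_sync`: the largest value within the inclusive lag window
  +/-5 ms around zero, clamped at 0 from below. With 2 ms bins the
  window spans lags -2..+2. Ties report the smallest `|lag|`, negative
  first (the max value itself is tie-invariant).
* `kappa_oscsync`: the fraction of DFT power of the correlogram in a
  chosen frequency band (default 30-50 Hz, low gamma). The band maps to
  DFT bins by `m = round(f * N * delta)`; conjugate bins `N - m` are
  included so a real tone's full power is counted, and the DC bin stays
  in the denominator exactly as the power-ratio definition is written
  (an option excludes it). `N` defaults to the correlogram length; no
  zero padding.

The statistic is computed per (electrode pair, stimulus, repetition)
over the full trial by default. Whether the original analysis window
covered the whole 8 s trial or only the 4 s moving-grating epoch is not
stated in the source; `synchrony_table(window = )` exposes the choice.

## Tensor construction

`enumerate_pairs()` lists unordered live-channel pairs (canonical low-id
first). On a homogeneous grid with spacing `d_grid`, pairs at Euclidean
distance at most `sqrt(2) * d_grid` are *neighboring* (lattice neighbors
including diagonals), the rest *remote*; a full 4 x 4 grid splits into
42 + 78. As printed, the defining inequality in the source is
typographically garbled; the distance reading used here is the only one
that reproduces that 42/78 split.

`build_tensor()` places the statistics into an I x J x K array (pair x
stimulus x repetition) and refuses incomplete or duplicated cells —
missing-data decompositions are out of scope. Centering
(`center_tensor()`) is sequential single-mode subtraction, by default
mode 1 then 2 then 3 (the source specifies sequential centering in all
dimensions but no order). Sequential centering leaves exactly zero
fiber means only for the last-centered mode; earlier modes are
re-perturbed, which is a property of the procedure, not a bug. No
scaling is applied anywhere.

## PARAFAC by alternating least squares

The model is `x_ijk = sum_f a_if b_jf c_kf + e_ijk`. `als_fit()` cycles
conditional least-squares updates of A, B, C; each update solves the
normal equations of a linear regression against the Khatri-Rao product
of the other two loading matrices, so the residual sum of squares is
non-increasing by construction. Convergence is declared when the
relative change in residual falls below `1e-8`, capped at 2000
iterations (the source names no tolerance). Rank-deficient conditional
systems fall back to the Moore-Penrose pseudoinverse with a warning.
Initialization is uniform random in `[0, 1)`; because ALS can stop in
local optima, 10 independent starts are run by default and the best fit
kept (all start fits are reported, with best and median summarized).

The CP scale/sign indeterminacy is fixed by convention: B and C columns
have unit norm, magnitude is absorbed into A, and the
largest-magnitude entry of each B and C column is made positive.
Components are ordered by explained-variance contribution, descending —
cosmetic only, since the model itself has no component order.
`component_congruence()` reports per-mode cosines between components and
their elementwise product ("combined" Tucker congruence); a combined
congruence below -0.85 between two components triggers a degeneracy
warning.

## Choosing the number of components

No exact rule exists; the procedure here mirrors the two-part heuristic
of the source analysis. First, the scree part: components are added
while each new one still removes a *significant* share of the residual
sum of squares left by the previous model. Significance is judged
against a parallel-analysis-style noise benchmark: the share of a
pure-noise tensor's sum of squares that a best rank-one term can
absorb, approximated by the random-matrix top-singular-value fraction
`min_n (sqrt(d_n) + sqrt(IJK / d_n))^2 / (IJK)`. The benchmark adapts
to the tensor's dimensions with no tuned constant — about 10% of the
remaining residual for a 12 x 8 x 20 tensor, about 2% for the full
105 x 8 x 63 session tensor — and sits between the gains of genuinely
structural components and the gains measured when fitting one more
component to unstructured residual (verified empirically in both
regimes). A fixed fraction can be supplied via `rel_gain_tol`; a
0.01-percentage-point absolute floor covers the noiseless edge case.
Second, the binding congruence
part: among the admitted candidates, the chosen `F` is the largest whose
best model has no pair of components with combined congruence magnitude
above 0.85 ("correlated components"; the 0.85 level is standard multiway
practice — the source gives no number). `F = 1` is always admissible; a
selection where every larger candidate is correlated is flagged.

## Validation

*Split-half*: repetitions are split by index parity (odd/even), which
interleaves the warm/deactivation/rewarm phases equally into both
halves; each half is fitted independently and components are aligned by
a greedy assignment on combined congruence over the shared pair and
stimulus modes. Similar loadings and similar explained variances in the
halves indicate a stable model.

*Residual bootstrap*: residuals of the baseline fit are either resampled
with replacement (empirical set) or replaced by draws from a Gaussian
fitted to them (`Normal(mean(e), sd(e))`); surrogate tensors are refit
and scored against the baseline by the factor-match score (congruence
product over all three modes after alignment). Agreement between the two
score distributions indicates insensitivity to non-Gaussian errors —
the relevant check because least squares is only maximum likelihood
under Gaussian errors, and synchrony statistics are not Gaussian. Errors
are added to the model reconstruction by default (parametric bootstrap);
the source's wording "added to the original data" is available verbatim
as `mode = "literal"`, which stacks new noise on top of the residuals
already present.

## The PCA baseline

`pca_on_tensor()` unfolds the array (default: repetition mode as
observations, where the contrast with the trilinear model is most
direct) and runs column-centered SVD. For data that truly factorizes
trilinearly *plus substantial measurement noise*, PCA must absorb noise
variance to accumulate a given share of total variance and needs at
least as many components as the trilinear rank; on noiseless trilinear
data the unfolding has matrix rank F and PCA trivially saturates within
F components, so the contrast is only meaningful — and only asserted —
in the noisy regime.

## The synthetic experiment generator

No recordings are distributed with the source analysis, so the package
generates its own study conditions. `simulate_experiment()` reproduces
the session structure: a 4 x 4 grid at 500 um pitch with one dead
channel (channel 13 here; which electrode was dead is not recorded),
hence 15 live channels and 105 pairs; 8 stimuli (4 grating orientations
x 2 motion directions); 8 s trials (2 s gray + 2 s static + 4 s moving
grating); and 63 repetitions per stimulus as 3 cycles x 7 repetitions
for each phase — warm (1-21), deactivation (22-42), rewarm (43-63).

Synchrony is planted by the mother-process construction: each
within-assembly pair receives a Poisson train of shared events copied
into both channels with independent 1 ms Gaussian timing jitter (inside
the +/-5 ms detection window, wider than one 2 ms bin, so peaks are
realistic rather than single-bin). The mother rate is
`injection_rate x stimulus weight x phase multiplier`, giving the
planted synchrony an exactly trilinear rate structure. The three default
assemblies are overlapping 6-channel groups with distinct preferred
stimuli *and* distinct deactivation sensitivities (1.0, 0.6, 0.25, with
a 0.9 rewarm factor for the second); identical phase profiles would
make the repetition factor k-rank 1, violate Kruskal's uniqueness
condition for a 3-component model, and leave the planted decomposition
unrecoverable in principle, while the overlap produces the dense
pairwise synchrony pattern typical of cortical correlation matrices (a
pair driven by two assemblies simply sums their mother rates, which
preserves exact trilinearity). The default deactivation multiplier 0.3
plants the synchrony dip in repetitions 22-42. An optional common
sinusoidal rate modulation (default 40 Hz) with a trial-shared random
phase gives a designated channel group gamma-band oscillatory
synchrony.

Default rates are a 20 Hz Poisson background per channel and a 15 Hz
injection at preferred stimulus and full phase multiplier. The
injection share is deliberately large: a single-trial `kappa_sync` from
an 8 s train pair has a chance-coincidence noise floor of ~2.5 counts
and counting noise that grows with the rates, and only when assembly
pairs share an appreciable fraction of their spikes does the synchrony
tensor reach the explained-variance regime the method is designed for —
as is typical for gamma-synchronized multi-unit activity, where
correlogram peaks are of the order of the firing rate itself. With weak
injections the tensor is dominated by estimation noise, every component
removes a share of residual indistinguishable from the noise benchmark,
and any honest rank-selection heuristic reports F = 1.

What the generator does *not* emulate: biophysical neurons, LGN or
feedback circuitry, within-trial rate nonstationarity beyond an
optional per-epoch rate factor, electrode drift, and spike-sorting
artifacts. Passing tests on this emulation therefore demonstrate
correctness of the analysis chain on data whose generative assumptions
match what the jitter-corrected correlogram measures — not performance
on raw cortical recordings.

A nonlinearity is worth understanding when interpreting end-to-end
results: `kappa_sync` is a clamped maximum over five lag bins, so its
expectation is a soft-thresholded, compressive function of the planted
rate product, with a wide transition around the noise floor. The
expected statistic surface is consequently *not* exactly rank-3 in the
planted loadings even in the noise-free limit. The global least-squares
optimum (verified by truth-initialized refits) recovers the planted
assemblies cleanly in the pair mode and the deactivation dip in the
repetition mode, but its numerical congruence to the raw planted
loading vectors saturates well below 1; exact-recovery assertions are
therefore made on `simulate_tensor()` fixtures, where the measurement
is the identity, and the experiment-level tests assert assembly
identification, dip direction and significance.

## Problem sizes and numerical choices in the test suite

The test suite and the acceptance script generate everything they use.
Tensor-level statistical checks use planted-rank tensors of dimensions
around 12 x 8 x 20 to 30 x 8 x 40 with 20-seed replication; the
end-to-end pipeline runs at the full default scale (105 pairs x 8
stimuli x 63 repetitions, ~1.9 million spikes) once. ALS tolerance
1e-8, multi-start counts 4-10 depending on the check, congruence
threshold 0.85, scree threshold 10% of remaining residual. Monte-Carlo
null checks (Poisson pairs, 100 seeds) compare means against 3 standard
errors. Where a check is inherently directional (deactivation dip,
oscillation-band elevation), one-sided rank tests at alpha = 0.01-0.05
are used over independent seeds.
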