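# trisync

Trilinear decomposition of spike-train synchrony tensors.

`trisync` is an R package for asking *which electrode pairs synchronize,
for which stimuli, and when* in multi-electrode spike recordings. It
implements the full chain:

1. **Synchrony estimation.** Spike trains are binned at 2 ms; for each
   electrode pair the cross-correlogram
   `lambda_raw(tau) = sum_t x(t) y(t + tau)` is corrected for
   rate-driven chance coincidences by the jitter method in its
   convolution form (both trains convolved with a homogeneous kernel
   spanning `T_jitter = 6 ms`, correlogram of the convolved trains
   subtracted). Two scalars summarize the normalized correlogram: the
   synchrony `kappa_sync` (largest non-negative peak within +/-5 ms of
   zero lag) and the oscillatory synchrony `kappa_oscsync` (fraction of
   DFT power in a chosen band, default 30-50 Hz).
2. **Tensor assembly.** One `kappa` per (electrode pair, stimulus,
   repetition) fills a three-way array; pairs on a grid are classified
   as *neighboring* (distance <= sqrt(2) x grid spacing; 42 of the 120
   pairs of a full 4 x 4 grid) or *remote* (78). The array is centered
   sequentially in all three modes; no scaling.
3. **PARAFAC (canonical polyadic) decomposition** fitted by multi-start
   alternating least squares:
   `x_ijk = sum_f a_if b_jf c_kf + e_ijk`, with loading matrices A
   (pairs), B (stimuli), C (repetitions). The component count F is
   chosen by a two-part heuristic (residual decrease still significant;
   no two components with combined Tucker congruence above 0.85).
4. **Validation**: odd/even split-half refits with congruence-aligned
   factor-match scores, and a residual bootstrap comparing refits under
   empirical vs Gaussian-fitted error draws.
5. **Bilinear baseline**: PCA on the unfolded tensor, with the count of
   components needed to reach a cumulative-variance threshold.
6. **Synthetic experiment generator** emulating the study design the
   method was built for — a 4 x 4 grid (500 um pitch, one dead channel,
   105 live pairs), 8 grating stimuli, 8 s trials, 63 repetitions per
   stimulus in warm (1-21) / deactivation (22-42) / rewarm (43-63)
   phases — with pairwise synchrony planted via jittered mother
   processes whose rates have exact trilinear (pair x stimulus x phase)
   structure, and optional common gamma-band rate modulation.

## Worked example

```r
library(trisync)

# a full synthetic session: 15 live channels, 8 stimuli, 63 repetitions,
# three assemblies whose synchrony dips during the deactivation phase
ds <- simulate_experiment(seed = 42)
ds
#> spike_dataset: 15 live channels, 8 stimuli, 63 repetitions, 8 s trials, 2417141 events
#> phases: warm -> deactivation -> rewarm

tab <- synchrony_table(ds)                 # 105 x 8 x 63 kappa_sync values
x   <- center_tensor(build_tensor(tab))    # centered synchrony tensor
x
#> synchrony_tensor [105 pairs x 8 stimuli x 63 repetitions]; metric kappa_sync; centered: mode1, mode2, mode3

fit <- als_fit(x, n_components = 3, seed = 1)
fit
#> parafac_model: F = 3 on [105 x 8 x 63], explained variance 10.34%, 76 iterations (converged)

# the ten pairs loading strongest on component 1 are one planted
# assembly; their synchrony dips during the deactivation phase
top_pairs <- rownames(fit$A)[order(abs(fit$A[, 1]), decreasing = TRUE)[1:10]]
top_pairs
#>  [1] "6-9"  "9-10" "1-2"  "1-10" "1-5"  "5-9"  "5-10" "6-10" "1-6"  "2-6"

sub <- tab[tab$pair %in% top_pairs, ]
phase <- cut(sub$repetition, c(0, 21, 42, 63),
             labels = c("warm", "deactivation", "rewarm"))
round(tapply(sub$kappa_sync, phase, mean), 2)
#>         warm deactivation       rewarm
#>         6.99         3.81         6.97

sh <- split_half(x, 3, seed = 2)
sh
#> split_half_result: F = 3; explained variance odd 10.92% / even 12.52%; pair+stimulus factor match 0.3836
```

The explained variance is modest because single-trial synchrony
estimates carry heavy counting noise — the model captures the planted
structure (the assembly pairs and the dip) while most of the tensor's
sum of squares is estimation noise. The three panels of `plot(fit)`
read like the loading figures standard in multiway analysis: pair
loadings say *which* connections, stimulus loadings say *for what
input*, repetition loadings say *when* — here the planted dip in
repetitions 22-42, visible above as a drop of mean synchrony from ~7.0
to ~3.8 coincidences and full recovery after rewarming.

The same stages are scriptable end to end with provenance:

```r
cfg <- default_pipeline_config(seed = 1, out_dir = "run1")
run_pipeline(cfg, stages = c("simulate", "metrics", "tensor",
                             "decompose", "select", "splithalf", "pca"))
```

or from a shell via `inst/scripts/trisync-pipeline.R`. Every artifact is
a plain TSV/JSON file and the manifest records seeds, configuration and
content hashes.

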