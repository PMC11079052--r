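---
title: "Quantifying chromocenter binding: foci measurement, FRAP kinetics and the buffering diagnostic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromocenter binding: foci measurement, FRAP kinetics and the buffering diagnostic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromofoci)
```

## The scientific problem

In mouse cells, methyl-CpG binding proteins such as MeCP2 concentrate in a
handful of bright nuclear foci — chromocenters, clusters of pericentromeric
heterochromatin built on long, heavily CpG-methylated satellite DNA arrays.
Whether such foci are liquid-liquid phase-separated condensates or simply
the visible footprint of dense methyl-CpG binding sites is a live question,
and it is answered quantitatively: by measuring foci against nucleoplasm in
live-cell images, by timing fluorescence recovery after photobleaching
(FRAP), by testing how foci respond to expression level, and by analysing
the satellite sequences themselves. This package implements that entire
measurement chain, together with a synthetic-data module that generates
images, FRAP traces, cell populations and satellite arrays with known
ground truth, so every stage can be validated end to end without any
external data.

## Synthetic scenes and what they do (and do not) emulate

`simulate_scene()` renders a two-channel field of view: disc-shaped nuclei
whose DNA channel carries bright foci over a dimmer nucleoplasm, and a
reporter channel that either co-enriches at foci (`colocalized`) or stays
flat across the nucleus (`diffuse`). Key choices:

* **Hard-edged top-hat foci.** Foci are uniform discs, not blurred blobs.
  This makes every downstream quantity exact by construction — the
  foci/nucleoplasm ratio equals the configured contrast, integrated
  intensity decomposes exactly into foci and nucleoplasm terms, and the
  full segment–detect–measure pipeline must reproduce generator parameters
  *exactly* on noise-free scenes. A smoothed profile would trade these
  exact oracles for realism without changing any measured quantity's
  definition; smoothing is instead available on the detection side
  (`foci_config(smoothing_sigma_px = ...)`).
* **Poisson foci counts, fixed radius.** Real chromocenter size and count
  distributions are not specified by any reference we reproduce, so the
  generator declares simple defaults (Poisson count with mean 4, fixed
  radius) rather than pretending to infer them.
* **Additive Gaussian noise, clamped at zero.** No photon (Poisson) noise,
  no point-spread function, no 3D: passing tests demonstrates correctness
  of the measurement chain, not robustness to every optical artefact of a
  confocal microscope.

Intensities are in arbitrary units with the nucleoplasm at 100 by default;
noise is expressed in the same units (so `noise_sd = 15` is 15% of the
nucleoplasm level).

## Segmentation and per-nucleus foci detection

`segment_nuclei()` is a classical segmenter: global Otsu threshold on the
(optionally max-projected) DNA channel, hole filling, connected components,
minimum-area filter, optional distance-transform watershed for touching
nuclei. Published masks from external tools (e.g. deep-learning
segmenters) can be imported via `method = "external_mask"`, which validates
and relabels rather than recomputes.

One numerical choice deserves a note: the Otsu threshold is computed on
`log1p` intensities. With bright foci occupying a few percent of the
image, the raw histogram is trimodal (background / nucleoplasm / foci) and
the Otsu optimum can flip between the background–nucleus split and the
nucleus–foci split depending on the exact foci area. The log transform
compresses the foci mode onto the nucleoplasm mode, making the
background–nucleus split the stable optimum. On noise-free synthetic
scenes the segmentation is then pixel-exact; at noise up to 15% of the
nucleoplasm level the per-nucleus Jaccard overlap with ground truth stays
above 0.95.

`detect_foci()` thresholds *within each nucleus independently* (per-nucleus
Otsu by default, `mean + k*SD` as an alternative, k = 2), which makes
detection invariant to per-cell absolute brightness — two nuclei with the
same internal contrast but five-fold different expression yield identical
foci calls. A nucleus with constant intensity has no defined threshold and
yields no foci; it is reported in the `skipped_nuclei` attribute rather
than silently dropped.

`measure_nuclei()` reports, per nucleus and channel: mean intensity within
foci, mean in the nucleoplasm (the nucleus minus its foci), integrated
nuclear intensity, and the foci/nucleoplasm ratio (absent when a nucleus
has no foci). Areas are converted to µm² only at output
(`pixels * pixel_size_um^2`); all internal arithmetic is in pixels.
`classify_distribution()` turns ratios into the three-category
spotty / mixed / diffuse call used for species panels; the thresholds
(spotty at ratio ≥ 1.5, diffuse at ≤ 1.1) are package defaults calibrated
on synthetic scenes — the original classification of real cells was manual,
so these numbers are exposed and echoed in every output rather than
hard-coded.

## FRAP normalization and the two-phase association model

A FRAP acquisition records four series: the bleached spot, an unbleached
control spot, an extracellular background, and time (1 frame/s for 400 s
with 5 pre-bleach frames in the default geometry). `normalize_frap()`
applies the standard double normalization

$$N(t) = \frac{F(t) - B(t)}{C(t) - B(t)} \times
         \frac{\bar C_{pre} - \bar B_{pre}}{\bar F_{pre} - \bar B_{pre}}$$

with the pre-bleach terms averaged over all pre-bleach frames (a
single-frame option exists for sensitivity checks). Because acquisition
photobleaching attenuates the FRAP and control spots identically (same
illumination), the control-spot ratio cancels it exactly: for noise-free
traces the normalized curve is invariant to the bleach rate and to any
constant background, and the normalized pre-bleach level is exactly 1.
These invariances are tested on a grid of bleach rates and backgrounds at
1e-6, and they are the reason the equation uses the control-spot ratio at
all.

`fit_two_phase()` fits

$$Y(t) = y_0 + s_f\,(1 - e^{-k_f t}) + s_s\,(1 - e^{-k_s t})$$

by bounded Levenberg-Marquardt least squares (spans and rates ≥ 0).
Initialization: $y_0$ at the first post-bleach value; total span at the
mean of the last 10 points minus $y_0$, split 70/30 between phases; rates
0.1 and 0.01 s⁻¹; a fixed schedule of up to five rate-rescaled restarts
(x0.25, x4, x0.05, x20, x100) guards against local minima, and
$k_f \ge k_s$ is enforced by swapping after convergence. A constant input
series is recognized and returns the exact flat fit rather than a
degenerate optimizer run. The fit is a classed model object with `coef`,
`predict`, `fitted`, `residuals`, `summary` and `plot` methods.

`summarize_fit()` converts the fitted curve into the reporting convention:

* **mobile fraction** = 100 x the fitted curve at the *last observed time
  point* — not the asymptote. Slowly recovering cells never plateau within
  the window, and the end-of-window convention is the one that matches how
  such curves are summarized in practice.
* **immobile fraction** = 100 − mobile, exactly.
* **T50** = the smallest time at which the curve crosses 0.5, i.e. half of
  the *pre-bleach* level (which is 1 by construction of the
  normalization), not half of the plateau. Found by bisection to 1e-6
  relative tolerance (the model is non-decreasing, so bisection is exact);
  it is absent, with a flag, when the curve never reaches 0.5.

The package ships two preset recovery regimes (`frap_regime_params()`)
spanning the observed contrast between methylation-rich and
methylation-free cells: slow (mobile 75.2%, T50 75.5 s — a large stably
bound pool) and fast (mobile 97.5%, T50 9.9 s — near-complete rapid
exchange). Given a target plateau and T50 with fixed $y_0$ and rates, the
two spans solve a 2x2 linear system, so the presets hit their targets
exactly. Parameter recovery is validated on 20 noisy replicates per regime
(N(0, 0.02) on the normalized scale, 1 Hz, 400 s): every replicate's
mobile fraction lands within 3 points and T50 within 10% of truth, and the
two regimes never overlap in T50.

## The buffering diagnostic

Liquid-liquid phase separation makes a sharp prediction ("concentration
buffering"): above the saturation concentration $c_{sat}$, adding more
protein grows the condensates while the concentration *inside* them stays
pinned at $c_{sat}$. The alternative ("size buffering") is that foci size
and number stay put while concentrations inside and outside rise together,
keeping their ratio stable. `run_buffering_test()` regresses, over a
population of cells, log10 focus concentration, focus area and focus count
on log10 total expression, and calls the regime from the three R² values:
concentration buffering when the concentration R² is at or below `r2_low`
(0.2) and the area R² at or above `r2_high` (0.5); size buffering when the
concentration R² is at or above `r2_high` and both area and count R² at or
below `r2_low`; otherwise `indeterminate`. The two-threshold rule is a
package construction — R² values are what the underlying plots show, but no
published decision rule exists — so the thresholds are exposed, echoed in
the result, and `indeterminate` is the honest default between them.
Fluorescence axes are log-scaled because transient transfection spans
decades of expression; area and count are left linear (only the
fluorescence axes are logarithmic in the source plots).

`simulate_population()` generates both regimes with multiplicative
lognormal noise (unit mean, CV `noise_cv`). Under concentration buffering
the focus concentration is pinned at `c_sat`, foci area grows linearly
with expression, and the nucleoplasm rises weakly
(`(E/E_min)^0.2` by default) — a pinned-but-not-perfectly-flat dilute phase,
which is what multicomponent cellular condensates show and what makes the
foci/nucleoplasm ratio *fall* with expression under this regime. Under
size buffering both concentrations scale linearly with expression and area
and count are fixed up to noise. At the study scale (100 cells, CV 0.1,
two decades of expression) the diagnostic calls both regimes correctly in
well over 95% of seeded populations; `ratio_stability()` and
`bin_expression()` (tercile low/medium/high split by largest remainder)
cover the accompanying presentations.

## Satellite sequence analyses

The methylation side of the story is sequence-level. The package models a
sequence plus the set of methylated CpG cytosines (`methylated_seq`;
forward-strand C only — the emulated assays cannot see hemimethylation)
and four built-in restriction enzymes as sensitive/insensitive pairs:
HpyCH4IV (ACGT, blocked by CpG methylation) versus ApoI (RAATTY, not
blocked), and the isoschizomers HpaII/MspI (both CCGG, only HpaII
blocked). `find_sites()` scans the top strand with full IUPAC support (the
built-in sites are palindromic, so one strand suffices); a blocked
enzyme's match is suppressed when *any* methylated CpG lies in the
recognition window — blocking is all-or-nothing, partial-activity kinetics
are out of scope. `digest()` returns fragment lengths on a linear
molecule; they always sum to the input length, an invariant tested across
random sequences, enzymes and methylation patterns. A fully methylated
satellite array therefore yields a single full-length fragment under
HpyCH4IV or HpaII while MspI still cuts — the digestion contrast that
reads out satellite methylation on a blot.

`gc_content()` is exact base counting with strict input validation (the
bundled red deer satellite I probe is 725 nt at 55.2% GC — markedly
GC-rich against a ~40% GC bulk genome, which matters because it shows
AT-richness is not what makes satellite arrays coalesce).
`count_probe_matches()` is a sliding-window Hamming scan (both strands on
request, overlaps counted) validated against a naive re-scan.

`tandem_structure()` estimates the repeat period as the lag maximizing
per-base self-identity, locates the maximal repeat span at that lag (probes
cloned into vectors carry non-repetitive flanks, so the span is reported
rather than assumed), and counts unit copies against the modal consensus.
A trailing truncated copy counts when at least a third of the unit is
present at the identity threshold: cloned amplicons are routinely cut
mid-unit, and a probe that touches three repeat copies is a three-repeat
probe even when the last copy is incomplete. On the bundled mouse major
satellite probe (804 nt printed sequence) this reports a 234-nt period and
3 copies: the satellite insert between the vector flanks is 578 nt — two
complete units plus 47% of a third.

## Statistics

The toolbox mirrors the tests used around such imaging data: Welch's
unpaired two-tailed t test (`welch_t()`), Welch's heteroscedastic one-way
ANOVA (`welch_anova()`, with the Brown-Forsythe F reported alongside as a
labeled companion statistic), Games-Howell post-hoc comparisons
(`games_howell()`: pairwise studentized-range statistics with per-pair
Welch degrees of freedom; the studentized-range probabilities come from
R's `ptukey`, which performs the required numerical integration), and
Tukey outlier fences (`tukey_outliers()`, quartiles by linear
interpolation, strict inequality at the fences; `box_stats()` exports the
matching box-plot summary). For two groups the chain is consistent by
construction — Welch ANOVA, Welch t and Games-Howell agree — and the t test
holds its nominal type-I error (within [0.045, 0.055] at alpha = 0.05 over
20,000 null simulations with 3-fold unequal variances). Small-sample
Games-Howell conventions differ slightly across references; this
implementation is pinned against an independent reference implementation
to 1e-6 rather than asserted to match any particular software bit for bit.

## Pipelines and reproducibility

`run_foci_pipeline()` (TIFF directory to measurement/call/summary CSVs)
and `run_frap_pipeline()` (trace manifest to per-trace fits and a grouped
mobile/immobile/T50 table with SD and SEM, non-converged fits excluded and
counted) compose the stages with per-file error capture: a corrupt image
or missing trace is recorded in the JSON run manifest and the run
continues; only an empty or fully failed input set is an error. Manifests
record the package version, a config hash, per-file checksums and
timestamps; identical config and inputs reproduce identical outputs. All
generators take explicit integer seeds — no global RNG state is consumed
or disturbed.

## Problem sizes used in the shipped checks

The bundled validation uses 4-6 nuclei per synthetic scene, 100-cell
populations with 20 seeded replicates per regime, 20 noisy FRAP replicates
per recovery regime at 395 post-bleach frames, and 20,000 null simulations
for the calibration check — sizes at which every statistical criterion is
comfortably powered while the whole suite runs in well under a minute.

## Known limitations

* 2D discs only; no Z-stacks, PSF optics or photon-noise calibration.
* The classifier thresholds (1.5/1.1) and the buffering decision
  thresholds (0.5/0.2) are calibrated constructions, exposed in the
  configuration, not community standards.
* Methylation blocking is binary per recognition site; no partial enzyme
  activity.
* The tandem-repeat estimator assumes a single dominant period; nested or
  higher-order repeat structure is reported only through the chosen lag.
* FRAP fitting is empirical two-phase association; no reaction-diffusion
  modeling or bleach-spot geometry correction.
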