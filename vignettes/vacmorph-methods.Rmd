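---
title: "Methods: vacuole morphodynamics, pollen hydration, and the NCC state-space model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vacuole morphodynamics, pollen hydration, and the NCC state-space model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacmorph)
```

## The measurement problem

Papilla cells on the Brassicaceae stigma supply water to compatible
pollen. Their large central vacuole remodels continually before
pollination — constricting, shedding small and tubular satellite
vacuoles, re-fusing — and becomes quiescent after pollination or under
drugs that block the remodeling. Two readouts quantify this:

* a **frame-similarity series**: the normalized correlation coefficient
  (NCC; Pearson correlation over pixels) between the frame at time $t$
  and the first frame of the movie. A static cell stays near 1; active
  remodeling pushes the series down.
* a **constriction count**: the number of times a new vacuole border
  appears completely across the cell within a 10-minute observation
  window.

Pollen hydration is read out in parallel as the percentage change in
pollen width, measured as the minor axis of a moment-matched ellipse.

## Preprocessing chain

The NCC is computed after, in this order: medial z-slice selection
(second of three or third of five slices — `select_medial_slice()`), a
3×3 median filter with reflection padding (`median_filter3()`), and a
histogram adjustment mapping the 97th intensity percentile to the
dynamic-range maximum (`normalize_percentile()`). All arithmetic after
filtering is floating point; outputs are not re-quantized before the
correlation. Since the NCC is invariant to positive affine intensity
maps, the percentile cap matters only through its clipping of the top 3 %
of pixels (it suppresses the influence of rare bright speckle).

Two choices here were genuinely open:

* **Per-frame vs per-sequence normalization.** The percentile cap is
  applied per frame by default, the common display-normalization
  practice; `preprocess_stack(per_frame = FALSE)` pools the histogram
  over the whole sequence instead. The package exposes both because the
  protocol wording does not fix the scope.
* **Degenerate frames.** A constant (zero-variance) frame has no defined
  correlation; `ncc()` returns `NA` with a `degenerate` attribute, and
  `ncc_series()` propagates the missing entry. Missing entries are
  excluded from model fitting rather than imputed.

## Constriction detection

The field counting rule is visual: a *new* border spanning the whole cell
width. `detect_constrictions()` operationalizes it directly: per frame,
pixels above an Otsu threshold (computed on the masked frame) are scanned
row-wise; rows whose bright pixels cover at least `span_frac` (default
0.9) of the local cell width form border candidates (contiguous runs
merge into one candidate, because a physical border is 1–3 px thick); a
candidate becomes an *event* if no candidate existed within `merge_dist`
(5 px) of its axial position during the previous `persistence` (2)
frames. "Local width" matters because the cell tapers at the tip — a
border near the apex is shorter in absolute pixels but still spans the
cell. Raising `span_frac` can only remove candidates, so counts are
monotone non-increasing in it; this is tested as a property.

A border that disappears and reappears at the same site after the
persistence window counts again, flagged in the `reappearance` column —
the underlying manual protocol does not specify this case, so the
detector makes its choice visible rather than silent.

All detector defaults were validated only against the synthetic ground
truth (recall and precision 1.0 over 20 noisy preset movies; exact counts
on noiseless movies). Real movies may need different thresholds; manual
counts can bypass detection entirely via CSV.

## Pollen hydration

`fit_ellipse_minor_axis()` fits the ellipse with the same normalized
second central moments as the segmented grain (adding the 1/12 px²
variance of a unit pixel, the usual discrete-moment convention) and
returns $4\sqrt{\lambda_{\min}}$ scaled by pixel size. The hydration rate
is $(L_t-L_0)/L_0\times100$ with $L_0$ the width at the first recorded
frame, evaluated by default at 5, 10 and 15 min with a ±0.5 min matching
tolerance (half the 1-min acquisition interval).

## The state-space model

For a control and an experimental condition observed at time points
$t=1..T$ (the $t=0$ self-comparison, which is exactly 1 and outside the
Beta-proportion support, is excluded):

$$\mu[t]\sim\mathrm{Normal}(\mu[t-1],\sigma_\mu),\qquad
\mathrm{delta}[t]\sim\mathrm{Cauchy}(\mathrm{delta}[t-1],\sigma_{\mathrm{delta}}),\quad t=2..T$$

$$\mathrm{NCC_{c}}[t]\sim\mathrm{BetaProportion}(\mu[t],\kappa),\qquad
\mathrm{NCC_{e}}[t]\sim\mathrm{BetaProportion}(\mu[t]+\mathrm{delta}[t],\kappa)$$

with $\mathrm{BetaProportion}(\theta|\mu,\kappa)=
\mathrm{Beta}(\theta\,|\,\mu\kappa,(1-\mu)\kappa)$ and $\kappa$ shared
across groups and time. Each cell's NCC value at time $t$ is treated as
an i.i.d. draw from its group's observation distribution at that $t$ —
the minimal extension of the single-series equations to $n$ cells per
condition. The heavy-tailed Cauchy transition lets the group difference
jump abruptly (e.g. when a treatment effect switches on mid-series)
without forcing the smooth component to follow.

**Priors.** Following the default behaviour of the software the model was
originally specified for, every parameter gets an improper uniform prior
on its *constrained* support ($\mu[t]\in(0,1)$, $\mu+\mathrm{delta}\in(0,1)$,
scales $>0$); on the unconstrained sampling scale this contributes the
transform log-Jacobians. (Flat priors on the *unconstrained* scale would
instead put an extra $1/\sigma$ on each scale parameter and make the
posterior improper as $\sigma_{\mathrm{delta}}\to0$; this alternative
reading was considered and rejected.)

**Sampling.** `sample_posterior()` runs Hamiltonian Monte Carlo (compiled
leapfrog integrator, analytic gradients, dual-averaging step size
targeting 0.8 acceptance, diagonal metric adapted in expanding warmup
windows, leapfrog count jittered on 1..`max_steps`). Defaults: 4 chains ×
1000 warmup + 1000 draws, seeded deterministically per chain.

The sampler works in *non-centered* coordinates for the difference walk:
innovations are parameterized as $e_t=\tan(\pi(u_t-\tfrac12))$ with
$u_t\in(0,1)$, so $\mathrm{delta}[t]=\mathrm{delta}[t-1]+
\sigma_{\mathrm{delta}}e_t$ and the Cauchy transition density is absorbed
into the uniform prior on $u_t$. This removes the
$\sigma_{\mathrm{delta}}\to0$ funnel (the worst case being a truly
constant difference, exactly the null-calibration world) while targeting
the identical posterior — the change of variables is exact, and the test
suite verifies the identity between the centered and non-centered
evaluators analytically. The centered log posterior remains available as
`log_posterior()`, the reference the compiled code is tested against.

**Diagnostics and summaries.** Split-Rhat and effective sample size are
reported per parameter; if any Rhat exceeds 1.01 or ESS falls below 100
the posterior carries `converged = FALSE` and a warning. (With 4×1000
draws the split-Rhat noise floor is about 1.01–1.02, so the flag is
conservative; ESS is the more informative number.) `summarize_posterior()`
reports per-$t$ posterior medians and central 95 % credible intervals of
$\mu$ and delta, plus a flag for intervals excluding 0 — the working
criterion for a condition difference. Out-of-support observations are
clipped to $(10^{-6}, 1-10^{-6})$ with a warning; in practice only the
excluded $t=0$ value sits on the boundary.

## The synthetic world

`simulate_vacuole_sequence()` renders a 30×120 px capsule-shaped cell
(hemispherical tip) whose central vacuole is drawn as a static 2-px
bright contour, with:

* `satellite_vacuole_count` small bright rings near the apex performing a
  random walk whose step size scales with the total event rate — so a
  scenario with zero rates renders bit-identical frames, and more active
  conditions show more frame-to-frame change;
* constriction events: a 2-row bright line across the full local cell
  width, persisting 2–6 frames, onset ≥ 3 frames into the movie, with
  axial separation constraints ensuring each logged event is a separately
  detectable appearance;
* fusion events: a satellite vacuole disappears (or a transient blob is
  absorbed at the contour);
* wortmannin-style invagination: *static* internal tonoplast rings —
  abnormal but frozen morphology, which is exactly why the treated cell's
  NCC stays high relative to mock;
* Poisson shot noise plus Gaussian read noise (`noise_sd`; 0 disables
  both, giving noiseless geometry for exact-count tests).

Event counts per movie are drawn as `qpois(u, rate)` with the uniform
draw at a fixed position in the RNG stream, making counts comonotone in
the rate for a fixed seed: a lower-rate preset can never produce more
events than a higher-rate one under the same seed.

Preset rates (events per 10 min) encode only the *orderings* reported for
the real conditions — none of the underlying numbers are published:
unpollinated = mock (8 constrictions, 3 fusions), E-64d 14 (fusion
inhibitor, many stacked tubular vacuoles), PDMP 2, pollinated 1.5,
wortmannin dose-responsive from 8 (dose 0 = mock) down to ≈1.9 at 500 µM
with half-effect near 33 µM. Hydration presets give mock a 40 % plateau
with τ = 4 min (a typical saturating hydration curve reaching ≈ 38 % by
15 min) and suppress the wortmannin plateau dose-dependently; pollen
$L_0$ defaults to 20 µm.

What the generator does **not** emulate: real confocal optics (PSF,
z-bleed-through, photobleaching), cytoplasmic streaming, cell-to-cell
geometry variation, drift/registration error, and the visual complexity
of real tonoplast texture. A green test therefore establishes that the
*algorithms* implement their stated rules and recover known truths — not
that the detector thresholds transfer to real microscope data.

## Numerical choices

* NCC is accumulated in double precision; the brute-force definition is
  the test oracle at $10^{-10}$.
* Percentile = R's default (type-7) sample quantile; the cap makes
  normalization idempotent only up to re-estimation on the clipped frame
  (relative $\sim10^{-5}$), which the tests acknowledge.
* Otsu threshold on a 256-bin histogram of masked intensities, recomputed
  per frame so slow brightness drift cannot move detections.
* HMC initial values are moment-matched (per-$t$ geometric means of the
  observations on the logit scale) with per-chain jitter; initialization
  retries with shrinking jitter if the log posterior is not finite, and
  errors only after 30 attempts.
* The Dunnett test integrates the exact equicorrelated multivariate-$t$
  tail with `mvtnorm` (quasi-Monte-Carlo with fixed seed, absolute
  tolerance $10^{-6}$); Tukey-HSD uses `ptukey`; Welch uses `t.test`.
  Stars follow the convention `**` $p<0.01$, `***` $p<0.001$.

## Known limitations

* The constriction detector assumes the cell mask is given (the generator
  provides it; real data would need a segmentation step first) and that
  borders are transverse — strongly oblique borders would be split across
  rows and could fall below `span_frac`.
* The TIFF codec intentionally covers only uncompressed little-endian
  grayscale; anything else should be converted on import.
* With ≈ 5 cells per group the Beta-proportion likelihood cannot separate
  within-cell from between-cell variance; $\kappa$ absorbs both, so
  credible bands are calibrated for exchangeable cells only.
* The split-Rhat flag at 1.01 trips occasionally at default chain
  lengths even when ESS is in the hundreds; treat `converged = FALSE`
  with large ESS as a prompt to lengthen chains, not as a failed fit.
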