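# vacmorph

Quantitative analysis of vacuole morphodynamics in stigma papilla cells
and of pollen hydration, for time-lapse fluorescence microscopy.

During compatible pollination in Brassicaceae, the papilla cells of the
stigma donate water to the attached pollen grain. Live imaging of the
tonoplast (the vacuole-bounding membrane) shows that before pollination
the large central vacuole of a papilla cell constricts and fuses
continually, while after pollination — or under drugs such as wortmannin —
this remodeling is suppressed, together with pollen hydration. `vacmorph`
implements the analysis chain used to quantify these observations:

1. **Frame-similarity time series.** Each movie frame is compared with the
   first frame by the normalized correlation coefficient

   $$\mathrm{NCC}(A,B)=\frac{\sum_{x,y}(A-\bar A)(B-\bar B)}
   {\sqrt{\sum_{x,y}(A-\bar A)^2\;\sum_{x,y}(B-\bar B)^2}},$$

   after the standard preprocessing chain: medial z-slice selection
   (second of three or third of five), a 3×3 median filter, and histogram
   normalization capping at the 97th intensity percentile. NCC ≈ 1 means
   the vacuole morphology is unchanged since imaging started.

2. **Constriction counting.** A constriction event is the appearance of a
   new vacuole border *completely across* the papilla cell.
   `detect_constrictions()` automates this manual counting rule (per-frame
   Otsu threshold, row-scan for borders spanning ≥ 90 % of the local cell
   width, 2-frame persistence); manual counts can be supplied as CSV
   instead.

3. **Pollen hydration.** Pollen width is the minor axis of the
   moment-matched ellipse of the grain mask (the Fiji "fit ellipse"
   measure), and the hydration rate at time $t$ is
   $(L_t - L_0)/L_0 \times 100\,\%$.

4. **Bayesian state-space comparison.** NCC series from a control and an
   experimental condition are modeled with a Normal random-walk mean
   $\mu[t]$, a Cauchy random-walk group difference $\mathrm{delta}[t]$,
   and Beta-proportion observations:

   $$\mu[t]\sim\mathrm{Normal}(\mu[t-1],\sigma_\mu),\qquad
   \mathrm{delta}[t]\sim\mathrm{Cauchy}(\mathrm{delta}[t-1],\sigma_{\mathrm{delta}}),$$
   $$\mathrm{NCC_{control}}[t]\sim\mathrm{BetaProportion}(\mu[t],\kappa),\qquad
   \mathrm{NCC_{experimental}}[t]\sim\mathrm{BetaProportion}(\mu[t]+\mathrm{delta}[t],\kappa).$$

   The posterior is sampled by a built-in Hamiltonian Monte Carlo sampler
   (compiled, analytic gradients); a condition difference is reported
   where the 95 % credible band of delta excludes 0.

Because the original confocal movies are not publicly deposited, the
package ships a first-class synthetic generator: tonoplast movies of a
capsule-shaped papilla cell with ground-truth constriction/fusion event
logs, pollen hydration assays with known kinetics, and NCC series drawn
directly from the state-space observation model. Every analysis stage is
validated against these known truths.

## Worked example

```r
library(vacmorph)

scn <- scenario_presets("unpollinated", seed = 1)
scn
#> scenario 'unpollinated': 8 constrictions / 10 min, 3 fusions / 10 min,
#>   4 satellite vacuoles, invagination FALSE, noise sd 6,
#>   60 frames @ 10 s (30 x 120 px), seed 1

sim <- simulate_vacuole_sequence(scn)   # movie + ground-truth event log
head(sim$events[, 1:5], 3)
#>   time_s         kind  position frame duration_frames
#> 1    110 constriction 0.4750000    12               6
#> 2    200 constriction 0.5916667    21               4
#> 3    210       fusion 0.3982120    22              NA

pre <- preprocess_stack(sim$stack)      # median filter + percentile cap
detect_constrictions(pre, sim$cell_mask)
#> constriction_result 'cell1': 6 events in 600 s window (6 detections total)

ns <- ncc_series(pre, cell_id = "unpoll_1", condition = "unpollinated",
                 mask = sim$cell_mask)
round(ns$ncc[c(1, 2, 31, 60)], 3)       # drifts away from 1 as shape changes
#> [1] 1.000 0.954 0.929 0.948

track <- simulate_pollen_assay(L0 = 20, plateau_rate = 40, tau = 4, seed = 1)$track
hydration_timecourse(track)
#>           pollen_id condition time_min rate_percent
#> pollen1.1   pollen1      mock        5     27.30911
#> pollen1.2   pollen1      mock       10     38.98427
#> pollen1.3   pollen1      mock       15     38.99189
```

Fitting the state-space model to NCC series simulated from a known truth
(T = 60 time points, 5 cells per group, κ = 50, delta ≡ −0.1):

```r
truth <- ssm_truth(mu = ncc_decay_path(60), delta = rep(-0.1, 60),
                   kappa = 50, seed = 11)
sdat <- ssm_data(ncc_sim_to_table(simulate_ncc_series(truth)),
                 "control", "experimental")
post <- sample_posterior(sdat, seed = 42)
sm <- summarize_posterior(post)
round(head(sm[, c("time_s", "mu_med", "mu_lo", "mu_hi",
                  "delta_med", "excludes_zero")], 3), 3)
#>   time_s mu_med mu_lo mu_hi delta_med excludes_zero
#> 1     10  0.948 0.928 0.967    -0.112             1
#> 2     20  0.941 0.923 0.958    -0.111             1
#> 3     30  0.927 0.907 0.944    -0.112             1
mean(sm$excludes_zero)   # delta band excludes 0 at every time point
#> [1] 1
```

The whole pipeline — simulate movies per condition, NCC, constriction
counts, hydration, state-space fits, Dunnett/Tukey/Welch group tests,
plots and manifest — runs from one config:

```r
run_pipeline(list(conditions = c("mock", "wortmannin"), dose_um = 500,
                  control = "mock", seed = 1, out_dir = "out"))
```

A command-line front end with subcommands `simulate`, `ncc`, `constrict`,
`hydrate`, `ssm`, `compare`, `run-all` is installed at `inst/cli/vacmorph`
(see `?vacmorph_cli`).

## Documentation

The methods vignette (`vignettes/vacmorph-methods.Rmd`) describes the
model and its assumptions, what the synthetic generator does and does not
emulate, the numerical choices in the sampler, and known limitations.
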