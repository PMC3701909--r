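# smkin — single-molecule pMHC:TCR binding kinetics

`smkin` is an R toolkit for measuring how long individual peptide-MHC
(pMHC) ligands stay bound to T cell receptors (TCRs) in live-cell
single-molecule imaging, and for testing whether those dwell times could
be an artifact of serial rebinding within receptor clusters. It is aimed
at quantitative microscopists and immunology labs doing supported-bilayer
/ TIRF single-particle tracking, and at anyone who wants a fully
synthetic, ground-truth-labeled test bed for such pipelines.

## The core model

A tracked ligand alternates between fast free diffusion in the bilayer
and a slow, receptor-bound state. A bound fluorophore disappears either
by unbinding (rate `1/τ_off`) or by photobleaching (rate `1/τ_bl`), so
observed dwell times are exponential with

```
f(τ_obs) = (1/τ_bl + 1/τ_off) · exp(−τ_obs · (1/τ_bl + 1/τ_off)),
⟨τ_obs⟩ = (1/τ_bl + 1/τ_off)⁻¹
```

Measuring the bleaching time on a bilayer standard recovers the molecular
off time:

```
τ_off = (1/τ_obs − 1/τ_bl)⁻¹        (requires τ_obs < τ_bl)
```

Around this sit the supporting stages, each its own module: a
synthetic-data generator (two-state Brownian trajectories, stepwise
intensity traces, rendered 16-bit movies with motion blur, fiducial bead
fields — all with ground truth); spot detection and optimal-assignment
track linking; two-component Rayleigh mixture fits of step-size
distributions with bound/free segment classification; Bayesian
change-point detection of intensity steps (photobleach counting, kinase
arrival); two-channel polynomial registration; ZAP70 recruitment
stoichiometry (feature intensity ÷ single-molecule intensity ÷ labeled
fraction); and an event-driven lattice simulation of ligand escape from a
TCR cluster.

## Worked example

Recover an off time from 10,000 simulated observed dwells using a
bleaching standard fitted from 10,000 simulated lifetimes, then count
recruited kinase molecules and check cluster escape:

```r
library(smkin)

tau_obs_true <- 1 / (1/5.2 + 1/30)   # 4.43 s observed mean
dwells <- withr::with_seed(11, dwell_sample(rexp(10000, 1 / tau_obs_true)))
bleach <- simulate_bleaching_survival(tau_bl = 30, n = 10000, seed = 12)
tau_bl <- fit_bleach_rate(bleach)
estimate_kinetics(dwells, tau_bl = tau_bl$tau_bl, tau_bl_sem = tau_bl$tau_bl_sem)
#> <kinetic_estimate> tau_obs = 4.41 +/- 0.044 s (n = 10000), tau_bl = 30.5 s -> tau_off = 5.16 +/- 0.061 s

estimate_stoichiometry(136.0, 47, labeled_fraction = 0.5,
                       feature_sem = 0.04, unit_sem = 2)
#> <stoichiometry_result> 136 counts / 47 counts per molecule = 2.9 visible; 5.8 total at labeled fraction 0.5

simulate_escape(escape_config(cluster_n = 100, k_on = 0.17,
                              n_iter = 10000, seed = 13))
#> <escape_result> tau_esc = 20.54 s over 10000 iterations (tau_off = 5.2 s, ratio 3.95, <n> = 2.96 rebinds)
```

Reading the output: the corrected off time (5.16 ± 0.06 s) recovers the
5.2 s ground truth from dwells whose raw mean (4.41 s) is bleach-biased.
A feature of 136 counts against a 47-count single-molecule calibration
holds 2.9 visible EGFP, about 6 kinase molecules at 1:1 labeling. A
100-receptor cluster releases its ligand after ~3 rebinds — escape takes
a few dwell times, not the orders of magnitude that would mimic a long
single dwell.

The full synthetic pipeline (simulate → dwell extraction → kinetics →
stoichiometry) runs with one call and writes CSV/JSON artifacts plus a
run log:

```r
run_pipeline(list(seed = 1, out_dir = "out"))
```

A thin command-line front end lives at `inst/cli/smkin.R`
(`Rscript inst/cli/smkin.R all --seed 1 --out out`).

## Package layout

| Path | Contents |
| --- | --- |
| `R/sim-tracks.R`, `R/sim-traces.R`, `R/render.R` | synthetic generators and the movie renderer |
| `R/detect.R`, `R/link.R`, `R/mobility.R` | detection, linking, mixture fit, classification |
| `R/changepoint.R` | Bayesian step detection |
| `R/kinetics.R` | dwell-time estimators and the photobleach correction |
| `R/registration.R`, `R/stoichiometry.R` | channel mapping, molecule counting |
| `R/escape.R` | cluster-escape lattice simulation |
| `R/io.R`, `R/pipeline.R` | readers/writers, pipeline driver |
| `vignettes/single-molecule-kinetics.Rmd` | methods notes: model, estimators, design choices, limitations |
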