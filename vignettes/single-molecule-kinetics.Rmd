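---
title: "Measuring single-molecule ligand-receptor kinetics under photobleaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-molecule ligand-receptor kinetics under photobleaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smkin)
```

# The measurement problem

A peptide-MHC (pMHC) ligand tethered to a supported lipid bilayer diffuses
freely (D around 0.44 µm²/s) until it binds a T cell receptor (TCR) in the
membrane of an overlying T cell. Binding changes the ligand's mobility: the
complex becomes nearly stationary and drifts slowly toward the center of
the cell contact. Tracking individual fluorescently labeled ligands
therefore reads out binding directly — a track's slow, localized segments
are dwells on a receptor.

Two complications make the dwell time a biased readout of the chemical off
rate:

1. **Photobleaching.** A bound fluorophore can bleach before it unbinds.
   Both events look identical (the slow spot disappears), so the observed
   dwell is the minimum of two exponential clocks. With mean bleaching
   time $\tau_{bl}$ and molecular off time $\tau_{off}$,

   $$f(\tau_{obs}) = \left(\tau_{bl}^{-1}+\tau_{off}^{-1}\right)
      e^{-\tau_{obs}\left(\tau_{bl}^{-1}+\tau_{off}^{-1}\right)},
   \qquad
   \langle\tau_{obs}\rangle =
      \left(\tau_{bl}^{-1}+\tau_{off}^{-1}\right)^{-1}.$$

   Measuring $\tau_{bl}$ separately on a bilayer bleaching standard lets
   one invert this: $\tau_{off} = (1/\tau_{obs} - 1/\tau_{bl})^{-1}$,
   valid only while $\tau_{obs} < \tau_{bl}$
   (`correct_dwell_time()`). Uncertainty propagates to first order with
   $\partial\tau_{off}/\partial\tau_{obs} = (\tau_{off}/\tau_{obs})^2$.

2. **Motion blur as a filter.** At long exposures (hundreds of ms) fast
   diffusers smear over many pixels and vanish into background while bound
   complexes stay diffraction-limited; at short exposures (tens of ms)
   both populations are resolved and the step-size histogram is bimodal.
   The package's renderer reproduces both regimes so that the detection
   and classification stages can be validated against ground truth.

Nothing in this package consumes real microscopy data by necessity: every
stage can be driven by the synthetic-data generator, which carries a full
ground-truth record (per-frame state labels, bound intervals with end
causes, true change points). That record is the oracle for all tests.

# The synthetic generator and what it emulates

`simulate_two_state_tracks()` implements the memoryless kinetic scheme

$$\mathrm{free} \underset{k_{off}}{\overset{k_{bind}}{\rightleftharpoons}}
  \mathrm{bound} \xrightarrow{k_{bl}} \mathrm{bleached},$$

with free diffusion `d_free`, bound residual diffusion `d_bound` plus
centripetal drift `v_radial`, and bleaching only from the bound state by
default (the bleaching standard used for the correction is measured on
bound-state-like, stationary molecules; free-state bleaching is a toggle).
State changes occur in continuous time; positions are integrated exactly
across the merged grid of frame times and transition times.

Defaults and why:

* `d_free = 0.44` µm²/s — the measured bilayer diffusion coefficient.
* `d_bound = 0.005` µm²/s — not reported by the experiments; chosen so
  that the slow and fast mobility modes are cleanly separable at a 500 ms
  lag, as the bimodal step histogram requires. Configurable.
* `v_radial = 0.05` µm/s — centripetal transport speed of bound
  complexes, order-of-magnitude of reported microcluster transport; the
  experiments do not quantify it. Configurable.
* `k_bind = 0.05` s⁻¹ — the single-molecule imaging regime keeps visible
  binding events sparse; a mean free period of 20 s gives a roughly 80:20
  free:bound duty cycle so that dwells are well separated within a track.
  No measured value exists for this pseudo-first-order rate (it depends on
  receptor density); it only sets how much data a movie yields.
* Camera model: pixel-integrated Gaussian PSF, constant offset plus
  Gaussian read noise, optional Poisson shot noise. EM-CCD excess noise is
  not modeled.
* Intra-exposure motion: `substeps` (default 25) positions per exposure,
  chord-interpolated between frame positions, optionally with
  Brownian-bridge fluctuation. The bridge needs a diffusivity; passing a
  named vector (`bridge_d = c(FREE = 0.44, BOUND = 0.005)`) blurs each
  state with its own mobility. Using a single large `bridge_d` for bound
  emitters would scatter their photons by ~0.14 µm per frame and corrupt
  downstream step statistics — states must blur with their own
  diffusivity.
* `boundary = "reflect"` confines molecules to the field of view for long
  rendered movies. A real bilayer is effectively infinite with molecules
  exchanging across the field edge; reflection is the simplest stand-in
  that conserves density. It slightly shortens steps measured against the
  walls, which is why rendered-movie tests fit the mixture on the data
  itself rather than asserting the nominal `d_free`.

What the generator does **not** emulate: cell landing and spreading,
adhesion structures, receptor clustering in the image (clusters are not
resolved at these densities), fluorophore blinking and dark states, EM
gain statistics, stage drift. Passing tests therefore show the analysis is
correct for an idealized-but-noisy imaging model, not that it is robust to
every artifact of live-cell data.

# Detection, tracking and mobility classification

`detect_spots()` band-passes each frame with a difference of Gaussians
(`band_low` < `band_high` pixels), takes 8-neighborhood local maxima above
`dog_k` robust SDs of the filtered image, and refines each candidate with
an intensity-weighted centroid against a local median background. Spots
are gated uniformly on integrated intensity and apparent diameter. There
is no Gaussian PSF fitting: the centroid is accurate to well under 0.1 px
at the tested signal-to-noise, which is all the downstream analysis needs.
`border_px` discards localizations whose PSF is clipped by the frame edge;
clipped spots flicker in and out of detectability and would fragment
dwells.

`link_tracks()` performs per-frame optimal assignment (a hand-written
O(n³) Jonker-Volkgenant-style solver, tested against brute-force
enumeration) minimizing total squared displacement, with links forbidden
beyond `max_disp * sqrt(gap)` and gap closing up to `max_gap` missed
frames. Optimal assignment, unlike greedy matching, is order-independent
and deterministic.

For isotropic diffusion the displacement magnitude at lag $\Delta t$ is
Rayleigh, $p(r) = \frac{r}{2D\Delta t}e^{-r^2/4D\Delta t}$.
`fit_mobility_mixture()` fits a two-component Rayleigh mixture by EM and
falls back to one component when BIC prefers it (the "before cell landing"
case). The reported `r_star` is the single-step posterior crossing.

`classify_bound_segments()` labels each sample by the windowed **median**
squared per-frame displacement against the closed-form crossing of the two
components' squared-step densities (squared Rayleigh steps are
exponential, so the crossing is analytic). Two deliberate choices:

* *Median, not mean.* A single corrupted step — a transient overlap with a
  passing molecule pulls the centroid — inflates a windowed mean and
  splits a long dwell in two. The median of a 3-step window ignores one
  outlier; mid-dwell false breaks drop from several percent per frame to
  the per-mille range.
* *Ties break toward FREE*, which is conservative for dwell durations.

Maximal runs of BOUND frames become dwell events, censored only when they
touch the movie boundary. A track that simply disappears ends its dwell
*uncensored*: disappearance is unbinding-or-bleaching, and separating
those two is exactly the job of the photobleach correction, not of the
tracker. `edge_margin_um` drops events whose mean position hugs the field
edge, where detection is unreliable.

Two estimator refinements in `fit_exponential_mean()` matter in practice:

* **Dead time** (`t_min`): a classifier with a w-frame window cannot
  resolve dwells shorter than a few frames. Dropping events below
  `t_min` and subtracting `t_min` from the rest is unbiased for an
  exponential (memorylessness).
* **Censoring** (`censor_policy = "survival_mle"`): when dwells are not
  short against the movie (45 s dwells in a 300 s movie), excluding
  censored events biases the mean low, because long dwells are
  preferentially censored. The survival MLE
  $\hat\tau = \sum_i t_i / \#\{\text{uncensored}\}$ handles this.

A caveat the package documents and tests rather than hides: the step-size
histogram alone cannot identify the kinetic rates — doubling both
$k_{on}$ and $k_{off}$ at matched occupancy leaves it statistically
unchanged. Rates come from dwell durations, not step sizes.

# Intensity steps and molecule counting

`detect_change_points()` segments a trace by recursive binary splitting
under a Gaussian model. For a segment $y_{1..n}$ the marginal likelihood
with unknown mean and variance under the reference prior
$p(\mu,\sigma^2)\propto\sigma^{-2}$ is
$m(y) \propto \pi^{-(n-1)/2} n^{-1/2}\,\Gamma\!\left(\tfrac{n-1}{2}\right)
SS^{-(n-1)/2}$ with $SS$ the centered sum of squares. A split at the best
location (uniform prior over candidates, each side at least 2 frames, ties
to the earlier index) is accepted when the log10 odds against the
constant-mean model exceed 2 — "decisive" on the Jeffreys scale. Segment
levels are posterior (= sample) means; noise is estimated per trace from
lag-1 differences (MAD/√2), since the cited experiments do not state a
global noise model. $SS$ is floored at machine scale so noiseless traces
segment exactly instead of dividing by zero.

Counting is sign-aware: downward steps are bleaching (or unbinding),
upward steps are arrivals and are never counted as bleach steps. A trace
is single-molecule iff it has exactly one downward step to background and
no upward steps; two-step traces flag dimers and are excluded from
calibration by `calibrate_single_molecule_intensity()`.

Stoichiometry then is plain arithmetic with propagated SEMs
(`estimate_stoichiometry()`): visible molecules = feature intensity /
single-molecule unit intensity; total molecules divide further by the
labeled fraction (default 0.5 for a tagged protein expressed 1:1 with its
endogenous counterpart). The canonical worked example: 136.0 counts / 47
counts per molecule = 2.9 visible, about 6 total. Counts are reported to
two significant figures. The 315 nm integration window is exactly 3
pixels at 105 nm/px; its capture fraction (~0.9 for a 0.8 px PSF) cancels
between feature and calibration, which is what makes the ratio a molecule
count. Background under each anchor is the per-frame median of a 3–6 px
annulus; the cited experiments do not specify their estimator.

Registration between the two camera channels (`fit_channel_map()`) is a
least-squares polynomial per output coordinate, default order 2 because
the registration error of real two-camera systems varies across the field;
order 1 is available. With 25+ beads and 10 nm localization noise the map
is good to ~20 nm, several-fold better than the one-pixel (105 nm)
colocalization criterion used downstream.

# The cluster-escape simulation

`simulate_escape()` asks whether rapid serial rebinding inside a receptor
cluster could masquerade as a long single dwell. A cluster of `cluster_n`
TCRs is a square lattice with 10 nm spacing (the receptor footprint,
density 10⁴ µm⁻²). One ligand starts bound at a uniformly drawn site and
alternates:

* a bound period $\tau_{off,i} \sim \mathrm{Exp}(\langle\tau_{off}\rangle)$;
* an unbound period $\tau_{on} \sim \mathrm{Exp}(1/(k_{on}\rho_{TCR}))$
  followed by a Gaussian hop with per-axis SD
  $\sqrt{2 D_{SLB} \tau_{on}}$, landing on the nearest lattice site.

Landing on the cluster rebinds; landing off it (or on an inactive pad
site of a non-square cluster) is escape, and
$\tau_{esc} = \sum_{i=0}^{n}\tau_{off,i} + \sum_{i=1}^{n}\tau_{on,i} +
\tau_{exit}$ — an identity the code records and the tests verify exactly
per iteration.

Two printed phrases required interpretation, recorded here as deliberate
readings: "exponential with mean $k_{on}\rho_{TCR}$" is dimensionally a
rate, so the mean unbound interval is its reciprocal
$1/(k_{on}\rho_{TCR})$; "standard deviation $2D_{SLB}\tau_{on}$" is read
as $\sqrt{2D_{SLB}\tau_{on}}$ per axis, the only reading consistent with
Brownian motion and the stated Rayleigh step construction. At
$k_{on} = 0.17$ µm²s⁻¹molecule⁻¹ the per-axis hop SD is 22.8 nm — over
twice the lattice spacing — so a single receptor almost always loses its
ligand on first unbinding (ratio $\tau_{esc}/\tau_{off} \approx 1.1$). At
$k_{on} = 0.51$ the hop SD is 13.1 nm, about one lattice spacing: the
fastest binding that still allows rebinding to the same receptor. Both
values are exposed; neither is hard-coded.

The ratio $\tau_{esc}/\tau_{off}$ is independent of $\tau_{off}$ (since
$\tau_{off} \gg \tau_{on}$, it equals $\langle n\rangle + 1$ up to
sampling error), grows roughly linearly with cluster size, and at the
measured parameters stays order-unity for clusters up to ~100 receptors —
about 1.1 at 1 receptor and below 5 at 100 in this implementation. The
experiments publish no numeric surface for this figure, so the acceptance
tests assert exactly these qualitative properties plus agreement within
10% with an independent brute-force oracle: an explicit random walk at
dt = $\tau_{on}/100$ with per-step binding attempts, which validates the
single-jump event-driven shortcut. "Escape within a handful of binding
events" (ratio < 5 for realistic clusters) is this package's quantitative
reading of the claim that realistic clusters do not entrap their ligand;
minute-scale entrapment would need ratios of hundreds, reached only at
thousands of receptors.

Rebinding on landing is unconditional — the text describes no per-contact
acceptance probability. `n_iter` defaults to 100, the published iteration
count; tests use 4,000–10,000 for tighter sampling error.

# Problem sizes and numerical tolerances used by the tests

Simulation sizes were chosen so each check is statistically meaningful at
interactive runtimes: 10⁴ draws for all direct estimator recoveries (3-SE
criteria), ~9,000 bound intervals for the exponentiality KS test
(α = 0.01), 200 seeds for change-point localization and 1,000 null traces
for the false-positive bound, 20 seeds for mixture parameter recovery, and
8 rendered movies of 2 molecules × 600 frames (80×80 px) for the
end-to-end label-accuracy/off-time criterion. The rendered movies use the
slow receptor (τ_off = 53.8 s, τ_bl = 300 s): its ~90-frame dwells are
far above the classifier's dead time, so the end-to-end test measures the
pipeline rather than the frame-rate resolution limit. Sparse fields (2
molecules per 8.4 µm square) keep spot overlap — which genuinely corrupts
any tracker — from dominating the statistics; crowding robustness is a
known limitation, not a tested property.

EM iterates to a 10⁻¹⁰ relative log-likelihood tolerance with
quantile-based initialization; the mixture falls back to one component on
BIC. Change-point ties break to the earlier index. The dwell-time
correction round-trips its forward map to 10⁻¹²; its error propagation is
first-order, with a bootstrap (1,000 resamples) available for small
samples. All generators draw from one seeded stream per call
(`withr::with_seed`), so identical seeds give bit-identical artifacts.

# Known limitations

* Dwells shorter than ~3 frames are unresolvable by the windowed
  classifier; the dead-time correction removes the bias but those events
  carry no information. Choose the frame interval so that
  $\tau_{obs} \gtrsim 10$ frames.
* The tracker has no model of spot merging; two molecules within ~3 px
  produce one detection and can swap identities. Densities above ~0.1
  molecules/µm² degrade dwell integrity.
* No blinking/dark-state correction: a blinking fluorophore would be
  scored as two dwells.
* The escape simulation treats the cluster as static and fully occupied;
  competition between ligands and receptor turnover are out of scope.
* Registration is fiducial-based only; there is no image-correlation
  fallback.
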