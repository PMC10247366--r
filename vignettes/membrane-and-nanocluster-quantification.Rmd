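---
title: "Membrane remodelling and nanocluster quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane remodelling and nanocluster quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterkit)
```

This vignette documents the models behind `clusterkit`, the defaults and
their units, the synthetic-data generators, and the numerical design
choices, in enough detail that a user can judge what a passing test suite
does — and does not — demonstrate about real data.

## The scientific setting

Reticulon-homology-domain (RHD) proteins bend membranes; ubiquitin
moieties tethered to RHD lysines (K160, K264) strengthen both curvature
induction and receptor clustering. The package quantifies this from two
directions: coarse-grained membrane simulations (bead point clouds in nm
and ns) and DNA-PAINT single-molecule localization microscopy (nm and s).
Both arms share the same statistical backbone: geometric estimators,
renewal-process waiting times and log-normal population summaries.

## Membrane curvature

**Sphere fit** (`fit_sphere`). Beads on a closing bicelle/vesicle are fit
with a sphere by least squares: an algebraic (Coope) linear solve seeds a
geometric refinement that minimises radial residuals, with the radius
profiled out as the mean centre distance. The signed mean curvature is
`H = s / R`, `s = +1` when the fitted centre lies on the luminal side
(membrane bending away from the upper, cytosolic leaflet). The sign is
read off the leaflet labels: for a vesicle the cytosolic leaflet is the
outer shell. Two degenerate-input rules matter:

- clouds with fewer than 4 points are an error; exactly coplanar clouds
  are *not* — they are flat membranes and report the capped radius;
- a cloud is *quasi-flat* when the best-fitting plane (from the SVD
  thickness) explains it at least as well as the best sphere, or when the
  fitted radius exceeds `r_cap = 1e4` nm. Quasi-flat clouds report
  `R = 1e4` nm, so `|H| <= 1e-4 nm^-1` and the frame classifies as a
  bicelle. Without the plane comparison, a noisy disc converges to a
  spurious finite radius — the sphere family contains near-planes of
  enormous radius, and noise selects one of them.

**Monge fields** (`height_field_from_cloud`, `monge_curvature`). Buckled
or flat membranes are described as a height function `z(x, y)` on a
regular lattice (default spacing 1 nm; the upstream tooling for this
analysis does not publish its grid spacing, so the default here is
declared, not inferred). Binning uses the mean z per cell; isolated empty
cells are filled from two or more populated 4-neighbours, remaining holes
stay masked. Curvatures come from central differences:

$$H = \frac{(1+z_y^2)\,z_{xx} - 2 z_x z_y z_{xy} + (1+z_x^2)\,z_{yy}}
           {2\,(1+z_x^2+z_y^2)^{3/2}},\qquad
  K_G = \frac{z_{xx} z_{yy} - z_{xy}^2}{(1+z_x^2+z_y^2)^2},$$

with `k_{1,2} = H ± sqrt(H^2 - K_G)` (radicand clamped at zero within
-1e-9). Non-periodic boundary nodes are masked, never extrapolated. The
discretization error is `O(h^2)`: the tests verify closed forms for a
plane, a sphere cap (`|H| = 1/R`) and the sinusoidal buckle
`z = A sin(2 pi x / lambda)` (crest `|k_1| = A (2\pi/\lambda)^2`, the other
principal curvature zero), and that halving the spacing shrinks the error
at least threefold. Note the division of labour: fitting *noisy point
clouds* binned at 1 nm amplifies sampling noise in second derivatives, so
quantitative curvature tests use analytic or densely, regularly sampled
surfaces; bin-mean noise on random clouds is a property of the data, not
the estimator.

**Transition classification** (`classify_transition`). A replicate has
vesiculated at the first time `|H|` *strictly* exceeds the threshold
(default 0.15 nm^-1); otherwise it is right-censored at its horizon. The
strict inequality is deliberate: equality stays a bicelle. The same
strictness convention is used for the 10 nm cluster cut-off below, so the
pristine 3 x 3 protein grid with exactly 10 nm spacing is unclustered at
t = 0.

**Curvature sampled by proteins** (`curvature_preference`). Per-frame
protein positions are looked up in the `H` field by bilinear
interpolation — continuous in position and consistent with the `O(h^2)`
derivative accuracy — and summarised as a histogram plus occupancy-weighted
mean. Positions outside a non-periodic field are dropped and counted.

## Vesiculation kinetics

Waiting times to vesicle formation follow a Poisson process with rate `k'`
preceded by a constant lag `tau` for closure of the curved disc:
`p(t) = k' e^{-k'(t-\tau)}` for `t > tau`. (The source literature prints
the associated cumulative expression with a density-like right-hand side;
the implementation uses the proper CDF `1 - e^{-k'(t-\tau)}` — the printed
density and the Poisson-with-lag description are unambiguous.) Two
estimators:

- **MLE**: `tau-hat = min(t)`; `k'-hat = n_u / (sum_u (t_i - tau) +
  sum_c (h_j - tau)_+)`. Censored replicates contribute their exposure
  beyond the lag (survival terms); how non-transitioning replicates enter
  the fit is a declared choice of this package. `tau-hat = min(t)` carries
  the known positive order-statistic bias of order `1/(n k')`; it is
  reported uncorrected and the bias is covered by a test.
- **CDF least squares**: `1 - e^{-k'(t-\tau)}` fit to the empirical CDF of
  uncensored times with `tau <= min(t)`, via `minpack.lm::nlsLM`.

Both report the overall rate `k = 1/(1/k' + tau)` and feed
`acceleration_factor`, `acc = k_sys / k_ref` with the non-ubiquitinated
reference `k_ref = 0.0018 ns^-1`. Pooled per-condition fitting is used
throughout. `closure_count` tallies uncensored replicates per temperature
for barrier-height comparisons (e.g. 280 K vs 300 K).

The microsecond coarse-grained trajectories behind the published
acceleration factors are not redistributable, so the kinetics module is
validated by parameter recovery on synthetic data: 200 datasets of n = 100
keep the median relative error of `k'-hat` below 10%, and a planted
1.5-fold rate is recovered within 10%. The acceleration-recovery
experiment uses 400 replicates so that the estimator's sampling s.e.
(~3.5%) sits well inside the 10% tolerance — with 100 replicates the s.e.
alone (~7%) would make that check uninformative.

## Protein clusters, contacts and budding

- `com_distance_matrix`: pairwise COM distances with the minimum-image
  convention on periodic axes.
- `single_linkage_clusters`: connected components of the graph with edges
  `d < cutoff` (strict), equivalent to cutting the single-linkage
  dendrogram at the cut-off; implemented as a BFS and cross-checked in the
  tests both against a brute-force transitive-closure oracle and against
  `hclust(method = "single")`. `hclust`/`cutree` cannot be the
  implementation because `cutree` cuts at height `<=` h, and the exact
  10 nm grid boundary requires strict `<`.
- `ub_contacts`: a residue pair of two ubiquitin moieties is in contact
  when any bead pair is closer than 0.6 nm — a declared, configurable
  default for coarse-grained beads; the published analysis does not state
  its criterion. Contacts on one molecule are *cis*, across molecules
  *trans*. Runs of contact frames become records with lifetime
  `(last - first + 1) x frame spacing`; `gap_tolerance` (default 0,
  contiguous) optionally bridges short interruptions.
- `budding_metrics`: emits the `L_X(t)`, per-protein `z(t)` and membrane
  z-extrema traces. The budding flag — `L_X` below 95% of its initial
  value for at least 10 consecutive frames — is an advisory heuristic;
  published budding calls are made by inspecting trajectories, so the
  traces are the primary output.
- `ppi_scale`: `eps_alpha = eps_0 + alpha (eps_original - eps_0)`,
  `alpha = 1` native, `alpha = 0.65` the standard reduced
  protein–protein-interaction condition.

## DNA-PAINT localization processing

Defaults follow standard DNA-PAINT practice: PSF symmetry
`0.7 < FWHM_x / FWHM_y < 1.4`, localization precision `< 50 nm` (both
strict), intensity threshold configurable (default 1 photon, i.e.
pass-through, since published intensity cuts are instrument-specific);
linking radius `5 x` the NeNa precision with at most 8 intervening dark
frames; fiducial traces are those with a run of more than 20 consecutive
frames; pixel size 158 nm for pixel-unit tables.

Conventions worth stating precisely:

- **Dark-frame counting.** A gap between members at frames `f1 < f2`
  contains `f2 - f1 - 1` dark frames; linking requires that count `<= 8`.
  So frames 1 and 10 link; frames 1 and 11 do not. The same convention
  gives dark times `(delta frames - 1) / frame rate` in the qPAINT module.
- **NeNa.** Distances from each localization to its nearest neighbour in
  the *next* frame are fitted with the correlated-pair density
  `p(d) = (d / 2\sigma^2) e^{-d^2/4\sigma^2}` plus a linear background
  term that absorbs uncorrelated molecules. Each QC-rejection is tallied
  under the first criterion it fails so the tallies sum to the rows
  removed.
- **Linking** is greedy in frame order against running trace centroids —
  deterministic and order-stable.

## Cluster detection

**DBSCAN** (`dbscan_nanoclusters`), radius 31 nm, minimum 10 localizations,
classical definition with the point itself counted among its neighbours.
Neighbour search uses an eps-sized grid index, so dense fields stay
tractable; the tests prove equivalence to a brute-force
density-reachability oracle on hundreds of random instances (core-point
partitions identical; border points assigned to one of their reachable
clusters, the classical ambiguity). Cluster area is the convex hull of the
members — the published pipeline reports only that diameters come "from
cluster areas", so the hull is a declared choice — and the diameter is the
equivalent circle's, `2 sqrt(area/pi)`, an exact identity in every output.

**Voronoi microclusters** (`voronoi_microclusters`). The tessellation is
computed by incremental half-plane clipping per cell with a
nearest-first early exit; unbounded edge cells are closed by clipping to
the bounding box inflated by the median nearest-neighbour distance (cell
areas tile that region to within 0.1%, which the tests check). The
first-rank density of a localization is
`(1 + #neighbours) / (own cell area + neighbour cell areas)`. Seeds exceed
`delta x` the global mean density (`n / region area`); adjacent seeds
merge; each object then annexes adjacent cells above *half* the seed
threshold — a two-level hysteresis in the spirit of DBSCAN border points.
Without annexation the hard seed cut clips the rim of a genuinely dense
object (planted-disc recovery drops to ~94%); with it, recovery exceeds
99% while a homogeneous field still yields nothing, because isolated
fluctuation seeds never reach the 800-localization floor. Candidate
objects must have at least 800 member localizations and an
equivalent-circle diameter of at least 100 nm, the diameter computed from
the convex hull of member localizations — summed member *cell* areas would
include the large rim cells of the object–background transition and
inflate small objects past the 100 nm gate. The density factor must lie in
[2, 6] and is a required per-dataset parameter, reflecting how such
thresholds are calibrated per cell in practice. The first-rank density
formula is stated as implemented; no claim is made that it is bit-identical
to any particular GUI tool's edge handling.

## Log-normal modes and qPAINT copy numbers

Cluster-size and qPAINT-index distributions are summarised by the mode of
a fitted log-normal. When a fit is reported through linear-space moments
`(mu, sigma)` — as figure legends usually do — they are converted by moment
matching,

$$\sigma_{\log}^2 = \ln\!\big(1 + (\sigma/\mu)^2\big), \qquad
  \mu_{\log} = \ln\mu - \sigma_{\log}^2/2,$$

and the mode is `d = exp(mu_log - sigma_log^2)`. This interpretation of
legend moments reproduces the published modal diameters (88, 24) nm →
79 nm and (123, 46) nm → 101 nm exactly after rounding, which is the
strongest available evidence that it is the intended reading.
`fit_lognormal` fits raw samples by log-space MLE or binned relative
frequencies by weighted least squares and reports both parameterisations.

`dark_times` collapses bright frames into events (runs of consecutive
frames), measures dark intervals between events, and estimates the mean
dark time `tau_D` by least squares on the empirical exponential CDF, with
the interval mean (the MLE) reported as a cross-check. The qPAINT index is
`1/tau_D`; `copy_number` is the mode ratio of cluster and calibration
index distributions. Applying the same moment-conversion mode ratio to
published index moments gives ≈ 2.7 and ≈ 14.2 versus printed mean copy
numbers 2.5 and 12.6 — same order, not equal; the exact histogram-fit
procedure behind those numbers (binning, weighting) is not published, so
the package reports both the moment-based and the direct-fit routes and no
exact match is claimed for copy numbers themselves.

## Synthetic data: what is and is not emulated

All generators take a `seed`, restore the caller's RNG state, and attach
their ground truth so recovery tests never compare against hard-coded
numbers.

- `gen_membrane`: uniform sampling on analytic surfaces — sphere (two
  leaflet shells ±1 nm about the mid-surface, upper = outer), disc,
  sinusoidal buckle (default 57 x 28 nm, amplitude 5 nm, matching the
  fixed-box buckled-bilayer setup), tubule (default radius 7 nm, within
  the 12–15 nm diameter range of RHD-driven tubules) — plus isotropic
  Gaussian noise. Not emulated: lipid packing, thermal undulation spectra,
  protein-induced local deformation.
- `gen_waiting_times`: `t = tau + Exp(k')` with horizon censoring.
- `gen_trajectory`: nine proteins on a 3 x 3 grid with 10 nm spacing
  (recorded pristine at t = 0), 2D Brownian COM motion with periodic
  wrapping, an optional coalescence pull after `t_aggregate`, an optional
  budding signature after `t_bud` (10% `L_X` contraction, protein z
  excursion above the membrane), and two ubiquitin beads per protein at
  fixed offsets. Not emulated: inter-protein forces, membrane-mediated
  interactions, realistic bud geometry.
- `gen_smlm`: per docking strand, alternating dark (`Exp(k_on c)`, default
  0.01 s^-1) and bright (`Exp(1/0.4 s)`) intervals over 20,000 frames at
  10 Hz; a strand is bright in a frame when its bright interval overlaps
  the frame, and bright episodes shorter than half a frame are dropped
  (finite camera integration). Each bright frame yields one localization
  at the cluster centre plus Gaussian noise (default sigma 10 nm), with
  plausible PSF-width, photon and precision columns; fiducials emit every
  frame; background is homogeneous Poisson. The acquisition length and
  rate are the standard experimental settings; the per-strand kinetics are
  chosen as realistic for ~50 pM imager concentrations. Not emulated:
  camera noise models, PSF rendering, drift.

One measurement subtlety is worth knowing: dropping sub-half-frame bright
events merges the dark gaps they separated. A geometric sum of exponential
gaps is again exponential, so visible dark intervals are exponential at
the *effective* rate `k_eff = k_on c × P(visible)` — about 12% below the
raw binding rate at the defaults. This cancels in copy-number ratios
(cluster and calibration share the kinetics) but shows up when comparing
absolute dark times with `1/(n k_on c)`, and it is why the simulator tests
check against `k_eff`. For the same reason the dark-time linearity check
treats *clusters* as the replicate unit: pooled-interval standard errors
are so small that benign frame-quantization artifacts (a few per cent)
would dominate a pooled 2-s.e. comparison, whereas across-cluster
variability is the honest experimental error scale.

## Problem sizes in the test suite

The suite is sized for a single CPU: oracle equivalence uses 500 random
single-linkage instances (n ≤ 50) and 130 DBSCAN instances (n ≤ 100);
kinetics recovery uses 260 synthetic datasets; the end-to-end qPAINT check
simulates full 20,000-frame acquisitions with 30 clusters per strand count
in {1, 2, 5, 10, 15} plus a 60-cluster calibration; Voronoi fixtures use
~2,600 localizations. The whole suite runs in under two minutes.

## Known limitations

- Trajectory ingestion is CSV/point-cloud based; GRO/XTC readers are not
  bundled — export bead coordinates (e.g. headgroup markers) to CSV first.
- The Voronoi density definition matches the formula stated above; other
  implementations may differ at edges.
- The budding flag is a heuristic over `L_X`; use the traces for any
  quantitative claim.
- `tau-hat = min(t)` is biased upward by `~1/(n k')`; at the replicate
  counts used here the bias is far below the reported uncertainties, but
  for very small n consider the CDF-LS estimator.
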