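# clusterkit

Quantitative analysis of membrane remodelling by curvature-active,
ubiquitin-modified proteins — from coarse-grained membrane simulations to
DNA-PAINT single-molecule microscopy.

ER-phagy receptors such as FAM134B carry a wedge-shaped reticulon homology
domain (RHD) that bends the endoplasmic-reticulum membrane, and
ubiquitination of the RHD enhances both membrane remodelling and receptor
clustering. Testing that mechanism quantitatively requires two very
different toolchains, which this package provides in one place:

**Membrane / simulation arm**

- **Curvature.** Least-squares sphere fits of bead point clouds give a
  global signed mean curvature `H` per frame (positive away from the
  cytosolic leaflet); Monge-representation height fields `z(x, y)` give
  local fields of the principal curvatures `k1, k2`, the mean curvature
  `H = (k1 + k2)/2` and the Gaussian curvature `K_G = k1 k2`.
- **Vesiculation kinetics.** A bicelle has formed a vesicle at the first
  time `|H| > 0.15 nm^-1` (strict). Waiting times follow a Poisson process
  with a closure lag: `p(t) = k' exp(-k'(t - tau))` for `t > tau`, overall
  rate `k = 1/(1/k' + tau)`, with censored replicates entering the
  likelihood as survival terms. Acceleration factors are
  `acc = k_sys / k_ref` against the non-ubiquitinated reference
  `k_ref = 0.0018 ns^-1`.
- **Clustering and budding.** Single-linkage protein clusters at a 10 nm
  COM cut-off (minimum-image distances), cis/trans ubiquitin contact
  records with lifetimes, box-width (`L_X`) and protein-height budding
  traces, and the protein–protein interaction scaling
  `eps_alpha = eps_0 + alpha (eps_original - eps_0)`.

**Single-molecule / DNA-PAINT arm**

- **Localization processing.** PSF-symmetry / precision / intensity QC,
  NeNa localization precision from consecutive-frame nearest neighbours,
  greedy trace linking (radius 5 sigma, up to 8 dark frames), and
  fiducial removal (traces with > 20 consecutive frames).
- **Cluster detection.** DBSCAN nanoclusters (31 nm, 10 localizations)
  with convex-hull areas and equivalent-circle diameters, and Voronoi
  first-rank-density microcluster segmentation with the standard
  thresholds (density factor in [2, 6], >= 800 localizations, >= 100 nm).
- **Quantification.** Log-normal fits of cluster-size distributions with
  the mode `d = exp(mu_log - sigma_log^2)` (moments converted by
  `sigma_log^2 = ln(1 + (sigma/mu)^2)`, `mu_log = ln(mu) - sigma_log^2/2`),
  and qPAINT copy numbers: the inverse mean dark time of a cluster is
  proportional to its docking-strand count, so
  `n = mode(cluster indices) / mode(calibration indices)`.

Seeded generators (`gen_membrane`, `gen_waiting_times`, `gen_trajectory`,
`gen_smlm`) produce inputs with known ground truth for every stage, so the
whole chain is testable without external data.

## Worked example

Vesiculation kinetics from synthetic waiting times, and a modal cluster
diameter from reported log-normal moments:

```r
library(clusterkit)

s <- gen_waiting_times(k_prime = 0.005, tau = 100, n = 100,
                       horizon = 2000, seed = 42)
fit <- fit_shifted_exponential(s)
fit
#> shifted_exp_fit (mle): k' = 0.004564 1/ns, tau = 105.8 ns, k = 0.003078 1/ns
#>   n = 100 uncensored + 0 censored
acceleration_factor(fit)
#> acceleration: k_sys = 0.003078 / k_ref = 0.0018 -> acc = 1.710

lognormal_mode(88, 24)
#> [1] 79.02158
```

The fitted Poisson rate `k'` and lag `tau` recover the planted 0.005 ns^-1
and 100 ns within sampling error; the overall rate `k` is about 1.7 times
the 0.0018 ns^-1 reference. A log-normal cluster-size fit with linear-space
mean 88 nm and s.d. 24 nm has its mode — the modal cluster diameter — at
79 nm.

A miniature DNA-PAINT acquisition, clustered and quantified:

```r
truth <- smlm_ground_truth(centers = rbind(c(0, 0), c(800, 0),
                                           c(0, 800), c(800, 800)),
                           n_strands = 6, k_on_c = 0.01, sigma_loc = 8)
tab <- gen_smlm(truth, seed = 7)
db <- dbscan_nanoclusters(tab, eps = 31, min_pts = 10)
db$clusters[, c("cluster", "n_localizations", "diameter_nm")]
#>   cluster n_localizations diameter_nm
#> 1       1             518    43.96618
#> 2       2             598    49.11300
#> 3       3             567    46.44996
#> 4       4             630    44.83456
cluster_qpaint_indices(tab, db)
#> [1] 0.0511 0.0517 0.0624 0.0587
```

All four planted clusters are recovered; their qPAINT indices scatter
around `6 x k_on_c x P(visible)`, i.e. six docking strands each, and
dividing by a single-strand calibration mode returns the copy number (see
`copy_number()` and `run_smlm_arm()`).

## Documentation

The methods vignette (`vignettes/membrane-and-nanocluster-quantification.Rmd`)
describes the models, the default parameters and their provenance, what the
synthetic generators do and do not emulate, and the numerical design
choices. Function-level documentation lives in the roxygen comments in
`R/`.
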