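---
title: "Analysing multi-resolution ensembles of multi-domain proteins with bmbsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing multi-resolution ensembles of multi-domain proteins with bmbsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Flexible multi-domain proteins such as K48-linked polyubiquitin chains
populate many long-lived metastable arrangements of their domains.
Coarse-grained (CG) molecular dynamics explores this conformational space
cheaply but at reduced accuracy and detail; atomistic simulations are
accurate but far too slow to cross the free-energy barriers between
domain-domain arrangements. Back-mapping based sampling (BMBS) bridges the
two: a 2D projection of the CG ensemble is used to pick a set of CG
conformations, those are back-mapped to atomistic resolution by an external
tool, many short atomistic simulations are launched from them, and the
growing atomistic ensemble is compared quantitatively against the CG map
over time. `bmbsr` implements the analysis side of this loop — features,
projection, seeding, convergence monitoring and conformational clustering —
with a synthetic-ensemble generator so the whole workflow can be exercised
and validated without running any MD.

## Collective variables: residue-wise minimal distances

Both resolutions must be described by the same coordinates, so the package
uses residue-wise minimal distances (RMD) over backbone sites (C-alpha
atoms, or CG backbone beads at the same positions). For domains $P$ and $Q$
the pairwise site distance matrix $D_{P,Q}$ is reduced to its row minima
(each residue of $P$ to anywhere in $Q$) and column minima, and the blocks
for all domain pairs are concatenated. For three domains the block order is
$A_B, B_A, B_C, C_B, A_C, C_A$ with pairs $(A,B), (B,C), (A,C)$ — the
conventional order for ubiquitin trimers; for more domains, unordered pairs
are taken lexicographically. With three 76-residue units whose four
flexible C-terminal tail residues are masked, each domain contributes 72
unmasked sites and the vector has $(D-1)\sum_d n_d = 2 \cdot 216 = 432$
dimensions. Distances are in nm, uncapped; masked residues stay in stored
coordinates but contribute neither features nor centre-of-geometry
observables.

## The 2D map: an autoencoder with a sketch-map loss

The projection is an autoencoder whose loss augments reconstruction with a
distance-matching term,

$$L = k_a L_\mathrm{auto} + k_s L_\mathrm{sketch} + \mathrm{Reg},$$

$$L_\mathrm{auto} = \frac{1}{N}\sum_i \lVert X_i - \tilde X_i \rVert, \qquad
L_\mathrm{sketch} = \frac{1}{N}\sum_{i \ne j}
  \bigl(\mathrm{SIG}_h(\lVert X_i - X_j\rVert) -
        \mathrm{SIG}_l(\lVert x_i - x_j\rVert)\bigr)^2,$$

where $x_i$ is the 2D bottleneck and each sigmoid

$$\mathrm{SIG}_{\sigma,a,b}(D) = 1 - \bigl(1 + (2^{a/b}-1)(D/\sigma)^a\bigr)^{-b/a}$$

maps $0 \mapsto 0$, $\sigma \mapsto 1/2$ and saturates at 1, selecting the
band of distances the map should preserve. Defaults follow the canonical
tri-ubiquitin parameter set: 10,000 steps, 3 hidden layers of 300 tanh
neurons per half, $\mathrm{SIG}_h = (20, 12, 10)$,
$\mathrm{SIG}_l = (1, 2, 10)$, $k_a = 1$, $k_s = 500$.

Several details are deliberate package choices, surfaced in
`encodermap_hyperparams()` and logged with every run:

* $D(\cdot,\cdot)$ is plain Euclidean distance — RMD features are
  non-periodic, so no dihedral-style wrapping is needed or offered.
* `Reg` is an L2 penalty on network weights plus an L2 penalty on
  bottleneck magnitudes, both defaulting to `1e-4`. The penalty keeps the
  bottleneck from drifting to extreme scales where the low-dimensional
  sigmoid saturates.
* Optimiser Adam, batch size 256, learning rate `1e-3`, tanh activations;
  the sketch term is evaluated over all pairs within each minibatch
  (all-data pairs would be quadratic in the ensemble size), and a step
  means one minibatch.
* Features are not standardised by default, since all RMD columns share
  units; a flag enables it for heterogeneous features.
* Training is bit-reproducible given `rng_seed`; a non-finite loss aborts
  with the step index rather than continuing silently.
* The two projection axes of a non-linear map carry no physical units, so
  plots omit axis ticks.

`project_map()` is a pure function of the trained encoder — projecting new
data (e.g. the atomistic frames produced later) costs one forward pass.

## Seeding strategies

Seeds are picked from a binned 2D map (default 50 x 50 over the
projection's bounding box, which matches the visual granularity at which
such maps are typically inspected; bin-population ties are broken by grid
order so all three strategies are pure functions of their inputs and seed):

* **Minima-focused** visits bins in decreasing population and takes
  `round(n * bin_share)` seeds from each (at least one, sampled without
  replacement within a bin) until `n` seeds exist — reproducing the deepest
  basins and their weights as closely as a small `n` allows.
* **Boltzmann-weighted** repeatedly picks an occupied bin uniformly and
  accepts it with probability proportional to its population (normalised
  by the fullest bin, which maximises acceptance); accepted bins contribute
  one uniformly chosen member. Sampling is with replacement across
  iterations, so seed shares converge to bin populations for large `n`
  while rare bins still appear.
* **Uniform** draws occupied bins without replacement, one seed per bin,
  replenishing the pool if it empties before `n` seeds — every occupied
  bin is covered once before any contributes twice, which matters exactly
  when `n` approaches the number of occupied bins.

Selected frames are exported as a multi-model PDB for hand-off to an
external back-mapping tool (for MARTINI models, the "backward" script);
the back-mapping itself is outside the package's scope, and returned
atomistic structures re-enter through `load_ensemble()`.

## Convergence monitoring with a normalised earth mover's distance

Two binned 2D distributions are compared by the exact earth mover's
(Wasserstein-1) distance with Euclidean bin-centre ground distance, solved
as a minimum-cost transport problem. Histograms are mass-normalised first —
ensembles of different sizes must compare on equal footing — and, because
the ground distance is a metric, shared mass optimally stays in place, so
the solver transports only the signed difference (exact, and much faster
for similar histograms; the test suite cross-checks the solver against an
exhaustive grain-assignment oracle).

Raw EMD values are unit-dependent, so they are unity-normalised:

$$\mathrm{EMD}' = \frac{\mathrm{EMD} - \min(\mathrm{EMD})}{\max(\mathrm{EMD}) - \min(\mathrm{EMD})}$$

with $\min(\mathrm{EMD}) = 0$ and $\max(\mathrm{EMD})$ defined as the EMD
between the reference projection and a same-count uniform sample over its
bounding rectangle. An $\mathrm{EMD}'$ of 0 means identical distributions;
1 means "as far from the reference as structureless noise"; values above 1
are possible. $\max(\mathrm{EMD})$ is a property of each reference data
set, so every analysis recomputes it (recording the RNG seed of the
uniform sample) rather than reusing constants from other systems. A
reference that is itself uniform over its bounding box gives a meaningless
normalisation and is rejected.

Time-resolved curves pool the frames of all trajectories within a growing
window — forward from each trajectory's start, or reversed, growing
backwards from each trajectory's end, which removes the seeding bias
(trajectories end wherever they relaxed to, not where they were planted).
Points of one ensemble projected onto another's grid can fall slightly
outside it; they are clipped to edge bins and counted. Cross-seeding
curves compare one strategy's growing histograms to the fixed last-10-ns
histogram of another strategy, distinguishing convergence to a shared
region from divergence.

## Conformational clustering

The clustering workflow operates in three spaces with different jobs:

1. **cc_analysis-style embedding** (10-40 dimensions): minimises
   $\sum_{i<j}(r_{ij} - \langle x_i, x_j\rangle)^2$, where $r_{ij}$ is the
   Pearson correlation between the RMD vectors of frames $i$ and $j$.
   The fit is initialised from the top-$k$ eigenvectors of the correlation
   matrix (subspace iteration for large ensembles) and refined with
   L-BFGS-B using the analytic gradient; frames with constant features are
   rejected by name since their correlations are undefined.
2. **HDBSCAN** in the raw embedding coordinates: mutual-reachability
   single-linkage hierarchy, condensed at `min_cluster_size`, clusters
   selected by excess-of-mass stability, low-density frames labelled -1.
   (An alternative reading would cluster a density estimate over the
   embedding rather than the coordinates themselves; raw coordinates are
   used because HDBSCAN already is a density method, and a pilot density
   estimate would add a bandwidth parameter without an obvious default.)
3. **The 2D map** for cheap expansion: each unassigned frame whose map
   position falls inside a cluster's 2D footprint (95th percentile of
   member radii around the cluster centroid, unless a fixed radius is
   given) is compared by C-alpha RMSD — Kabsch superposition over unmasked
   sites — to the cluster's representative (the embedding medoid, which is
   deterministic), and assigned iff the RMSD is within the cutoff
   (default 0.3 nm; configuration files may state it in Angstrom). The
   RMSD gate applies only to this expansion step, not to HDBSCAN's own
   members: the density clusters define the states, the gate keeps the
   cheap expansion conformationally tight.

Iterations repeat embedding + clustering + expansion on the remaining
unassigned frames (default three iterations, or until a target assigned
fraction), with later clusters' labels offset to stay unique. Cluster
numbering is arbitrary; order carries no meaning. If a first pass finds no
cluster structure at all, it is retried allowing the hierarchy root itself
to be selected, so a single-basin ensemble yields one cluster rather than
none — with the usual excess-of-mass selection the root is never eligible,
which is also what makes pure noise come out as noise.

`cluster_growth_curve()` follows one cluster's cumulative membership over
individual simulation time, reporting the plateau time after which no
trajectory adds frames — the signature of trajectories visiting and then
abandoning a seeded state.

## The synthetic generator: what it emulates, and what it does not

`generate_synthetic_ensemble()` plants five metastable states of a
three-domain chain mirroring the regions of a tri-ubiquitin-like map:
`open` (extended, domain centres collinear at the open distance),
`collapsed` (all three centres mutually at the contact distance), and the
three pairwise-contact states. The two length scales default to 2.5 nm
(contact) and 6 nm (open) — a domain diameter of ~3 nm makes centres
2.5 nm apart touch, and twice that clearly separated. Domains are rigid
templates (a deterministic compact spiral per domain size) placed at the
state geometry, given a random global rotation and translation per frame,
plus isotropic Gaussian site jitter (default 0.03 nm, small against the
0.3 nm RMSD gate but visible against format precision). The default chain
is three 76-residue units with 4-residue masked tails — 72 unmasked sites
per domain. The "atomistic" resolution applies a fixed deterministic
deformation to the templates, emulating back-mapped sites that sit near
but not exactly at bead positions.

The generator reproduces the *geometry* of a multi-state landscape:
distinct basins, configurable weights and noise, rigid-body degeneracy of
the features. It does **not** emulate internal domain flexibility,
transition paths between states (frames are i.i.d. given their state),
force-field physics, or the continuous free-energy surface of a real
chain. Tests passing on synthetic data therefore validate the machinery —
feature invariances, exactness of the transport solver, statistical
contracts of the seeding rules, recovery of planted structure — not the
physical fidelity of any simulation model.

## Numerical choices and degenerate inputs

* Internal units are nm everywhere; Angstrom values are converted at the
  boundary (PDB/DCD input, `3A`-style cutoffs in the CLI).
* Residue indexing is 0-based internally; partition config files declare
  their `index_base` so biology numbering (residues 73-76 of a 76-residue
  unit) reads naturally.
* Histogram bins are half-open `[lo, hi)` with the last bin closed, so
  bounding-box extremes are never dropped.
* The transport solver treats masses below `1e-14` as zero and refuses
  unbalanced problems beyond `1e-9` relative mass mismatch.
* `kabsch_rmsd` excludes the reflection branch of the SVD, requires at
  least 3 sites, and is symmetric by construction.
* Sigmoid derivatives at zero distance vanish for exponents $a > 1$ (the
  only regime used), so coincident points contribute no sketch gradient.
* Degenerate inputs error early with classed conditions
  (`bmbs_config_error`, `bmbs_format_error`, `bmbs_domain_error`) rather
  than propagating NaNs.

## Problem sizes used in the shipped checks

The package's own validation runs at desk scale, chosen so the complete
suite exercises every component in a few minutes: ensembles of a few
hundred to 5,000 frames with 8-12-residue toy domains for clustering,
600-point 20-D blob sets with a reduced network (64 neurons, batch 128,
2,000 steps) for the projection, 50 x 50 grids with ~2,000 points for the
EMD anchors, and at most 6-bin histograms wherever an exhaustive transport
oracle is enumerated. The canonical full-scale parameters (the package
defaults,
72-site domains, 432-dimensional features) remain the package defaults and
are exercised for dimensional correctness; headline results of
microsecond-scale studies (e.g. specific normalisation constants or
cluster counts of deposited trajectory sets) are properties of those data
sets and are not reproduced here.

## Known limitations

* The exact transport solver is dense; histograms beyond ~50 x 50 with
  thousands of occupied bins become slow. No sliced or entropic
  approximations are offered — exactness is the point of the monitor.
* The HDBSCAN implementation materialises the full distance matrix
  (O(n^2) memory), comfortable to ~10,000 frames per clustering iteration.
* `load_ensemble()` reads PDB (incl. multi-model), GRO, DCD and columnar
  tables; XTC is not supported by any available reader and must be
  converted upstream.
* The decoder is trained but unused for structure generation; back-mapping
  is an external tool's job by design.

## A worked run

```{r, eval = FALSE}
library(bmbsr)
cfg <- demo_run_config(rng_seed = 1)
paths <- run_pipeline(cfg, "demo_run")
jsonlite::read_json(paths$summary)
```

The summary reports the feature width, the data-derived normalisation
maximum, each seeding strategy's normalised EMD against the source map
(minima-focused is reliably the smallest — it replicates the source
histogram by construction), and the cluster count with assigned fraction.
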