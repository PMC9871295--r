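# bmbsr

Analysis workbench for **back-mapping based sampling (BMBS)** of
multi-domain proteins: comparing coarse-grained (CG) and atomistic
conformational ensembles of systems like K48-linked tri-ubiquitin on a
shared two-dimensional map, selecting atomistic simulation seeds from that
map, monitoring convergence with an exact earth mover's distance, and
resolving the ensemble into conformational states.

Who it is for: simulators running multi-resolution studies of flexible
multi-domain proteins who need the analysis loop around the MD — the MD
engines and the back-mapping tool itself stay external.

## What it computes

* **Residue-wise minimal distances (RMD)** — the collective variable shared
  by both resolutions. For domains *A*, *B*, *C* the pairwise backbone-site
  distance matrices *D*<sub>A,B</sub>, *D*<sub>B,C</sub>, *D*<sub>A,C</sub>
  are reduced to row and column minima and concatenated
  (*A*<sub>B</sub>, *B*<sub>A</sub>, *B*<sub>C</sub>, *C*<sub>B</sub>,
  *A*<sub>C</sub>, *C*<sub>A</sub>); three 76-residue units with masked
  4-residue tails give the canonical 432-dimensional vector.
* **A 2D conformational map** from an autoencoder with a sketch-map loss,
  *L* = *k*<sub>a</sub> *L*<sub>auto</sub> + *k*<sub>s</sub> *L*<sub>sketch</sub> + Reg,
  where *L*<sub>sketch</sub> matches sigmoid-transformed pairwise distances
  between the inputs and the 2D bottleneck,
  SIG<sub>σ,a,b</sub>(D) = 1 − (1 + (2<sup>a/b</sup> − 1)(D/σ)<sup>a</sup>)<sup>−b/a</sup>.
* **Three seeding strategies** on the binned map — minima-focused,
  Boltzmann-weighted, uniform — for choosing the CG frames from which
  back-mapped atomistic simulations are launched.
* **Unity-normalised earth mover's distance**,
  EMD′ = (EMD − min EMD)/(max EMD − min EMD), with max EMD defined by the
  reference map vs. an equal-count uniform rectangle; computed by an exact
  min-cost-flow transport solver (Rcpp) and tracked in time-resolved
  forward/reversed and cross-seeding curves.
* **Iterative conformational clustering**: correlation-preserving embedding
  (minimising Σ(r<sub>ij</sub> − ⟨x<sub>i</sub>,x<sub>j</sub>⟩)²), HDBSCAN
  with noise, and RMSD-gated expansion of clusters over the 2D map
  (Kabsch superposition, 0.3 nm default cutoff).
* **A synthetic three-domain generator** with planted metastable states
  (open / collapsed / pairwise contacts) so every component can be
  validated without running MD.

See `vignettes/bmbs-workbench.Rmd` for the model details, parameter
defaults and design decisions.

## Worked example

```r
library(bmbsr)
cfg <- demo_run_config(rng_seed = 1)   # synthetic 3-domain ensemble, scaled-down map
paths <- run_pipeline(cfg, "demo_run")
cat(readLines(paths$summary), sep = "\n")
```

```
{
  "n_frames": 1200,
  "n_features": 72,
  "max_emd": 1.63730885919364,
  "seed_emds": {
    "minima_focused": 0.0413749603374346,
    "boltzmann": 0.636913860648115,
    "uniform": 0.35471142175265
  },
  "n_clusters": 5,
  "assigned_fraction": 1
}
```

Reading the numbers: `max_emd` is the data-derived normalisation constant
(the raw EMD between this run's 2D map and structureless uniform noise over
its bounding box — every reference data set gets its own). The `seed_emds`
are each strategy's normalised EMD between its 50 seed points and the full
map: minima-focused reproduces the source histogram by construction and is
smallest (0.041), while Boltzmann and uniform seedings deliberately spread
into rare bins and sit further away. The clustering workflow recovers the
generator's five planted states (`n_clusters: 5`) and assigns every frame
(`assigned_fraction: 1`) — planted states are rigid templates plus small
jitter, so nothing is noise.

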