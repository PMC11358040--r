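# trsaxs

Analysis of **time-resolved high-throughput small-angle X-ray scattering
(TR-HT-SAXS) conformational screens**: plate-scale triage of ligand libraries
by the conformational transitions they induce in a target protein, here the
switch of a monomer to its functional dimer, as seen directly in solution
scattering. The package is written for structural biologists and screening
scientists who collect frame-resolved 1-D SAXS profiles (e.g. 300-ms frames
of a 10-s exposure per well) alongside orthogonal binding assays (DSF thermal
shifts, MST amplitudes) and want a reproducible pipeline from raw `.dat`
files and a plate manifest to ranked, clustered, kinetically characterized
hits.

## What it computes

* **Guinier metrics** — per frame, a weighted fit of
  ln *I*(*q*) = ln *I*(0) − *q*²*R*g²/3 on a window shrunk to
  *q*max·*R*g ≤ 1.3, with aggregation diagnostics and the normalized Kratky
  transform (*qR*g)²·*I*/*I*(0). Rising *I*(0) and *R*g report dimerization
  (forward scattering doubles at equal mass concentration).
* **Assay resolvability** — Z-factors
  *Z* = 1 − 3(σ₊ + σ₋)/|μ₊ − μ₋| from replicate monomer/dimer control
  measurements of *R*g and *I*(0); 0.5–1.0 is the usable band.
* **Volatility of ratio (V_R)** — the shape-similarity metric between two
  curves: the intensity ratio is averaged in 25 equal-width *q* bins across
  0.015–0.15 Å⁻¹ and V_R = Σᵢ |R*ᵢ*₊₁ − R*ᵢ*| / ((R*ᵢ*₊₁ + R*ᵢ*)/2).
  V_R is zero for identical shapes, symmetric, and invariant to scaling of
  either curve — so it sees conformation, not concentration. All-pairs V_R
  values form the SAXS similarity matrix (SSM).
* **Significance envelopes** — per time point, replicate benchmark traces
  give a mean and an averaged standard uncertainty σ̄; mean ∓ 3σ̄ defines when
  a sample's V_R trace has left the monomer state or entered the dimer
  state.
* **Chemotype clustering** — single-linkage agglomerative clustering and
  k-means (k-means++ restarts) of SSM rows, with the cluster number chosen by
  the Krzanowski–Lai index or the elbow (second-difference) rule.
* **Transition kinetics** — each V_R time series is fit to
  V(*t*) = C + A·e^(−k·t); the rate constant k_VR ranks compounds by how fast
  they drive the transition, and 1-D clustering of k_VR values separates fast
  from slow chemotypes.
* **Orthogonal triage** — Boltzmann *T*m fits of DSF melt curves with QC
  exclusion rules, 3-s.d. ΔTm hit calls against a DMSO reference pool, MST
  time-averaged amplitudes with one-sided 3-s.d. calls, and one-site
  *K*d fits R(c) = R₀ + ΔR·c/(K_d + c).
* **Synthetic study plate** — an analytic two-state generator (sphere
  monomer, tangent two-sphere dimer, first-order conversion
  x(t) = x∞(1 − e^(−kt)), frame-wise Gaussian noise, replicate controls,
  planted chemotypes and DSF/MST responses) that makes every stage testable
  against planted ground truth.

## Worked example

Simulate the default screen plate (12 compounds in four planted chemotypes,
duplicate monomer controls, triplicate dimer controls, duplicate buffers) and
run the full pipeline:

```r
library(trsaxs)
cfg    <- sim_config(seed = 42)
plate  <- simulate_screen_plate(config = cfg)
report <- run_screen(plate, seed = 42)
report
#> <screen_report> 19 wells, 10 frames (t = 0.3..3 s)
#>   Z-factors: Rg 0.996, I(0) 0.891
#>   k_VR ranking: F01 > F02 > F03 > F07 > F04
head(report$kinetics$ranking[, c("label", "k_vr", "k_se", "rank", "cluster")], 5)
#>   label      k_vr       k_se rank cluster
#> 1   F01 2.1253211 0.01843891    1       1
#> 2   F02 1.6140644 0.02739059    2       1
#> 3   F03 1.2762485 0.01388905    3       1
#> 4   F07 1.0383539 0.02652216    4       2
#> 5   F04 0.8435095 0.01373486    5       2
```

The Z-factors say the monomer and dimer control states are cleanly resolvable
from single 300-ms frames. The ranking recovers the planted rate order: the
three full dimerizers (F01–F03, planted k = 2.0/1.55/1.2 s⁻¹) head the list
with the fastest fitted k_VR, followed by the weak-but-fast and partial
converters; inactive compounds are flagged non-transitioning and never
ranked. `report$clusters_late` holds the 2.1-s SSM clustering (chemotype
groups), and `export_report(report, "out/")` writes the CSV/JSON artifacts.

A shell entry point with the same functionality ships in
`inst/exec/trsaxs.R` (`simulate`, `run`, `triage` subcommands).

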