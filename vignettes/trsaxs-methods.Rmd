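---
title: "Methods: time-resolved SAXS conformational screening with trsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved SAXS conformational screening with trsaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trsaxs)
```

## The measurement and the model

A time-resolved high-throughput SAXS screen measures, for every well of a
plate, a short series of 1-D scattering profiles $I(q)$ — here ten 300-ms
frames spanning 0.3–3.0 s of X-ray exposure, on a momentum-transfer grid
$q = 4\pi\sin\theta/\lambda$ covering 0.01–0.59 Å$^{-1}$. For a target
protein whose active state is a dimer, exposure-driven reduction triggers
the monomer-to-dimer transition in wells where a bound ligand permits it,
and the frame series records that transition directly: forward scattering
$I(0)$ (proportional to mass concentration times molecular weight) rises
toward twice its initial value, the radius of gyration $R_g$ grows, and the
whole curve shape converges on the dimer benchmark.

The pipeline composes the stages a screening scientist would run by hand:

1. time-matched buffer subtraction (replicate buffer frames averaged, then
   subtracted frame-by-frame, scale factor fixed at 1.0 for
   compound-matched buffers, with a config override);
2. Guinier analysis per frame; Z-factors from control replicates;
3. volatility-of-ratio (V$_R$) similarity against benchmarks, over time and
   all-pairs (the SAXS similarity matrix, SSM);
4. replicate-derived significance envelopes and per-sample transition
   classification;
5. chemotype clustering of SSM rows;
6. single-exponential kinetics of V$_R$ traces (k$_{VR}$), ranking, and 1-D
   kinetic clustering;
7. DSF/MST triage merge.

## V$_R$: the similarity statistic

For two curves $a, b$ covering the analysis window (default
0.015–0.15 Å$^{-1}$), the window is partitioned into $n_{\text{bins}} = 25$
contiguous equal-width $q$ bins; within each non-empty bin the mean
intensities $\bar I_a, \bar I_b$ give a per-bin ratio
$R_i = \bar I_a / \bar I_b$, and

$$ V_R = \sum_{i=1}^{m-1} \frac{|R_{i+1} - R_i|}{(R_{i+1} + R_i)/2}. $$

The relative first differences make $V_R$ exactly invariant to separate
rescaling of either curve and exactly symmetric under swapping the
arguments ($R \to 1/R$ leaves each term unchanged). We deliberately bin the
*intensities* and then take the ratio, rather than binning the pointwise
ratio: the two conventions converge as bins narrow, but only the former
preserves the symmetry identity exactly in floating point, which the test
suite asserts at $10^{-12}$. Pairs inside a similarity matrix are always
evaluated in canonical label order so that a permuted input reproduces every
entry bit-exactly.

The window bounds and bin count are configurable; published V$_R$ heat maps
produced by other implementations may use different binning constants, so
absolute magnitudes should be compared only within one convention.

## Guinier fitting policy

`guinier_fit()` regresses $\ln I$ on $q^2$ (weighted by $(I/\sigma)^2$ when
uncertainties are present), starting at the first positive-intensity point
and shrinking or growing the upper bound from the high-$q$ side until the
fixed point $q_{max} R_g \le 1.3$ is reached, with at least five points.
The 1.3 limit is the globular-particle convention; it is a *window*, not an
asymptotic regime, and on an ideal sphere it carries a systematic
$\approx 2\%$ overestimate of $R_g$ (the quartic term of the sphere form
factor). Closed-form checks against $R_g = \sqrt{3/5}\,R$ (sphere) and
$\sqrt{8/5}\,R$ (tangent two-sphere dimer) therefore use a stricter
$q_{max} R_g \le 0.8$ window, where the bias is below 1%. Cycle detection
in the fixed-point iteration resolves oscillating windows toward the
smaller (safer) one.

Aggregation is flagged by refitting the two halves of the window (low-half
$R_g$ more than 5% above the high-half value) or by systematic positive
curvature of the low-$q$ residuals; windows under 10 points return an
indeterminate flag rather than a guess.

## Significance envelopes and kinetics

Monomer and dimer benchmark V$_R$ traces are summarized per time point by
the replicate mean and sample (n−1) SD; the per-time SDs are averaged into
a single standard uncertainty $\bar\sigma$, and the threshold trace is the
mean offset by $3\bar\sigma$ — downward for the monomer benchmark (a
responsive sample *falls below* it) and upward for the dimer
self-similarity benchmark (a converted sample *enters* it). The dimer
self-similarity trace uses leave-one-out references so a replicate is never
compared against an average containing itself.

Kinetic rate constants come from bounded Levenberg–Marquardt fits of
$V(t) = C + A e^{-kt}$ ($A, k \ge 0$), initialized from the trace itself
(plateau from the last value, rate from log-linearization). The plateau $C$
is left free rather than pinned to the dimer benchmark because partial
converters genuinely plateau above it. A fit is reported
*non-transitioning* when the amplitude is not significantly positive
($A < 2\,\mathrm{SE}(A)$, with a floor excluding the degenerate exactly-flat
case) or $k < 10^{-3}\,\mathrm{s}^{-1}$. In the pipeline, kinetic fitting is
additionally gated on envelope responsiveness — only samples whose trace
crossed the monomer significance threshold are fit — which mirrors the
screening logic and suppresses the $\sim 2\%$ borderline-amplitude false
positives that the amplitude test alone admits among inactive compounds.

Because the V$_R$-to-converted-fraction mapping is monotone and nearly
linear, fitted k$_{VR}$ tracks the underlying conversion rate to within
a few tens of percent (a mild, amplitude-dependent upward distortion) and,
more importantly for screening, preserves rank order. Parameter-recovery
benchmarks (median $|\hat k - k|/k \le 10\%$ at noise-to-amplitude 0.05)
are run on the full 10-s exposure series, where the plateau is actually
reached and $k$ and $C$ decouple; on a 3-s span the same noise level roughly
doubles the spread, which is an honest limitation of short series.

## Cluster-number selection

k-means uses Lloyd iterations from k-means++ seeds, keeping the best of 50
restarts by total within-cluster sum of squares $W_k$; all stochastic steps
take an explicit seed. The Krzanowski–Lai scan computes
$\mathrm{DIFF}_k = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k$ and
$\mathrm{KL}(k) = |\mathrm{DIFF}_k / \mathrm{DIFF}_{k+1}|$, choosing the
interior maximizer (ties to the smaller $k$; vanishing denominators are
excluded with a warning and flagged low-confidence). The elbow rule picks
the interior maximizer of the second difference of $W_k$. For SSM
clustering the feature vectors are matrix rows — each sample's V$_R$
profile against every other sample — and both the KL-selected and a
forced-$k$ (default 4) assignment are always reported, so an off-trend
selection at one time point never hides the chemotype structure.

## DSF and MST triage

Melt curves are fit with the Boltzmann sigmoid
$F(T) = B + (P-B)/(1 + e^{(T_m - T)/a})$ on a window truncated at the
global fluorescence maximum plus 2 °C, excluding the post-peak dye decay;
the fit is affine-invariant in fluorescence. QC fails curves whose initial
fluorescence exceeds half the maximum (pre-aggregated or interfering),
whose maximum sits in the final three points (no transition), or whose fit
$R^2 < 0.95$. Hit calls use $k\sigma$ cutoffs ($k = 3$) computed from the
*unrounded* reference-pool SD — two-sided for ΔT$_m$ (both stabilizing and
destabilizing binders matter when the native ligand itself lowers T$_m$),
one-sided for MST amplitude deviations. MST amplitudes are the mean
normalized fluorescence (baseline × 1000) over a 4–5 s window inside the
20-s excitation phase, averaged over three consecutive scans. One-site
binding fits $R(c) = R_0 + \Delta R\, c/(K_d + c)$ are declared
indeterminate when the span is insignificant or $K_d$ exceeds the top
concentration tenfold.

## The synthetic study plate

The generator exists so every stage can be validated against planted truth.
It emulates:

* two analytic end states — a uniform sphere (radius $R = 25$ Å by default)
  and a tangent two-sphere dimer with per-particle
  $I(q) = 2 s V^2 P(q)\,[1 + \sin(2qR)/(2qR)]$ — normalized so monomer
  forward scattering is 1. The default radius keeps the sphere's first
  intensity zero ($q = 4.4934/R$) above the 0.15 Å$^{-1}$ window edge,
  where a node would make intensity ratios ill-defined under noise. The
  form-factor amplitude switches to its series expansion below $u = 0.05$
  to avoid catastrophic cancellation;
* first-order conversion $x(t) = x_\infty (1 - e^{-kt})$, mixed
  number-weighted so that $I(0,t)/I(0,0) = 1 + x(t)$ holds exactly in the
  noiseless limit;
* frame-wise Gaussian noise
  $\sigma(q) = \epsilon \sqrt{I(q,t)/I(0,t)}$ (floored at $\epsilon/10$),
  the post-subtraction counting-statistics shape; and a per-well
  concentration factor $\mathcal N(1, 0.015)$ emulating pipetting scatter.
  The split matters: the per-well factor spreads replicate $I(0)$ values —
  putting the $I(0)$ Z-factor in the high-0.8s, typical of a good assay
  window — while leaving $R_g$ and the scale-invariant V$_R$ untouched;
* a 12-compound library in four planted chemotypes: full converters with
  the fastest rates (k 1.2–2.0 s$^{-1}$), partial converters at
  intermediate rates (0.43–0.80 s$^{-1}$, plateaus 0.64–0.74), weak but
  fast converters ($x_\infty \approx 0.245$, k 0.51–1.05 s$^{-1}$), and
  inactives. The rates form a ladder with adjacent spacing chosen to be
  resolvable within the 3-s span at the default noise
  ($\epsilon = 5\times10^{-4}$, the bright-beamline regime), and the
  plateaus equalize each class's converted fraction at 2.1 s so the
  chemotype geometry is tight within classes and well separated between
  them. A weak-and-slow class would be kinetically unresolvable on 3 s of
  data — that design corner is deliberately avoided, and real screens with
  such compounds should use the 10-s series option;
* DSF melts (Boltzmann plus post-peak decay) and MST step traces with
  planted shifts, a planted pathological-curve fraction (default 0.23,
  as flat-high interference or no-transition ramps), and DMSO reference
  pools. Reference replicates scatter with the pool spread
  ($\sigma_{T_m} = 0.15$ °C), compound wells with the much smaller
  within-plate precision (0.03 °C); this is what makes 3-s.d. calls
  against a reference pool reliable in practice, and with the two
  conflated, a 3σ rule would mathematically admit ~0.3% false calls per
  compound no matter how many references are measured.

What it does **not** emulate: interparticle interference and concentration
effects, radiation-damage aggregation, detector artifacts, buffer-mismatch
systematics, capillary-shape MST artifacts, or realistic protein form
factors (the two-sphere dimer is the simplest shape with the right
$I(0)$ doubling and $R_g$ growth, not a structural model). Passing tests on
this plate therefore demonstrate that the *statistics and plumbing* recover
planted structure under idealized noise — not that any given real dataset
will separate as cleanly.

## Determinism and numerics

Every stochastic step (noise draws, k-means restarts) flows from explicit
integer seeds; identical configuration plus seed reproduces outputs
bit-identically, and `.dat` round-trips preserve 12 significant digits.
Time alignment in buffer subtraction tolerates 1 ms. Frame times default to
$(i{+}1) \times$ exposure when unstated, so the first 300-ms frame is
labeled 0.3 s. Degenerate inputs favor explicit flags over guesses:
undefined Z-factors (equal control means), indeterminate T$_m$ (no
significant rise), low-confidence KL scans (vanishing DIFF), and
sub-10-point aggregation windows all say so rather than returning a number
silently.

## Problem sizes

The test suite and the acceptance script run the full default plate
(17 protein wells × 10 frames × 256 $q$-points), 50-trace kinetic
recovery benchmarks, and 40-plate triage null screens; together they
complete in well under two minutes on a single core, and the sizes are
stated here as the package's validation conditions.

## Known limitations

* Absolute V$_R$ magnitudes depend on the binning convention; only
  within-convention comparisons are meaningful.
* k$_{VR}$ is a phenomenological rate: it inherits a mild amplitude-
  dependent distortion from the V$_R$-to-fraction mapping, so it ranks
  reliably but should not be read as a microscopic rate constant.
* The Guinier window convention ($q_{max} R_g \le 1.3$) trades a small
  systematic $R_g$ bias for robustness on short noisy frames.
* Buffer scaling is fixed at 1.0 by default; screens with compound-
  dependent buffer mismatch need the override and their own validation.
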