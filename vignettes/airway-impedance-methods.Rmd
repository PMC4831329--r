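---
title: "Modelling respiratory impedance from ventilation-defect maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling respiratory impedance from ventilation-defect maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungsim)
```

## The problem

Hyperpolarized-gas MRI of the asthmatic lung shows *ventilation defects*:
contiguous regions that receive little or no inhaled gas. The forced
oscillation technique (FOT) measures the same lung's mechanical state as a
complex input impedance — resistance $R_{rs}(f)$ and reactance $X_{rs}(f)$
over frequency. `lungsim` connects the two: it narrows the airways of a
computational airway tree wherever they coincide spatially with ventilation
defects, computes the resulting oscillatory impedance, and provides the
statistical machinery to relate ventilation defect percent (VDP) to the
impedance predictions. Because no patient images ship with the package, a
synthetic phantom and cohort generator stands in for the imaging study and
lets every stage run end to end.

## The airway-tree substrate

The mechanical substrate is an asymmetric, at-most-binary airway tree whose
per-generation branch counts, terminal counts and diameter statistics match
the packaged morphometry table (`default_morphometry()`): 26 generations,
64,893 branches, 32,447 terminal branches, tracheal diameter 14.12 mm.
`generate_tree()` reproduces the branch and terminal counts *exactly* —
which branches of a generation terminate is a seeded random choice — and
draws diameters from a normal distribution clipped to the tabulated
$[d_{min}, d_{max}]$. Clipping biases a sample mean away from the target,
by more than two standard errors in the distal generations, so the pre-clip
location is recentred analytically (via the closed-form clipped-normal
mean) to make the per-generation expected diameter equal $d_{mean}$.

Branch centerlines come from recursive halving of a lung bounding box
(default $300 \times 250 \times 210$ mm, matching a $128 \times 128 \times
14$ thoracic grid at $3.13 \times 3.13 \times 15$ mm voxels): each branch
owns a sub-box, children split it along its longest axis, and a branch's
endpoints are its parent's box centre and its own. The embedding guarantees
that subtrees occupy compact contiguous regions — the only property the
downstream defect-overlap step needs — but the centerlines are *not*
anatomical, and branch lengths (the Euclidean endpoint distances) exceed
anatomical airway lengths in the periphery. Absolute impedance magnitudes
are therefore somewhat high compared with anatomical models; the
VDP-impedance *relationships*, which are what the package studies, are
unaffected.

## Oscillatory mechanics

Each branch of radius $r_a$ and length $l_a$ carries the rigid-tube
oscillatory-flow (Womersley) impedance

$$Z_a(f) = \frac{j\,2 f \rho\, l_a}{r_a^{2}}
\left[1 - \frac{2 J_1(\alpha\sqrt{-j})}{\alpha\sqrt{-j}\,
J_0(\alpha\sqrt{-j})}\right]^{-1},
\qquad \alpha = r_a \sqrt{\frac{2\pi \rho f}{\mu}},$$

with air density $\rho = 1.16$ kg/m³ and viscosity $\mu = 1.85\times
10^{-5}$ Pa·s (humid air at 37 °C). Everything is evaluated in SI and
converted once to cmH₂O·s/L (÷ 98 066.5). The complex-order-zero/one Bessel
functions are evaluated from their power series in $u = z^2/4$ for
$\alpha \le 50$ and from the Hankel asymptotic $P/Q$ expansion beyond; the
two regimes agree to about $10^{-10}$ at the switch, and both are verified
in the tests against an independent integral-representation oracle. The
printed form $j 2 f \rho l / r^2$ equals the textbook
$j \omega \rho l / (\pi r^2)$ after $\pi$-cancellation; the argument
convention $\alpha\sqrt{-j}$ equals $\alpha\, j^{3/2}$ by Bessel parity,
which a test checks numerically.

Lung compliance is distributed evenly over the terminal airways: each of
the $N$ leaves is an alveolar compartment of elastance $E_t = E_L N$, so
the parallel combination returns the total lung elastance $E_L$ (default
10 cmH₂O/L, configurable — the value is a model parameter, not a measured
one). A terminal branch's impedance is $Z_t = Z_a - j E_t/\omega$. The lung
input impedance is the post-order reduction $Z_{in}(b) = Z_a(b) +
[\sum_c Z_{in}(c)^{-1}]^{-1}$, implemented as an iterative
generation-by-generation sweep (no recursion depth limits, vectorised per
generation) and verified against a brute-force nodal-analysis oracle to
$10^{-9}$ relative on random trees.

Respiratory-system impedance adds central-airway and chest-wall resistance
($R_{central} = R_{cw} = 0.5$ cmH₂O·s/L) and chest-wall elastance
($E_{cw} = 10.6$ cmH₂O/L). An optional upper-airway shunt divides flow
through a per-frequency complex $Z_{uaw}$ (log-frequency linear
interpolation, linear extrapolation to 0.2 Hz); it is off by default and
the packaged table (`default_shunt_table()`) is an explicitly *synthetic*
resistance-inertance-compliance stand-in, to be replaced by measured
values when available.

Spectra are evaluated on eleven frequencies over 0.2–32 Hz containing
0.2, 5 and 20 Hz exactly; `derived_metrics()` extracts the band metrics
$R_{rs0.2-5}$, $R_{rs5-20}$ and the low-frequency elastance $E_{rs}(f) =
2\pi f\,|X_{rs}(f)|$ at 0.2 and 5 Hz only. The magnitude is used because
$X_{rs}$ is negative where elastance dominates.

### Two properties that are *not* universally true

Exploration with the nodal oracle falsified two tempting monotonicity
statements, and the package documents rather than hides them:

* narrowing a branch can *lower* $\mathrm{Re}\,Z_{in}$ at
  elastance-dominated frequencies (~0.2 Hz): blocking a terminal pathway
  removes its resistive loading of the elastic current. At oscillometry
  frequencies (5–20 Hz) per-branch narrowing monotonicity holds and is
  tested.
* if *every* parallel pathway of a generation is narrowed to 10%, the
  narrowed tubes' inertance (~100× larger at one-tenth radius) dominates
  and $X_{rs5}$ flips positive. Defect-driven closures are always partial,
  and the monotone growth of $R_{rs5}$ and $-X_{rs5}$ with the closure set
  is asserted on partial closures.

## Imaging: segmentation, clustering, VDP

The thoracic cavity is segmented from a proton-like anatomical image by
seeded region growing: voxels whose intensity falls within the seed-region
range widened by 15% of the global intensity range, 26-connected to a
seed. Components are labelled with `igraph`; the same machinery serves the
defect-region extraction.

Ventilation voxels inside the cavity are classified into five clusters by
intensity, cluster 1 (C1) being signal void — the ventilation defect class
— and VDP is the C1 share of the cavity volume. Two clustering modes
exist. Without a reference, plain Lloyd k-means (k-means++ seeding, best
of five seedings, 100 iterations) runs on the cavity intensities, which is
the behaviour exercised by the plateau-phantom tests. For pipeline use a
*noise reference* (a sample of background voxels, about a tenth of the
cavity mass) participates in a first 2-means split that separates signal
void from ventilated signal; the ventilated voxels are then subdivided
into the remaining four classes. This two-stage hierarchy mirrors the
hierarchical variant of the validated segmentation method and is essential
in practice: flat 5-means on a unimodal ventilated distribution must
allocate ~10% of the cavity to its lowest cluster (so a fully ventilated
lung would never score VDP < 2%), and with a large void class it bistably
splits the noise peak instead. On the packaged phantoms the hierarchical
mode recovers true VDP to well under one percentage point at SNR 10.

Defect regions are 26-connected C1 components whose bounding box strictly
exceeds 10 voxels in x or y (≈ 3 cm at 3.13 mm spacing); smaller defects
still count toward VDP but do not drive closure.

## Coregistration

The tree model is mapped into image voxel space by a rigid transform
fitted to paired fiducial landmarks (8–10 points on the lung boundary)
with the closed-form orthogonal-Procrustes/Kabsch solution, including the
reflection guard; the fiducial registration error (FRE) is reported.
Voxel indices are R-style 1-based throughout (world mm = origin +
(index − 1) × spacing) — a deliberate convention choice for an R package.
Anterior-posterior slab resampling assigns z coordinates to half-open
15 mm slabs, so every point belongs to exactly one slab; Dice similarity
against the segmented cavity quantifies registration accuracy (phantom
registrations score DSC ≥ 0.75 on every substantive lung slice, typically
≈ 0.95). The per-slice 2D refinements and nonrigid step of interactive
workflows are intentionally collapsed into the single 3D rigid fit: the
phantom generator provides exact fiducial correspondences, so slice-wise
refinement has nothing further to correct.

## Defect-driven closure

"Airways within ventilation defects and within two voxels of their
boundary" is operationalised as: a branch of the target generation is
selected iff its midpoint voxel lies in the defect mask dilated by the
margin (Chebyshev/26-connected dilation, default 2 voxels). The midpoint —
rather than the full centerline — keeps selection unambiguous on 15 mm
slabs. Selected branches are narrowed to 10% of diameter, which raises
their Poiseuille resistance by 10⁴ and functionally closes the distal
subtree while avoiding zero diameters. The conventional proximal and
distal choices are generation 9 and generation 14. A configuration switch
(`narrow_scope = "at_and_distal"`) additionally narrows every descendant,
for the reading of "closed distal to generation N" in which the whole
subtree is narrowed; the default narrows the generation-N branches only,
since the distal lung is already blocked through them.

## The synthetic study

`generate_phantom()` builds one subject-condition: a two-ellipsoid lung
cavity placed in the model frame, a true rigid transform (small in-plane
rotation, jittered centring translation) into the image frame, a
proton-like image (body shell 200, cavity 60, background 0, Gaussian
noise), and a ventilation image whose cavity signal is a smooth field
(mean 100, ±17% regional modulation) with Gaussian noise at the target
SNR (default 20; SNR is ventilated mean over noise SD — Gaussian, not
Rician, noise is a deliberate simplification). Defects are the N cavity
voxels nearest to blob seeds, N chosen to hit the target defect fraction
exactly (well within the 0.5-point tolerance); when a tree is supplied the
seeds are midpoints of randomly chosen generation-9 branches, so defects
are subtree-aligned and segmental in character, which keeps closure plans
non-empty at realistic VDP. Fiducials are emitted in both frames with
1 mm image-side noise.

`generate_cohort()` draws 25 subjects × 3 conditions with true VDP from
truncated normals — (mean, SD) = (4, 4), (11, 10), (4, 2) percent for
baseline, post-methacholine and post-salbutamol, truncated to [0, 60] and
recentred so the truncated expectation equals the stated mean. Simulated
FEV₁ %predicted (means 84/64/87, SD 15) couples negatively (−0.6) to the
latent VDP draw; simulated Raw %predicted (mean 126, SD 69) couples
positively (+0.7). The couplings and truncation bounds are generator
choices, documented here, not measured values. `run_cohort_pipeline()`
then runs every stage — phantom, segmentation, clustering, VDP, defect
extraction, registration, closure at generations 9 and 14, impedance — on
each of the 75 subject-conditions, sharing one FRC-scaled tree (all
diameters and lengths × 0.8, volume ratio 0.512) and caching the
unnarrowed branch impedances so only narrowed branches are re-evaluated.

What passing on phantoms does *not* show: robustness to Rician noise,
coil shading, breathing motion, imperfect manual fiducials, or anatomical
centerline geometry. The phantoms test the pipeline's logic and the
model's directional behaviour, not clinical image quality.

## Statistics

`analyze_cohort()` reproduces the analysis matrix of this study design:
Shapiro-Wilk-screened correlations (Pearson when both variables pass at
0.05, Spearman otherwise) of VDP with FEV₁, Raw and the 5 Hz impedance
metrics; sign-agnostic Fisher-z comparisons of correlation magnitudes
(independent-samples formula; a Steiger-style dependent variant is
available when the inter-predictor correlation is known); per-frequency
slopes of each metric against VDP; ANCOVA slope-homogeneity tests
(computed directly from nested residual sums of squares, which returns
exactly F = 0 for identical fits where `anova()` blanks on round-off);
and Holm-Bonferroni step-down correction over the comparison family. All
75 subject-conditions are pooled as independent observations — mirroring
the emulated design — and the result object flags this pooling; a
mixed-effects treatment of the repeated measures is out of scope.

## Problem sizes and determinism

Default problem sizes are the study's own: the full 64,893-branch tree,
128 × 128 × 14 images, 25 × 3 subject-conditions, eleven frequencies. A
full cohort run takes a few minutes on one core. Every stochastic stage
(tree generation, phantoms, cohort draws, k-means seeding) consumes a
caller-supplied seed through an RNG-state-preserving wrapper, so identical
seeds give bit-identical trees, images and records.
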