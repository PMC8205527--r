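---
title: "Modelling the hinged coiled-coil architecture of the CtIP N-terminal domain"
author: "ctipcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the hinged coiled-coil architecture of the CtIP N-terminal domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctipcc)
```

## The scientific problem

The DNA double-strand-break repair factor CtIP tetramerises through a
short N-terminal motif (residues 18--32) and projects two long parallel
coiled-coil dimers in opposite directions -- a "dimer of dimers" capable
of bridging distant DNA sites.  Each dimer arm (the cNTD, residues
31--145) contains two coiled-coil segments, CC-N (V35--L84) and CC-C
(I117--L138), separated by a zinc-binding motif in which cysteines C89
and C92 of both chains share one zinc ion.  Solution data indicate that
this motif acts as a *hinge*: the zinc-bound wild type is kinked and
dynamically flexible, while a C89A/C92A mutant that cannot bind zinc is
near-straight, more rigid, and less thermostable.

`ctipcc` packages the quantitative machinery behind that conclusion as
reusable, tested code:

1. **Geometry** -- ideal Crick-parameterised coiled-coil dimers, a
   rigid-body hinge at the zinc motif, cis/trans tetramer assembly, and
   geometric observables (axial length, maximum dimension, interdomain
   angle).
2. **SAXS analytics** -- Debye-formula curves from coordinates, Guinier
   $R_g$, cross-sectional $R_c$, pair-distance distributions $P(r)$ with
   $D_{max}$, reduced $\chi^2$ model comparison, and hinge-angle
   inference by rigid-body grid search.
3. **CD thermal unfolding** -- two-state Gibbs--Helmholtz simulation and
   fitting, and melt/refold hysteresis quantification.
4. **DXT trajectory analysis** -- rotational Brownian simulation of
   tilting ($\theta$) and twisting ($\chi$) angles, motionless/edge
   filtering, time-averaged MSD, displacement distributions and
   WT$-$Mut difference histograms, and diffusivity estimation.
5. **Synthetic data** -- seeded paired WT/Mut bundles with recorded
   ground truth, used by the recovery tests.

## Coiled-coil geometry

Models are C$\alpha$ traces (optionally with a side-chain centroid
pseudo-atom 1.5 Å radially outward) built from the Crick
parameterisation: each helix winds with minor radius $r_1 = 2.26$ Å
about a local axis that supercoils at superhelical radius
$r_0 = 4.9$ Å around the shared axis, with an axial rise of
$1.485$ Å per residue and $3.62$ residues per turn in the laboratory
frame.  The superhelical pitch is not free: a heptad repeat fixes 3.5
residues per turn in the frame rotating with the supercoil, so
$P = d\,\frac{3.5\,n}{n - 3.5} \approx 157$ Å at the defaults.  Two
conventions matter numerically:

* the supercoil pitch angle carries the handedness sign (negative for
  the canonical left-handed dimer); with an unsigned angle the backbone
  acquires spurious ±0.5 Å C$\alpha$--C$\alpha$ oscillations;
* the two chains are related by an exact 180° rotation about the
  superhelical axis, which the tests exploit (chain-axis separation is
  exactly $2 r_0$ after unwinding the supercoil).

The zinc motif (residues 85--116) interrupts the heptad repeat: in the
crystal structure its helices run parallel rather than supercoiled.  We
model motif residues as straight, vertical-axis ideal α-helices
(lab-frame twist, same rise) anchored continuously to the flanking
supercoiled segments, with CC-C resuming supercoiling at the frozen
azimuth.  An earlier variant that merely froze the supercoil phase while
keeping the tilted-frame minor-helix terms broke the backbone-spacing
invariant (C$\alpha$--C$\alpha$ down to 3.54 Å); the current
construction keeps every step in 3.73--3.77 Å.

The hinge is a rigid-body rotation of everything C-terminal of a pivot
(default residue 91, the C89xxC92 midpoint) about an axis through the
dimer axis, applied identically to both chains; `angle_deg` is the
resulting CC-N/CC-C interior angle, so 180° is the identity.  Because
the published solution estimates of the wild-type angle disagree (120°
from multi-phase bead modelling, 140° from MD-based rigid-body
modelling), the angle is a free parameter everywhere and the default
synthetic scenario uses their midpoint, 130°.

Tetramers are an idealised head-to-head docking: a second copy is
rotated 180° about an in-plane axis through the centre of the shared
overlap region (residues 31--52), so the copies run anti-parallel with
their overlap windows superposed.  For hinged dimers the flip axis is
chosen along the bend direction (*cis*: both CC-C arms on the same
side) or perpendicular to it (*trans*: opposite sides).  Both
assemblies are exact involutions, so each has a true two-fold axis; the
tests verify the C2 explicitly and the invariant
$D_{max}(\mathit{trans}) \ge D_{max}(\mathit{cis})$.  No
interdigitation of the 18--32 tetramerisation motif is modelled -- the
docking stands in for a crystal structure that is out of scope.

## SAXS analytics and their limits

Theoretical curves use the vacuum Debye sum over unit point scatterers,
$I(q) = \sum_{ij} f_i f_j \,\mathrm{sinc}(q r_{ij})$ -- exact for the
model, but without hydration shell or atomic form factors.  Absolute
intensity is therefore never interpreted; every downstream quantity is
shape-based and scale-invariant (verified by test).

*Guinier*: $\ln I$ vs $q^2$ over the largest low-$q$ window with
$q_{max} R_g \le 1.3$ (default).  For strongly elongated particles the
Guinier approximation fails early: at the 1.3 limit the cNTD dimer's
$R_g$ is underestimated by ~7%.  The rod-appropriate limit 0.65
recovers the coordinate $R_g$ to 1--2% and is what the oracle tests use
for that model; the default is kept at 1.3 for compact particles.

*Cross-section*: $\ln(qI)$ vs $q^2$ over an automatically chosen
intermediate-$q$ window (highest $R^2$ among sliding windows starting
above the whole-particle Guinier region, subject to
$q_{max} R_c \le 1.3$), $R_c = \sqrt{-2\,\mathrm{slope}}$.  The
uniform-cylinder oracle ($R_c = R/\sqrt 2$) is met within 5%.  The
experimental values for the cNTD (8.4/9.4 Å) include solvent-contrast
cross-section that a C$\alpha$ trace cannot have; the model's
$R_c \approx 5$ Å is asserted only to lie on the coiled-coil scale, as
a range check.

*Hinge inference*: published flexible-modelling pipelines (bead models,
SAXS-directed MD) are replaced by a deterministic grid search with the
same rigid partition -- domains 31--91 and 93--145 rigid, flexibility
at the zinc site.  For each candidate angle a hinged dimer is built,
its Debye curve computed on the data grid, and the reduced $\chi^2$
after optimal scalar scaling recorded; the fit is the arg-min.  With
the synthetic noise model (multiplicative Gaussian,
$\sigma(q) = I(q)(a + b\,q/q_{max})$, defaults $a = 0.01$, $b = 0.04$)
a 120° model is recovered within ±5° at 3% noise, straight-model data
returns exactly 180°, and the noise-free profile is unimodal.

**What the Dmax criteria establish.**  The ideal 31--136 dimer spans
156.0 Å axially, matching the 160 Å crystal length within the 5 Å
tolerance.  The experimental solution $D_{max}$ values (Mut 180 Å,
WT 170 Å) exceed the crystal-derived helix length -- the real protein's
$P(r)$ includes disordered termini and hydration.  An ideal-helix model
that reproduces the crystal length therefore cannot also reach the
solution $D_{max}$: the straight 31--145 model gives 169.1 Å (2.9 Å
below the 180 ± 8 Å window) and the 140°-hinged model 160.7 Å (1.3 Å
below 170 ± 8 Å).  The *contrast* -- hinging shortens $D_{max}$ by
~9 Å, close to the experimental 10 Å -- is reproduced; the two absolute
checks are deliberately left failing at their stated tolerances rather
than met by inflating the rise parameter.

## Two-state CD thermodynamics

Unfolding at 222 nm is modelled as two-state with
$\Delta G(T) = \Delta H\,(1 - T/T_m) + \Delta C_p\,(T - T_m - T\ln(T/T_m))$,
$K = e^{-\Delta G/RT}$, $f = K/(1+K)$, and the observed signal a
population-weighted mix of two linear baselines.  $\Delta C_p$ defaults
to 0 (the published fits do not print the rearranged equation or its
parameters); $f(T_m) = 1/2$ exactly for any parameters.  Defaults
emulate the reported system: $T_m$ 333.7 K (WT), 317.0 K (Mut),
323.0 K (EDTA-treated WT, zinc removed), grid 278--368 K in 2 K steps,
$\Delta H = 300$ kJ/mol (a typical coiled-coil-domain value; not
printed in the source data), baselines (−25, 0.02) and (−4, 0.01)
signal units, noise 0.4 units ≈ 2% of the transition amplitude.
Fitting is `nls` (port) over six parameters with data-driven starts and
perturbed-restart retries; non-convergence is flagged, never silent.
At 2% noise the median $|T_m|$ error is ≈ 0.16 K and median bias
< 0.02 K.

Wild-type refolding hysteresis is *phenomenological*: the refold branch
is generated at an apparent $T_m$ shifted by −6 K, mirroring the
qualitative observation that melt and refold curves of the zinc-bound
protein do not coincide while the mutant's overlap.  No kinetic model
is implied; `hysteresis_area()` integrates |melt − refold| on a shared
grid and is used only as an ordering/positivity statistic.

## DXT trajectory analysis

The pipeline starts from angular trajectories (spot id, $t$, $\theta$,
$\chi$) -- the detector-to-angle mapping is hardware-specific and out
of scope.  Motion is simulated as independent 1-D Brownian walks
(increments $\mathcal N(\mu\Delta t,\,2D\Delta t)$) at 25 ms/frame for
3 s (121 frames), with a motionless subpopulation ($D = 0$, default
20%) and a 5% edge-flagged subpopulation.  Filtering excludes edge
spots and spots whose total $\theta$ range is below 1 mrad (the
published threshold; range is the strictest simple statistic, since the
statistic itself is not stated).  MSD is time-averaged and pooled
across tracks; the displacement distribution at lag 200 ms uses 81 bins
over ±20 mrad.

Defaults $D_\theta^{WT} = 0.02$, $D_\theta^{Mut} = 0.008$,
$D_\chi = 0.008$ rad²/s reproduce the reported *pattern* -- a clearly
more dynamic wild type, with the difference confined to the tilting
angle -- as a detection property; no magnitudes are printed in the
source, so these are stated synthetic-world values, not estimates.  The
two-sample Kolmogorov--Smirnov comparison uses *non-overlapping*
displacement windows: non-overlapping Brownian increments are
independent, so the $\chi$-channel null rejects at the nominal ~5%
rate, while overlapping pooling (fine for MSD averaging) would inflate
it.  Over 50 seeded replicate pairs the $\theta$ channel is detected in
100% and the $\chi$ channel in ~6% of replicates.

## Synthetic bundles and what a green test establishes

`generate_scenario()` writes a paired WT/Mut bundle (2 scattering
curves, 6 melt curves, 2 track tables, `truth.json`, `manifest.json`
with MD5 checksums) deterministically from a master seed; regeneration
is bit-identical.  Ground truth is read only by tests.  The generator
emulates the *statistical structure* of the study's contrasts --
counting-like SAXS noise growing with $q$, two-state melts with
hysteretic WT refolding, $\theta$-specific diffusivity differences with
a static subpopulation.  It does **not** emulate hydration scattering,
inter-particle effects, instrument baselines and drift, non-two-state
folding intermediates, detector geometry, or tracking/linking errors.
A green recovery test therefore establishes that the analysis code
correctly inverts its own stated forward models at realistic noise --
not that it would reproduce the published numbers from raw beamline
data, which are not deposited.

## Numerical choices and degenerate inputs

* Angles are degrees in interfaces and reports, radians internally;
  coordinates in Å; temperatures in kelvin; $R = 8.314\times10^{-3}$
  kJ mol⁻¹ K⁻¹.
* $P(r)$ bin width 1 Å; $D_{max}$ is the exact maximum pair distance,
  not a bin edge.  Default $q$ grid 0.005--0.35 Å⁻¹, 256 points.
* `chi_square` interpolates the model onto the data grid, applies the
  analytically optimal scale, and divides by $n - 1$.
* Thin-rod cross-section fits return $R_c \approx 0$ (flat
  $\ln(qI)$) instead of erroring; truly globular curves error with a
  diagnostic.
* Single-residue ranges are legal models (axial length 0) but cannot be
  hinged or geometry-measured; hinge pivots must be strictly interior;
  `insert_hinge(·, 180°)` is the exact identity.
* PDB output is fixed-width (8.3 coordinates), so round trips are exact
  to 0.001 Å; malformed records error with their line number.
* All simulation seeds flow from explicit `seed` arguments (CLI:
  `--seed`); sub-seeds for bundle components are derived
  deterministically from the master seed.

## Known limitations

Vacuum unit scatterers (no hydration layer or form factors); idealised
tetramer docking without the real tetramerisation-motif interface;
phenomenological hysteresis; 1-D angular diffusion without great-circle
coupling; no fitting of the study's experimental curves (not deposited
with the text).  The two absolute $D_{max}$ checks fail by 1--3 Å for
the structural reason discussed above and are retained as failing
tests.
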