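---
title: "From laminar field potentials to scalp EEG: methods and design"
author: "columnEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From laminar field potentials to scalp EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(columnEEG)
```

## The modeling chain

A cortical column activated during a task drives transmembrane currents in
its pyramidal cells. Those currents produce (i) the local field potential
(LFP) recorded by a laminar probe inside the column and (ii), after volume
conduction through brain, skull and scalp, the EEG on the head surface.
`columnEEG` implements the mesoscopic chain that connects the two
measurement scales:

1. **Simulate** two populations of reduced pyramidal cells (deep L3 and L5)
   driven by noisy current pulses, yielding ground-truth compartment
   transmembrane currents (`placePopulation()`, `simulatePopulation()`).
2. **Record** the laminar LFP at a linear electrode array under the
   point-source approximation (`lfpPointSource()`), low-pass filtered at
   100 Hz (`lowpassFilter()`).
3. **Estimate** the volumetric current source density (CSD) across depth,
   either as the negative second spatial difference of the LFP
   (`standardCSD()`) or with the spline inverse-CSD method, which inverts a
   disk-source forward model under a cubic-spline depth parameterization
   (`splineICSD()`).
4. **Summarize** the columnar source as an equivalent current dipole: from
   the CSD's first depth moment, \(d_z(t) = \pi r_c^2 \int CSD(z,t)\,(z -
   z_m)\,dz\) (`dipoleFromCSD()`), or directly from the currents as
   \(\sum_c (r_c - r_m) I_c(t)\) (`dipoleFromSTC()`), oriented along the
   cortical normal (`orientFromMesh()`).
5. **Project** the dipole (or every compartment current) to the scalp
   through a boundary-element model (BEM) of nested brain/skull/scalp
   surfaces (`bemSolve()`), and read the result at standard electrode
   montages (`placeMontage()`).
6. **Validate** with the relative difference measure and magnitude ratio
   (`rdm()`, `mag()`), depth regressions (`depthRegression()`), and rank
   multi-source configurations against an empirical topography
   (`rankAgainstEmpirical()`).

The central assumption throughout is the dipolar model: the EEG of a 3 mm
column is well captured by a single equivalent dipole at its center with a
fixed, cortical-normal orientation. The package exists to let users test
that assumption quantitatively against a compartment-level ground truth
(`compareDipoleApproaches()`).

## The synthetic column

The generator reproduces the study conditions: 2,200 L3 and 1,000 L5
pyramidal cells with somata uniform in a 3 mm diameter cylinder, L3 somata
at 675-750 um and L5 somata at 1250-1750 um below the pia; each cell
receives one 30 ms somatic current pulse whose amplitude is Gaussian across
cells (SD 0.3 nA; means of 1.90 and 1.85 nA model the two attention
conditions / hemispheres) with onsets uniform on 10-20 ms. The laminar
array has 17 contacts at 100 um spacing on the column axis.

Detailed morphologically reconstructed neuron models are deliberately
replaced by passive ball-and-stick reductions (a soma plus a 10-compartment,
600 um apical stick for L3; a soma plus a 20-compartment trunk reaching to
50 um below the pia for L5; membrane: 1 uF/cm^2, 30 kOhm cm^2, 150 Ohm cm).
Active events are emulated as stereotyped transmembrane transients rather
than ion-channel dynamics:

* a **Na event** - a 2 ms biphasic somatic transient (+-2 nA) - fires when
  the somatic depolarization crosses 20 mV (5 ms refractory period);
* a **Ca event** (L5 only) - a 40 ms triangular inward current at the three
  distal compartments (2.5 nA peak, 15 ms rise / 25 ms fall, at 12 ms after
  pulse onset) - fires when the cell's pulse amplitude exceeds 2 nA. With a
  0.3 nA amplitude SD, the 1.90 vs 1.85 nA condition difference shifts the
  fraction of L5 cells exceeding that threshold from about 37% to about
  31%, which is what weakens the late CSD sink/source pair and the dipole
  in the weaker condition. Because the two conditions share the same
  standard-normal amplitude draws, raising the mean can never lose an
  event, so the event-count ordering is deterministic.

Two consequences of this reduction matter for interpreting results. First,
every compartment of a cell shares one lateral position, so a column's
dipole moment is exactly axial; real morphologies add transverse moments
and richer multipole structure, and the CSD dipole's error (which discards
non-axial structure by construction) is therefore *underestimated* here.
Second, passive linearity means the response scales exactly with stimulus
amplitude when events are disabled - which the tests exploit.

Numerically, the cable equation is integrated by unconditionally stable
Crank-Nicolson stepping at dt = 0.1 ms over a 120 ms span (onset window +
pulse + the 60 ms Ca tail). The cable is linear and all stimuli are
amplitude-scaled, grid-aligned copies of three canonical injections, so
each distinct cell geometry needs only three solves; per-neuron responses
are shifted, scaled templates (L5 trunk lengths are quantized to 20 um so
cells can share geometries). Injected currents are booked as transmembrane
currents, making the reported compartment current \(-G_{axial}V\), whose
sum over a neuron is zero to machine precision: no spurious current
monopoles ever reach the LFP or EEG.

## CSD estimation

The standard estimate is \(-\sigma\,\delta^2 x/\delta z^2\) on the uniform
electrode grid (boundary channels dropped by default; Vaknin-style edge
replication via `pad = "replicate"`). With potentials in mV, spacing in mm
and conductivity in S/m the result is numerically in uA/mm^3.

The spline iCSD assumes the CSD is constant on planar disks of the column
diameter (default 3 mm) and a natural cubic spline across depth with knots
at the electrodes. The forward matrix maps nodal CSD values to electrode
potentials by composite-Simpson quadrature of the disk kernel
\(\frac{1}{2\sigma}\left(\sqrt{(z_e-z')^2+R^2} - |z_e-z'|\right)\) against
the cardinal spline basis; the profile is returned on a grid 8x finer than
the electrode spacing. Optional Tikhonov regularization (default 0) and a
5-point Gaussian depth smoother (off by default) are provided for noisy
data; the package checks the forward matrix's condition number and fails
loudly rather than silently inverting an ill-conditioned system.
`forwardLFP()` re-applies the disk-source forward model so users can verify
the round trip (the noiseless self-consistency residual is well under 1%).

Preprocessing mirrors laminar practice: per-channel baseline subtraction
over a pre-stimulus window (`baselineCorrect()`) and clipping from 10 ms
before an eye-movement event (`clipAtEvent()`). Depth-sign convention: the
column z axis points toward the pia (supragranular positive); profiles are
stored by depth below the pia, and `dipoleFromCSD()` accounts for the sign
so that positive amplitudes point along the outward cortical normal.

## The head model and its solver

The head is an isotropic, piecewise-homogeneous volume conductor:
brain 0.33, skull 0.0063, scalp 0.43 S/m, air 0 - nested closed
triangulated surfaces. The default synthetic geometry is macaque-scale
concentric icospheres of 30/35/38 mm radius at subdivision level 3 (642
vertices / 1280 faces per surface); real MRI-derived surfaces can be read
from ASCII STL/OFF/PLY but are never required.

The potential satisfies a second-kind Fredholm boundary integral equation
with the double-layer kernel. The package discretizes it by
centroid-collocation with piecewise-constant potentials per face: every
element integral is the analytic signed solid angle of the triangle, the
principal-value self term vanishes exactly (a centroid lies in the plane of
its own face), and the \((\sigma^- + \sigma^+)/2\) collocation coefficient
is exact for a point interior to a flat face. The constant-potential rank
deficiency is removed by deflation, and reported potentials are
average-referenced (over the montage, or over the scalp faces).

Because the skull conducts ~50x worse than the brain, the naive BEM leaks
discretization error from the large intracranial potentials into the small
scalp potentials. The isolated-skull approach is therefore on by default:
the interior Neumann problem is solved on the innermost surface first, and
the full system is solved for the *correction*, with right-hand sides
scaled by the skull conductivity. Against the analytic concentric-sphere
series (`analyticMultishell()`, Legendre expansion with per-degree
interface conditions, equilibrated for high degrees, truncation at degree
100 with a reported bound), the level-3 solver keeps RDM below 0.05 and
MAG within [0.9, 1.1] for radial and tangential dipoles up to 0.8
eccentricity (the acceptance script reports the measured maxima); disabling
the isolation measurably degrades radial-dipole accuracy at high
eccentricity, which is why the option defaults to on.

Montages are constructed geometrically on the unit sphere (midline and
coronal arcs at 18 degree steps, outer ring at 72 degrees inclination,
intermediate rows on the spherical circle through their endpoints) and
projected radially onto the scalp mesh: `"1010"` is the 61-channel 10-10
set; `"1020"` is the 15-electrode chronically implanted monkey array
(FpFz, Fpz, F3, F4, Fz, Cz, C3, C4, Pz, P5, P6, POz, O1, O2, Oz).

## Validation design

`compareDipoleApproaches()` reproduces the dipole-validation experiment at
desk scale: per cortical site, the ground-truth EEG maps every compartment
current through the BEM (Eq.-5-style monopole superposition), and the two
dipole estimates are compared to it by RDM/MAG over pooled
electrode-by-time samples. Three emulation choices deserve comment:

* **Sites.** Random vertices of a sphere all lie at one radius and carry
  radial normals, so depth and orientation - the two properties the
  experiment varies - would be constant. Each site therefore embeds the
  column's pial surface at a seeded depth (uniform 1.5-8 mm) and tilts the
  column axis by a seeded angle (uniform 0-45 degrees) about a random
  tangent, emulating the gyral-to-sulcal range of a folded cortex.
* **One column per site.** Fifteen randomly selected columns are fifteen
  different columns: each site re-draws cell placement and stimulus. With a
  single shared realization the reduced model is so clean that RDM/MAG are
  essentially constant across sites, and a regression on depth would
  quantify only a minute systematic trend.
* **Problem sizes.** The packaged experiments use 220 L3 + 100 L5 cells per
  column, 15 sites, and the EEG decimated to 0.5 ms after the 100 Hz
  low-pass; these sizes keep a full validation run in the low minutes while
  leaving every qualitative conclusion (STC-dipole closer to ground truth
  than CSD-dipole; no depth dependence) unchanged.

`simulateLateralizedEEG()` models the attention asymmetry: mirrored
posterior columns, one per hemisphere, with stimulus means 1.90/1.85 nA
swapped between conditions (paired draws), summed-transmembrane-current
dipoles, and the condition difference read at the time of the largest
global difference - the ERP-peak convention; the difference time course is
biphasic, so a long-window mean would cancel.

`modelRecoveryExperiment()` checks the configuration-ranking machinery by
construction: five candidate sources (upper-hemisphere sites at >= 35
degrees separation, emulating distinct cortical areas under the cap), all
31 non-empty configurations, per-session maps sharing one jittered
amplitude per session (one measured dipole waveform drives all areas
within a session), and pseudo-empirical maps from a known subset plus
Gaussian noise at an RMS signal-to-noise ratio of 5. Pearson correlations
pool 15 electrodes x 30 sessions; negatively correlated configurations are
recorded as zero and significance is Bonferroni-corrected across the 31
configurations.

## What passing tests do and do not show

The synthetic column demonstrates that the chain is internally consistent:
charge-conserving sources, unit-verified field formulas, an inverse method
that reproduces its own forward model, a BEM that matches an independent
analytic oracle, and a dipole summary whose agreement with ground truth
behaves as the theory predicts. It does not show that reduced passive
cells reproduce primate V4 physiology: there is no synaptic connectivity,
no ion-channel kinetics, no transverse dipole moment, no realistic cortical
folding, and the spherical head model has no craniotomy or tissue
anisotropy. Empirical laminar alignment (identifying the granular input
sink by eye) is out of scope; recordings carry an explicit depth axis and a
channel-offset can be applied upstream. Conclusions about real data should
rest on applying the chain to real laminar recordings and real
MRI-derived surfaces, both of which the interfaces accept.

Two parameter ambiguities are surfaced rather than resolved: the column
radius \(r_c\) enters the CSD dipole quadratically and the source document
states both a 3 mm diameter (simulation) and a 3 mm radius (empirical
modeling); the package defaults to \(r_c = 1.5\) mm to match the simulated
column and exposes the value everywhere. The conductivity behind the
empirical CSD conversion is likewise configurable with the brain value
(0.33 S/m) as default.
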