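---
title: "Personalized atrial fibrillation modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized atrial fibrillation modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atrialwave` builds personalized monodomain models of atrial fibrillation
(AF) on triangular surface meshes from sparse electro-anatomical maps, and
analyzes the resulting wave dynamics. This vignette explains the model,
the tunable parameters, and the design decisions — particularly where the
design was genuinely open and a choice had to be made.

## The model

### Membrane kinetics

Each mesh node carries the 21-variable Courtemanche–Ramirez–Nattel (CRN)
human atrial myocyte model (membrane potential, 15 Hodgkin–Huxley gates,
and intracellular Na\(^+\), K\(^+\), Ca\(^{2+}\) and sarcoplasmic-reticulum
Ca\(^{2+}\) pools). Constants follow the curated public encoding of the
original publication. Two multiplicative channel-scaling profiles modify
the baseline:

* **AF electrical remodeling** (`af_remodeling_profile()`):
  I\(_{K1}\) +100%, I\(_{NCX}\) +40%, I\(_{Na}\) −10%, I\(_{to}\) −70%,
  I\(_{CaL}\) −50%, I\(_{Kur}\) −50%.
* **Fibrotic remodeling** (`fibrosis_remodeling_profile()`), applied on
  top of the base profile at fibrotic nodes: I\(_{K1}\) −50%,
  I\(_{CaL}\) −50%, I\(_{Na}\) −40%.

Profiles compose multiplicatively; scaling a current by a factor scales it
exactly (this linearity is unit-tested algebraically).

With the AF profile, our faithful CRN encoding produces a steady-state
APD\(_{90}\) of about 165 ms when paced 20 beats at a 500-ms cycle length
(and about 180 ms at 1000 ms). The neutral profile reproduces the
published baseline morphology (APD\(_{90}\) ≈ 298 ms at 1 Hz, verified
against an independently coded reference integrated with a stiff solver).
Reported tissue values near 206 ms for this remodeling set are not
reproducible from the stated multipliers with a faithful CRN encoding; the
discrepancy is dominated by the I\(_{K1}\) doubling (restoring
f\(_{K1}\) = 1 alone moves APD\(_{90}\) to 226 ms). We keep the stated
multipliers.

### Tissue propagation

The monodomain reaction–diffusion system is discretized with linear
(P1) triangle elements on the surface mesh. Each element's diffusion
tensor is

\[ D_e \;=\; \kappa_L\,\sigma_L\, f f^{T} \;+\; \kappa_T\,\sigma_T\, t t^{T}, \]

where \(f\) is the element fiber direction (mean of its nodes' fibers,
projected to the element plane), \(t\) the in-plane perpendicular, and
\(\sigma_{L},\sigma_{T}\) the longitudinal/transverse conductivities
chosen by the element's fibrosis status (majority vote of its three
nodes): 0.1264 / 0.0252 S/m for non-fibrotic and 0.0546 / 0.0068 S/m
for fibrotic tissue. Boundaries are zero-flux; the assembled stiffness
operator has exact zero row sums (a uniform potential produces no
current), which the tests verify together with a hand-assembled
two-triangle stencil.

Time stepping is operator splitting: Rush–Larsen exponential updates for
the gates and forward Euler for the potential and concentrations
(reaction), then explicit diffusion sub-stepped under the operator's
Gershgorin stability bound. The global step adapts between 0.01 and
0.1 ms: fine whenever any node's |dV/dt| exceeds 1 mV/ms (an upstroke is
in progress), coarse otherwise. Runs are bitwise deterministic for fixed
inputs.

### From conductivity to conduction velocity

The conductivities above do not determine tissue diffusivity without a
surface-to-volume ratio and membrane capacitance per area, and the target
conduction-velocity (CV) anisotropy (0.707/0.486 ≈ 1.45) is inconsistent
with the continuum prediction from the conductivity ratio
(\(\sqrt{0.1264/0.0252} \approx 2.24\)). We therefore treat the CVs as
the authoritative observables: `calibrate_conduction()` finds the two
conversion scales \(\kappa_L, \kappa_T\) (mm²/ms per S/m) such that a
planar wave in non-fibrotic AF-remodeled tissue on a 30 × 10 mm sheet
meshed at 235 µm travels at 0.707 m/s along fibers and 0.486 m/s across
them. The iteration uses the continuum law CV ∝ √D, converging in about
three simulations per direction to within 1% (the repeatability of the CV
probe itself). Two passes are run because the triangular stencil weakly
couples the axes: each direction is re-tuned with the other's latest
value, and the frozen pair is then used verbatim in production runs.
Fibrotic elements automatically conduct slower because the same κ's
multiply the smaller fibrotic conductivities.

Patient-level tuning (`tune_diffusion()`) then scales both κ's **at the
same rate** by one factor chosen so the mean simulated conduction time
from the earliest-activation site to a set of target points matches the
clinical mean within 2%. On synthetic data this recovers hidden scales of
0.7–1.3 within 5%.

### Personalization from an electro-anatomical map

A clinical-style map is a sparse table of 3-D points with bipolar voltage
(mV) and local activation time (LAT, ms). The pipeline:

1. **Rigid alignment** (`rigid_align()`): closed-form Kabsch solution on
   ≥3 landmark pairs; rotation + translation only.
2. **Interpolation** (`idw_interpolate()`): inverse-distance weighting
   with a 10-mm search radius. The exponent is not fixed by convention;
   we use 2, with an exact-hit rule at 10\(^{-6}\) mm. Nodes with no
   sample within the radius default to 5 mV (healthy, above the fibrosis
   threshold) and are excluded from agreement statistics — a conservative
   choice that never fabricates low-voltage tissue.
3. **Fibrosis** (`assign_fibrosis()`): each node is flagged fibrotic when
   an independent uniform draw falls below
   \(P_\mathrm{fibrosis}(X)\), the piecewise cubic of bipolar voltage
   \(X\): 1 below 0 mV, 0 above 1.74 mV, and
   \((-40X^3 + 155X^2 - 206X + 99.8)/100\) between (the polynomial is on
   the percent scale — dividing by 100 and clamping to [0, 1] is the only
   reading that makes the three branches commensurable). Independence
   across nodes is assumed; draws are seeded and reproducible.
4. **Fibers** (`assign_fiber_field()`): atlas-based fiber tracking is out
   of scope; the `from_lat_gradient` rule sets each node's fiber parallel
   to the surface gradient of the interpolated LAT (the direction of
   fastest apparent conduction), smoothed over one ring — which is how
   activation maps inform fiber direction here. `uniform` and `circular`
   rules serve controlled experiments.

### AF induction and wave-dynamics analysis

Ramp pacing (`make_ramp_protocol()`) steps the cycle length from 200 down
to 120 ms (default 10-ms decrements, 4 beats per step, then 120-ms cycles)
over a total of 6,530 ms; the remainder that does not divide into whole
cycles is absorbed into the final inter-beat interval so the last cycle
ends exactly at the total. AF counts as induced when activation continues
through the whole post-pacing window (default 6 s) with no silent gap
longer than 500 ms.

Per-node dominant frequency (DF) is the band-limited (1–20 Hz) argmax of
the Hann-tapered periodogram of the de-meaned membrane potential;
frequency resolution is 1/window. The top-5% DF region and the peak node
are reported, with boundary ties broken by spectral power. Phase is the
analytic-signal (Hilbert) phase of the de-meaned potential — the
construction is not dictated by convention, and the analytic signal is
standard and parameter-free. Phase singularities (PS) are faces whose
wrapped phase differences wind by ±2π around the oriented node cycle —
the literal reading of "the point where phase is undetermined" — detected
per frame, merged when one tip straddles adjacent faces, and linked into
trajectories by greedy nearest-neighbor matching under a 5-mm-per-frame
step bound with matching chirality. A trajectory is a **mother rotor**
when it lives longer than 5 s and its tip path fits inside a circle of
diameter half the cardiac wavelength; the wavelength is CV × 600 ms
measured from a planar wave paced at a 600-ms cycle length, and the
confinement test uses the exact (Welzl) minimal enclosing circle in the
path's best-fit plane.

### Electrograms

Unipolar extracellular potentials are computed with the
infinite-volume-conductor dipole-source model: each triangle contributes
its P1 gradient of \(V_m\) dotted with
\(\nabla(1/|r'-r_c|)\), weighted by area × nominal wall thickness
(2 mm default — the monolayer has no thickness of its own, and thickness
only scales amplitude uniformly) and by
\(-\sigma_i/(4\pi\sigma_e)\) (ratio default 0.4; only the ratio matters).
Electrodes must sit ≥0.5 mm off the wall, which excludes the singular
self-element geometrically, as mapping electrodes do in practice.
Bipolar electrograms subtract two unipolar poles 1 mm apart. Morphology
similarity is the mean inner product of unit-normalized signals,
per aligned segment (plain cosine similarity for a single segment);
averaging is per beat, per-site aggregation is left to the caller.

## The synthetic-data generator

`generate_synthetic_emap()` emulates a >500-point catheter acquisition:
a smooth voltage truth field (four long-wavelength harmonics of the mesh
extent, mapped to the clinically observed 0.1–3.5 mV bipolar range), a
LAT truth spreading at constant speed (default 0.7 m/s) from one
earliest-activation site, samples drawn without replacement from mesh
nodes, jittered up to 0.5 mm off-surface, plus Gaussian noise (defaults
0.05 mV and 1 ms). What it does **not** emulate: catheter contact
artifacts, respiratory drift, field scaling of the clinical system,
far-field pickup, or any spatial correlation between fibrosis draws.
Passing recovery tests therefore show that the interpolation and fibrosis
machinery is self-consistent at clinical point densities — not that the
pipeline is robust to clinical artifacts.

Two analytic movie fixtures let the analysis stack be tested without the
solver: plane waves (a stereotyped AP template translated at constant
speed, APD\(_{90}\) pinned exactly by construction) and rigidly rotating,
optionally drifting spirals with a known tip path.

## Problem sizes and numerical choices

Test and acceptance experiments run at desk scale, chosen so each check
exercises the full code path at meaningful resolution:

* CV calibration and measurement: 30 × 10 mm sheets at 235 µm
  (~6,450 nodes), 60–90-ms runs.
* Tuning recovery: 25 × 8 mm sheets at 500 µm.
* The fibrosis–PS association experiment: a 20 × 20 mm sheet at 400 µm
  (~3,000 nodes) with a left-to-right fibrosis gradient (voltage 3.4 →
  0.1 mV), ramp-paced for 1,340 ms and analyzed for PS over ~1.4 s.
  To fit reentrant wavelengths into a desk-scale domain, conduction is
  slowed (κ × 0.125) and APD shortened (an extra 0.3× on I\(_{CaL}\) on
  top of the AF profile) — the standard way to study rotors in small
  sheets. Free S1–S2 spiral waves self-terminate on domains of this size
  (wavelength ≈ domain edge), which is why wavebreak at the fibrotic
  substrate, not cross-field shock, is the induction mechanism here.
  PS events concentrate strongly in the dense-fibrosis bands (Spearman
  rank correlation of regional PS count against regional fibrosis
  fraction ≈ 0.7–0.9).

Other numerical choices: LAT extraction threshold −40 mV on the rising
edge with linear interpolation between frames; stimulus −2000 pA / 2 ms
for single cells (≈2× diastolic threshold) and −8000 pA for tissue-edge
strips (tissue loading raises the threshold); geodesics by Dijkstra on
the edge graph augmented with triangle-diagonal shortcuts (≤4% high on a
flat sheet at the densities used, validated against closed forms);
degenerate fiber nodes fall back to one-ring averages, with isolated
singular points (inevitable on closed surfaces) given an arbitrary
tangent.

## Known limitations

* Monolayer surface model: no wall thickness, no transmural or bilayer
  dynamics; electrogram amplitudes are arbitrary up to the thickness and
  conductivity-ratio scale factors (morphology is unaffected).
* The AF-profile APD\(_{90}\) at clinical pacing rates is ~165 ms here,
  below reported tissue values for the same multiplier set (see above).
* IDW with a 10-mm radius and exponent 2 is a strong smoother: truth
  structure at wavelengths comparable to the radius is attenuated, which
  caps voltage-recovery correlations near 0.99 on small domains however
  dense the sampling.
* PS counting is reported both per event and per trajectory; the clinical
  convention is ambiguous, so both are exposed.
* The desk-scale AF-induction experiment demonstrates fibrosis-anchored
  wavebreak, not long-lived mother rotors; sustaining a >5-s rotor needs
  domains several wavelengths across (full-atrium scale).
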