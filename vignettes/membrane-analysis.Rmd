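---
title: "Methods: analysing native and oxidized bilayer models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing native and oxidized bilayer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oxbilayer` implements the analysis chain used to compare protein-free
erythrocyte-membrane models in their native and ferroptosis-oxidized states.
This vignette documents the models and conventions behind each stage, the
parameters that matter, and the design decisions taken where more than one
defensible choice existed. Internal units are nm, ps, amu and kJ/mol
throughout; every reader converts on ingest (PDB angstroms, for instance).

## The composition model

The membrane model holds 200 phospholipids and 100 cholesterol molecules.
The paper-trail constraints the packaged default table satisfies are: the
inner leaflet carries 157 lipids and the outer 143 (these totals *include*
cholesterol, split 50/50 between leaflets); the cholesterol:phospholipid
molar ratio is 0.5; PC and SM are enriched in the outer leaflet and PE/PS in
the inner, as flippase/floppase activity maintains in red cells;
phosphatidylinositol is folded into PS (both carry a −1 charge, and PI is a
minor fraction); and the hydroperoxide classes of the oxidized membrane land
within ±0.3 mol% of the stated values (~4.3/4.6 mol% for 9/13-HPODE,
~5.6/5.6 for 12/15-HPETE, ~4/4 for 14/17-HPDHA, ~1.6/2.3/1.6 for the three
double-hydroperoxide classes). The per-species counts are a *reconstruction*:
exact per-species inventories are not published, so the default table is one
consistent realization of all the published constraints and is fully
user-overridable (`build_native_composition(table = ...)`).

Substitution follows the oxidation chemistry: a PUFA chain yields two
positional hydroperoxide isomers (proximal and distal bis-allylic attack),
so single-PUFA species split 50/50 between isomers. Odd counts are resolved
by rounding half up toward the proximal isomer — a deterministic, auditable
default — with a seeded coin flip available (`rounding_policy = "random"`).
Double-PUFA species map to a single product carrying the distal isomer at
sn-1 and the proximal at sn-2 (13/9, 15/12, 17/14), matching how
sn1/sn2-resolved hydroperoxide tables are reported. Oxidized double-bond
patterns use the primary trans-cis isomers (e.g. 9-OOH with 10E,12Z); where
published sources disagree internally on the 14/17-HPDHA patterns, the
assignment with the conjugated E bond adjacent to the OOH carbon is used.

`place_toy_coordinates()` is marker-resolution only (phosphate or
cholesterol-O3, carbonyl, mid-chain, terminal-methyl markers on a jittered
lattice honouring a 0.2 nm assembly tolerance). It generates valid,
collision-free coordinate files for I/O and geometry testing; atomistic
packing belongs to a packing engine and is out of scope.

## Trajectory I/O

GRO (fixed-width, nm-native) is parsed and written directly. PDB goes
through `bio3d`, with Å→nm conversion; PDB residue-name columns hold three
characters, so species codes ride in a JSON metadata sidecar
(`<file>.meta.json`) together with leaflet tags, and are merged back on
read. Binary trajectories use a self-contained CHARMM-style DCD codec
(Fortran sequential records, float32 coordinates in Å, unit-cell records);
the frame spacing in ps is stored in the header's delta slot so times
survive a round trip. The test suite cross-checks the codec against
`bio3d::read.dcd`. XTC's XDR compression is not implemented; requesting it
raises an explicit error. Boxes are orthorhombic only — membrane boxes in
this workflow are — and triclinic input is rejected, never silently
mangled. Coordinates are stored wrapped; unwrapping is an explicit
operation in the dynamics stage, never implicit.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of (parameters, seed) and attaches a
`synthetic_truth` object. They emulate the *statistical* structure the
estimators consume:

- `gen_layered_bilayer()`: component z-positions as leaflet-mirrored
  Gaussians (phosphates at ±z_P, carbonyls nearer the center, methyls about
  it), waters uniform outside an exclusion slab. Frames are independent
  draws.
- `gen_ordered_chains()`: all-trans carbon skeletons (every skeletal
  C(j−1)→C(j+1) axis parallel to the chain axis) tilted by a chosen angle
  about a random azimuth, optional ±120° gauche defects, or fully isotropic
  orientations. With zero gauche fraction and tilt t the order parameter is
  (3 cos²t − 1)/2 *exactly*, giving machine-precision oracles.
- `gen_brownian_membrane()`: independent 2-D Gaussian walks per lipid with
  per-axis step variance 2 D Δt, plus a shared per-leaflet drift; z fixed.
  D = 0 is allowed (a frozen membrane is a legitimate degenerate case for
  drift-removal tests); negative D is an error.
- `gen_umbrella_samples()`: exact biased Boltzmann sampling per window by
  inverse-CDF on a 10⁴-point grid — rejection-free and reproducible — with
  the exact biased densities retained for oracle comparisons.
- `gen_force_series()`: stationary Ornstein–Uhlenbeck series with
  autocovariance σ²e^(−t/τ) and σ²τ = (RT)²/D, the identity the
  force-autocorrelation estimator inverts. Series with τ ≤ 2Δt are rejected
  as under-resolved.

What they do **not** emulate: inter-lipid forces, correlated motions,
area/volume coupling, anomalous subdiffusion at short times, chain
isomerization kinetics, or electrostatics. Passing tests therefore
demonstrate estimator correctness (unbiasedness, unit handling, parameter
recovery at known truth), not force-field realism; conclusions about real
membranes still require real trajectories.

Temperatures follow the two-temperature convention of membrane permeation
studies: 310 K (RT = 2.577 kJ/mol) for trajectory-scale generators, 298 K
(RT = 2.478 kJ/mol) for the permeability stack, both overridable. The gas
constant is 8.314 J mol⁻¹ K⁻¹.

## Structural observables

Density profiles recenter every frame on the membrane center of mass
(non-water atoms by default) and average mass histograms; the default bin
width is 0.05 nm, and 1 amu/nm³ = 1.66054 kg/m³. Because the inner leaflet
carries more lipids than the outer, the COM-centered per-leaflet peak
positions are slightly asymmetric; the peak-to-peak thickness is unaffected.
Peaks are localized by a 3-point parabolic fit of the 3-bin-smoothed
maximum per half-space — sub-bin accuracy is needed because the head-group
shifts of interest are 0.1–0.2 nm, only 2–4 bins.

S_CD uses the skeletal-vector definition (the C(j−1)→C(j+1) axis against
the z normal), deliberately not the C–H-vector variant many tools default
to; the two differ for tilted all-trans segments, and the skeletal form is
what the tilt oracles above validate. Terminal carbons have no skeletal
axis and are excluded rather than erroneous. Per-chain averages are
available with and without the carbonyl-adjacent carbon (j = 2), since both
conventions appear in published tables.

The angle set measures α (P→terminal-methyl vs normal), β (splay between
the two chains), γ (interior angle at a mid-chain pivot; a straight chain
scores 180°, consistent with reported mean values of ~116–150°), δ
(P→segment-carbon vs normal) and α3 (cholesterol ring axis vs normal,
defined O3-carbon→C17 since no published definition exists — a logged
choice). α and δ are measured against the per-leaflet *outward-to-inward*
normal so that 0° means "pointing into the core" in both leaflets. The two
sn-2 variants (γ2_1/γ2_2, δ2_1/δ2_2) are distinguished only by which
oxidation-prone pivot carbon they use (first vs second position, e.g. C9 vs
C13 on linoleate); published definitions are textually identical for the
two, so this pivot parameterization is a documented interpretation, and the
pivot atoms are supplied explicitly by the caller through the marker table.

Leaflet assignment is by phosphate (or cholesterol-O3) z relative to the
membrane COM, fixed per lipid for an analysis — lipid flip-flop is not
expected at the trajectory lengths this pipeline targets.

## Hydrogen bonds

Detection is geometric: donor–acceptor distance ≤ 0.35 nm and H–D···A angle
≤ 30°, the de-facto standard in MD tooling, adopted because the source
analyses state no criteria; both knobs are exposed. Distances are
minimum-image. Rates are bonds per frame normalized per group instance.
An OOH group acts as both donor (its O–H) and acceptor (both oxygens) when
the caller builds selections that way; "total" columns in published rate
tables are interpreted as total-to-lipid (rows where the total is smaller
than the water column rule out total-to-everything), and since both
readouts are trivially constructible from partner classes, both remain
available.

## Lateral diffusion

Unwrapped per-lipid xy COM tracks are corrected by removing the
whole-membrane COM displacement first and the per-leaflet residual second
(the order is recorded in the result; the net effect equals leaflet-COM
removal when masses are uniform). The time-averaged MSD uses the FFT
decomposition (O(T log T)); a naive O(T²) estimator is kept as an in-package
reference and the two agree to numerical precision. The default lag
schedule stops at 5% of the trajectory length and the default fit window is
10–50% of the maximum lag: time-averaged MSD values at long lags have few
independent origin pairs and large variance, so fitting the early diffusive
regime is both statistically optimal for pure Brownian motion and
consistent with how short-lag fits are done in practice; both knobs are
arguments. D is reported per species/leaflet as the pooled-ensemble fit
(the headline value) and as mean ± SD across per-lipid fits — individual
lipid estimates scatter widely even for identical species, so the SD is
reported rather than hidden. Negative estimates are flagged, never clipped.

## WHAM, D(z) and permeability

The umbrella schedule defaults to the canonical pull: 40 windows 0.2 nm
apart from z = +4 nm (outer aqueous phase) toward −4 nm, half-open count
convention (centers 4.0, 3.8, …, −3.8), k = 100 kJ mol⁻¹ nm⁻². Each
window's leading fraction (default one half) can be discarded as
equilibration with `equilibration_trim()`.

WHAM iterates p(z) ∝ Σᵢ nᵢ(z) / Σᵢ Nᵢ fᵢ⁻¹ e^(−Uᵢ(z)/kT) with
fᵢ⁻¹ = Σ_z p(z) e^(−Uᵢ(z)/kT), until the largest change in any window free
energy −kT ln fᵢ drops below 10⁻⁶ kJ/mol (configurable); non-convergence and
adjacent-window histogram gaps are errors, not warnings. Numerical choices:
bin width 0.05 nm; bins with fewer than 10 total samples are treated as
unsampled and dropped (never interpolated) — a handful of counts carries no
usable free-energy information; and the reported grid is clipped to the
scheduled window span, because bins beyond the outermost centers are reached
only through the end windows' bias tails and are ill-conditioned. The
profile is anchored to zero over the outermost 0.5 nm plateau on the
starting (bulk-water) side; `anchor = "min"` is available. No symmetrization
is applied by default — these membranes are leaflet-asymmetric — though the
barrier is reported against both conventions (`pmf_barrier()`: vs bulk and
vs the interfacial minimum, since published barrier figures are ambiguous
between the two).

D(z) comes from the force-autocorrelation identity
D = (RT)²/∫₀^∞⟨δF(t)δF(0)⟩dt, with the integral truncated at the first zero
crossing of the FFT-computed autocovariance (exponential-tail fitting is the
alternative policy); series whose correlation collapses within a few samples
are rejected as under-resolved. The permeability integral
P = [∫ e^(ΔG/RT)/D(z) dz]⁻¹ is trapezoidal on the PMF grid with D
interpolated onto it (nearest-value extrapolation at the edges, where D
plateaus in bulk water), converted via 1 nm/ps = 10⁵ cm/s. T = 298 K is the
default for the exp(ΔG/RT) weight — the convention permeability
coefficients are usually quoted at — even when trajectories are generated
at 310 K; the temperature is an explicit argument precisely because the two
conventions coexist in the literature.

## Validation strategy and problem sizes

The full MD observables of real oxidized membranes (absolute thickness
values, order-parameter tables, per-species diffusion constants, tens of
kJ/mol barriers) require hundreds of ns of all-atom trajectory and are not
reproducible at package-test scale. The test suite therefore validates (a)
the composition model exactly against its published constraints, and (b)
every estimator by parameter recovery on synthetic truth: analytic S_CD
values to 10⁻¹², thickness to one bin width at phosphate layers placed
4.52 / 4.20 nm apart, Brownian D ∈ {0.5, 2, 5} µm²/s recovered within 5%
(100 lipids × 10⁴ frames under imposed leaflet drift), WHAM within
0.5 kJ/mol (max over the anchored grid) at 5×10⁴ samples per window on a
20 kJ/mol two-well curve, flat-profile permeability exact (P = D/L), a
square-barrier closed form to <1%, and the full synthetic
truth → windows → WHAM → D(z) → P chain within 10% of direct quadrature.
Hydrogen-bond detection is checked against a brute-force O(N²) oracle and
planted fixtures. These sizes keep the whole suite within a few minutes on
one CPU while leaving each statistical tolerance at ≥3 standard errors.

## Known limitations

- Orthorhombic boxes only; no triclinic PBC math.
- No XTC codec; DCD (and text GRO) carry binary/trajectory data.
- Marker-level coordinate generation only; no atomistic rebuilding.
- Geometric H-bond definition only; no energetic definitions or lifetime
  kinetics.
- MSD analysis assumes normal diffusion; anomalous-exponent fitting is out
  of scope, as are protein-crowding effects (the models are protein-free
  membrane domains).
- WHAM only; MBAR is not implemented.
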