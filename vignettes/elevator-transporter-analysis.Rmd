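---
title: "Methods: quantifying elevator-transporter conformations, interfaces, membrane bending and blocker binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying elevator-transporter conformations, interfaces, membrane bending and blocker binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevatorEM)
```

# Scope and model

Elevator-type glutamate transporters are homotrimers whose peripheral
transport domain moves as a quasi-rigid body against a static scaffold
(trimerization) domain, both across the membrane (substrate translocation)
and within the inward-facing state (gating). `elevatorEM` treats each
protomer as two rigid domains defined by a residue-range partition and
reduces a set of structures to a small table of geometric, surface-area,
membrane-deformation and binding quantities. The package computes; it does
not refine, morph or simulate.

## The domain partition

All selections are driven by a `domain_partition`: six named residue-range
sets (`scaffold`, `transport`, `hp1`, `hp2`, `tm8a`, `hp2_tm8a_motif`) plus
labelled reference residues (the HP1/HP2 tip residues used for the gating
distance, the extracellular anchor H37, the crosslink sites, the
N-terminal-helix range). Ranges use author numbering, inclusive at both
ends, because every residue discussed in the transporter literature is
referenced that way. The packaged GltPh partition is *curator-derived* from
the secondary-structure annotation of the deposited models — the boundaries
are not printed anywhere authoritative — so it ships as data
(`inst/extdata/gltph_partition.yaml`), is validated on load (non-overlap,
HP2 and HP2/TM8a contained in the transport domain, references resolvable)
and can be replaced per run. Loop-level boundary changes move the tilt and
interface numbers by a degree or a few percent; this sensitivity is the
reason the comparisons against deposited entries carry ±3° and ±15%
tolerances. One deliberate validation exception: the N-terminal amphipathic
helix precedes TM1 and therefore lies *outside* all six sets; the
containment check applies to the scalar references only.

## Membrane frame and conformational metrics

The membrane normal is not taken from any annotation: it is the three-fold
symmetry axis, extracted as the rotation axis of the optimal rigid (Kabsch,
SVD-based) superposition of one protomer's scaffold Cα onto the next
protomer's. A rotation angle deviating more than 15° from 120° aborts with
a symmetry error rather than returning a meaningless axis. The frame center
is the query protomer's scaffold Cα centroid, and the normal is oriented
extracellular using the HP2/TM8a motif centroid as a marker. For
single-protomer depositions (C1-refined protomers carry no symmetry axis)
the frame is inherited from a designated trimeric reference after scaffold
superposition.

- **Tilt (α₁)** is the angle between the transport-domain principal axis
  (smallest inertia moment of the Cα cloud — the long axis of the roughly
  cylindrical domain) and the normal, folded into [0°, 90°] since all
  reported tilts are acute. The default selection *includes* HP2, matching
  the whole-domain axis the study depicts; `exclude_hp2 = TRUE` is offered
  for sensitivity analysis.
- **Rotation (α₂)** between two states superposes state B's scaffold onto
  state A's, then extracts the optimal rigid transform carrying A's
  transport Cα onto B's; `α₂ = arccos((tr R − 1)/2)`. At exactly 180° the
  axis is undefined and flagged. Only residues resolved in both states (by
  author number) enter either superposition: unresolved residues shrink the
  comparison (with a message and a reported count), never abort it, down to
  a floor of 20 shared Cα.
- **RMSD** is all-shared-Cα after superposition on the same selection. The
  study does not state its superposition selection; all-Cα is the default
  and scaffold-only is available by passing that range set.
- **Translocation** is `(COM_B − COM_A) · n` of the transport-domain Cα
  after scaffold superposition; negative is cytoplasmic.
- Only Cα atoms enter axes, superpositions, centers of mass and RMSDs —
  sidechain disorder in 3–4 Å maps would otherwise dominate.

Numerically, the angle of a near-identity rotation is ill-conditioned
through `acos` (resolution ~`sqrt(.Machine$double.eps)` rad); the axis is
taken from the skew part of `R` and marked undefined when that part is at
machine epsilon, and self-comparisons report ~1e-6 degrees rather than an
exact zero.

## Surface areas and the domain interface

The buried interface between the HP2/TM8a motif and the scaffold uses an
in-package Shrake–Rupley SASA: a deterministic, seed-free Fibonacci spiral
lattice (default 960 points — common practice, and the lattice noise at 960
points is below 0.5% under rigid rotations), probe 1.4 Å, Chothia-type
heavy-atom radii from a packaged table (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å; unknown elements fall back to 1.70 Å with a warning). Hydrogens
are ignored; heteroatoms are excluded by default because the interface of
interest is protein–protein. The interface area is the PISA half-buried
convention `(SASA_A + SASA_B − SASA_AB)/2`, each term evaluated with only
the two sets present; whether the published areas used half- or full-buried
is not stated, so the full value (exactly 2×) is one flag away and the
deposited-entry tolerance is ±15%, which also absorbs the unrecoverable
radii set of the original PISA computation. The implementation is verified
against the closed form for one and two spheres, a dense random-lattice
brute force, and an independent published implementation (agreement within
2%).

## Nanodisc deformation maps

The membrane-bending analysis turns a 3-D density map into a 2-D height
field:

1. **Segmentation** — a voxel is nanodisc iff its value is at least
   `threshold_sigma` map standard deviations (computed over
   protein-masked voxels; default 1.0 σ since no contour level is
   published), farther than `protein_mask_radius` (default 4 Å) from every
   model atom, and within `slab_half_width` (default 25 Å, a typical
   bilayer-plus-headgroup extent) of the frame center along the normal.
   A contrast-free or over-thresholded map errors out rather than
   returning an empty field.
2. **Leaflet surface** — the segmented map is resampled by trilinear
   interpolation onto an in-plane grid in the membrane frame (spacing =
   smallest voxel; deterministic and convention-free). Per column, the
   *outermost* threshold crossing on the requested side is taken — the
   surface of the density, not a density-weighted centroid — and refined
   sub-voxel by linear interpolation of the 0.5-occupancy crossing.
3. **Zero level** — the mean surface height over an annulus (default
   0–8 Å) around the projected reference Cα: H37 for extracellular views,
   the N-terminal helix for cytoplasmic views. Displacement is height
   minus zero level; with the normal pointing extracellular, negative
   values mean inward bending on the extracellular side and outward
   bending on the cytoplasmic side — the two sides' reporting conventions.
4. **Extremum** — the signed displacement of largest magnitude in a
   region, typically a disc (default radius 15 Å) around the projected
   transport-domain centroid.

Resolution behavior is checked by construction: on synthetic slabs the RMS
surface error at least halves when the voxel size halves, and planted
deflections of 0–8 Å are recovered within 0.5 Å plus half a voxel.

## ITC: independent identical sites

The bound-titrant concentration is the stable closed-form root of the
mass-action quadratic, `2 n Mt Xt / (s + sqrt(s² − 4 n Mt Xt))` with
`s = n Mt + Xt + K_D`. Forward simulation uses perfusion-cell
(displacement-dilution) accounting — each injection of volume `v` dilutes
the cell contents by `1 − v/V₀` — because that is what commercial
instruments assume; the default cell volume is 185 µL. Heats are in µcal
and molar enthalpies in cal/mol (× 4.184 for J). One measurable
consequence of displacement dilution: the *total* heat of a titration
depends on the injection granularity at second order in `v/V₀` (~0.3% for
2 µL into 185 µL), so splitting injections conserves total heat only to
first order — the property the tests assert.

Fitting profiles the linearly-entering parameters (ΔH and the per-injection
baseline) out exactly by least squares at each candidate `(n, log₁₀ K_D)`,
and searches the remaining two by Nelder–Mead from a deterministic
multi-start grid (K_D log-spaced 10⁻⁹–10⁻³ M × n ∈ {0.5, 1, 2}). A fit is
`converged` only when the optimizer succeeded *and* the residual sum of
squares improves at least two-fold on a flat-baseline model, so pure-noise
or constant heat vectors are flagged rather than fitted. Identifiability is
reported through the Wiseman parameter `c = n·[M]/K_D`: below `c = 0.5`
the isotherm is essentially featureless in `n` and the fit carries an
`n_poorly_determined` flag (a threshold diagnostic; the package does not
bootstrap). The first injection is kept by default — common practice
discards it, so `exclude_first` removes its residual while preserving its
effect on the cell contents.

On the study's design (40 µM cell, 400 µM syringe, 25 × 2 µL, 15 °C)
noiseless round trips recover `n`, `K_D` (3.8 and 6.5 µM) and ΔH within
1%, and with 2% Gaussian heat noise at `c ≈ 10` the least-squares estimator
sits on the Cramér–Rao bound for this design (median K_D error ≈ 8.4%,
verified over 200 seeded replicates).

# What the synthetic generators emulate — and what they do not

- `make_two_domain_toy` builds Cα-only helical cylinders (radius 4–5 Å,
  ~40 Å long, 100 points — enough for stable inertia axes) and plants
  tilt, an oblique-axis rotation about the transport centroid, and a
  normal-direction shift as exact rigid transforms. Because the planted
  quantities are the definitions of the measured ones, recovery is exact
  up to the inertia-axis discretization (<0.01° here). Real protomers are
  not rigid: hairpin restructuring, partial disorder and boundary
  ambiguity are absent from the toys, which is precisely why the
  deposited-entry comparisons carry wider tolerances than the synthetic
  ones.
- `make_toy_trimer` applies exact 120° copies, so the three-fold axis
  extraction is tested against a perfect symmetry; real C1 reconstructions
  deviate by fractions of a degree, absorbed by the 15° symmetry guard.
- `make_slab_density` builds a uniform slab with antialiased faces and a
  Gaussian deflection of both faces toward the stated side — a bending
  deformation, matching how a bilayer accommodates a protruding domain
  (the planted depth appears with the side's sign convention on both
  leaflets). It does not emulate leaflet-thickness changes, scattering
  falloff, the MSP belt, or map sharpening; the deposited-map comparison
  defaults to the primary deposited map since the study does not say
  whether its figures used sharpened maps.
- `make_itc_isotherm` adds seeded Gaussian noise to the simulated heats;
  real baselines drift and first injections under-deliver, which the
  generator does not model (the `exclude_first` option exists for the
  latter).

All generators are pure functions of their arguments and seed; randomness
goes through one seeded stream that is restored afterwards, so generation
never perturbs a caller's RNG state.

# Problem sizes and determinism

The shipped tests run entirely on generated fixtures: toys of 200 Cα
atoms, slabs of ~60–80³ voxels, titrations of 25 injections, and 200
replicate noisy fits — a few tens of seconds in total. The batch pipeline
(`analyze_states`) sorts rows by entry label and protomer, echoes every
parameter into a manifest, marks failing entries instead of aborting the
run, and reruns byte-identically from the same config.

# Known limitations

- Domain boundaries are data, not ground truth; all deposited-entry
  comparisons inherit their uncertainty.
- The SASA radii set and buried-area convention of the original interface
  numbers are unrecoverable; both conventions are exposed and the
  tolerance widened accordingly.
- The deformation analysis assumes the map and model share a coordinate
  frame (true for deposited pairs) and reports surface geometry only — no
  bending-energy estimates, leaflet thickness or lipid order.
- Single-site ITC only: no sequential or multi-site models, no raw-power
  baseline integration, and the low-`c` flag is a Wiseman-parameter
  threshold rather than a bootstrap interval.
- Structures are compared per protomer; the package does not decide for
  the user which protomer of a C1 reconstruction corresponds to a
  published panel (the pipeline reports all, plus their mean when
  aggregated downstream).
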