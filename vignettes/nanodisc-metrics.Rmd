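---
title: "Measuring nanodisc effects on a pentameric channel: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nanodisc effects on a pentameric channel: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discmetrics)
```

This vignette documents the models, conventions and numerical choices
behind each measurement family, what the synthetic generators emulate,
and where the package's guarantees end. Lengths are Angstrom internally
throughout; nanometres appear only at report boundaries (map diameters).
Residues are keyed by author numbering, because that is how structural
work names positions (the transmembrane domain spans residues 201–322 in
the channel these defaults were chosen for; the pore-lining helix M2 and
the lipid-facing helix M4 sit inside it, the agonist-binding
extracellular domain below residue 201).

## Pore axis

All distances, tilts and polar bins are referenced to the channel's
five-fold symmetry axis. Rather than relying on an external orientation
service, the axis is defined intrinsically: the three principal
directions of the pore-lining Cα cloud are candidate axes, and the
chosen one maximises C5 rotational self-agreement — the mean
nearest-neighbour distance between the cloud and its own copy rotated
by 72° about the candidate, through the selection centroid. For any
plausibly pentameric input the symmetry axis wins this comparison by a
large margin; fewer than three represented chains is a symmetry error,
a collinear cloud a geometry error. The direction is canonically
oriented (toward the extracellular side) against a reference vector so
that signed rotations are well defined.

## Helix tilt

The tilt of a helix against the pore axis is `acos(|h·d|)`, with `h` the
helix axis estimated per subunit. A subtlety dictated the estimator: the
Cα trace of a finite α-helix (1.5 Å rise, 100° per residue) is a coil
whose phase is *correlated* with the axial coordinate, so the dominant
principal component of the raw Cα cloud is biased away from the true
axis — by more than a degree for an 18-residue helix with a 2.3 Å coil
radius. The package therefore smooths the trace over approximately one
helical turn (two passes of a 4-point moving average, suppressing the
coil amplitude by a factor of ~60) before taking the principal
direction. With that choice, tilt recovery on ideal-helix fixtures is
accurate to ~0.02°, and reversing the residue order leaves the angle
unchanged (the axis is oriented N→C only to fix a sign). Traces with
fewer than 12 Cα fall back to single smoothing, below 8 to the raw
cloud; fewer than 5 Cα is an error, as is a cloud without a dominant
direction (first-to-second principal spread ratio below 1.5).

## Domain rotation

Agonist binding rotates the extracellular domain (ECD) relative to the
transmembrane domain (TMD). The package reports this as follows: the
second structure is superposed onto the first by least squares (Kabsch,
proper rotation enforced) over TMD Cα; the residual best rotation over
ECD Cα is then decomposed by the quaternion swing–twist construction
about the pore axis, and the twist component is reported as a signed
angle — positive counter-clockwise viewed from the extracellular side,
which with the canonical axis orientation is the plain right-hand rule.
The axial twist rather than the total rotation angle is the default
scalar because "rotation relative to the TMD" describes motion about
the channel axis; both are returned. Constructed ground truth (an ECD
twisted by a known angle about the axis) is recovered to well under
0.05°, and swapping the two structures negates the angle.

## Pore radius profile

At each axial sample the accessible radius is the minimum over atoms in
a slab of half-width `step/2` of (distance to the axis − element vdW
radius), clamped at zero, with the minimising atom's residue reported as
pore-lining. This is a deliberate, cheap contract — a slab minimum, not
a Monte-Carlo probe fit; it cannot thread side-chain gaps the way a
rolling-sphere method can, and empty slabs are flagged undefined rather
than interpolated. The bundled radii are Bondi-style values (C 1.70,
N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å; 1.70 for unknown elements) and
the table is replaceable, since no single published set is canonical.

## Membrane thickness

Thickness fields follow the instantaneous-midplane convention: per
frame, the midplane is the mean z of all lipid phosphorus atoms, each
lipid joins the upper or lower leaflet by its phosphorus height, and the
per-bin thickness is the mean height of upper lipids minus that of lower
lipids. Two markers are supported: the phosphate itself (overall
thickness) and the geometric centre of the glycerol backbone
(hydrophobic thickness; atoms C1, C2, C3, O21, O31 by default — the
name list is configurable because force fields differ). Binning is by
the smallest distance between the lipid's phosphorus and any TMD
backbone atom, in half-open 3 Å bins (last bin closed), or by polar
(r, θ) cells of 5 Å × π/15 about the pore axis with θ measured from +x.
Per-frame thicknesses are averaged across frames (mean ± SD); the
alternative order — averaging leaflet heights across frames first — is
exposed as a flag but is not the default. Empty bins are reported as
missing values with `n_obs = 0`, never as zeros, so plots can break
lines honestly.

Two loud caveats. First, no periodic-boundary imaging is applied:
nanodisc systems are finite, and planar-bilayer input must be
pre-imaged. Second, frames are assumed already aligned on the TMD; the
package provides `superpose()`/`apply_transform()` for that but does not
align implicitly.

## Contacts and partner types

A protein residue contacts the scaffold in a frame iff any of its atoms
is within the cutoff (inclusive ≤ 4.5 Å — boundary conventions decide
figure membership near thresholds, so they are stated) of any scaffold
atom. Probabilities are fractions of analysed frames; the trailing
window (250 ns) and sampling stride (200 ps) are parameters. The
high-contact rule is strict (> 0.25), so a probability of exactly 25 %
is excluded. Partner ratios count (frame, scaffold-residue) events —
one event per frame per scaffold residue regardless of how many atom
pairs qualify — normalised over the classes nonpolar
{G,A,V,L,I,P,M,C}, polar {S,T,N,Q}, charged {D,E,K,R,H}, aromatic
{F,Y,W}; histidine counts as charged. The partition is configurable and
documented as a choice, not a reproduction claim. Contact detection
uses a cell list over scaffold atoms with the same squared-distance
arithmetic as a naive all-pairs scan, and the tests require *exact*
equality with an independent naive implementation.

## Ellipse of best fit and disc diameter

Scaffold shape uses the direct least-squares conic fit with the
ellipse-specific constraint 4ac − b² = 1, solved by the partitioned
eigen-decomposition after centring/scaling for conditioning. The
constraint guarantees an elliptical solution and the method is
deterministic and exact on noiseless input (noiseless fixtures recover
axes and orientation to 1e-6; 1 Å isotropic noise on 200 points leaves
the mean axis error under 0.1 Å). The residual is the RMS Sampson
(gradient-normalised algebraic) distance. Both scaffold chains are fit
with a single ellipse, projected onto the plane perpendicular to the
pore axis; major/minor diameters 2a, 2b are recorded per frame, with
mean ± SD over the trailing window. When the semi-major axis oscillates
sinusoidally the series reproduces the closed-form mean and SD — note
the fitted labels swap if the "major" axis dips below the fixed minor
axis, so breathing fixtures keep `a − amp > b`.

## Density-map diameter

Maps are low-pass filtered in Fourier space with a raised-cosine edge
one reciprocal voxel wide beyond the cutoff frequency `1/resolution`;
the DC term is untouched, so the mean is preserved exactly. The soft
edge avoids the ringing a hard cutoff produces, which would shift
σ-contours; the price is that repeat filtering is only band-wise
idempotent — frequencies fully inside the pass or stop band are
reproduced exactly on a second pass, while content in the narrow cosine
edge is re-attenuated (a few percent of the value range on broadband
maps). The diameter protocol thresholds the filtered map at
mean + 1σ (σ over *all* voxels — the population is configurable),
restricts to an axial slab at membrane height (default ±15 Å around the
axial density maximum, where nanodisc density is widest), takes the
largest 6-connected above-threshold component, and reports the maximal
extent of the component's voxel centres over in-plane directions, in
nm. This automates what is traditionally a manual caliper measurement
at a displayed contour; comparisons against manually measured values
should carry a ±0.3 nm tolerance on top of the ±1 voxel the tests
enforce on synthetic discs.

## Synthetic generators

The generators produce every input class with analytic ground truth and
a seeded local RNG stream (bit-identical reruns; the caller's RNG state
is untouched).

- `make_toy_pentamer()`: five chains related by exact 72° rotations;
  per chain an M2-like and an M4-like ideal helix (Cα only; 18 residues
  by default — five exact turns, which makes phase coverage uniform)
  at configurable ring radii and radial tilts, and an ECD pseudo-atom
  blob twisted about the axis by a known angle. Helices occupy residues
  230–247 and 305–322, the ECD 50–79, so the default TMD/ECD split
  applies unchanged.
- `make_toy_bilayer_series()`: lipids uniform in the annulus between a
  rigid cylindrical backbone inclusion and the rim; phosphate heights
  ± thickness(d)/2 where d is the same minimum phosphorus-to-backbone
  distance the analysis bins on (evaluated by two fixed-point
  iterations, since the height feeds back weakly into the distance);
  glycerol centres exactly 4 Å inside the phosphate heights. With zero
  noise the constant-thickness fixture reproduces 38.6 Å in every bin
  with zero SD, and a radially thinning field is recovered at bin
  centres to well under 0.3 Å at 500+ lipids.
- `make_toy_scaffold_series()`: a belt of backbone-like points on a
  (possibly breathing) ellipse split over two chains, a small spread-out
  protein, and scripted partner residues placed inside the contact
  cutoff in exactly the scripted frames.
- `make_toy_density_map()`: a solid disc of known radius and height,
  optional denser central cylinder, flat background, optional Gaussian
  noise, grid centred on the origin.

What the fixtures deliberately omit: any physics. There are no sterics,
no force field, no lipid diffusion, no conformational ensembles; lipid
positions are static up to scripted jitter and scaffolds breathe as
pure sinusoids. Passing tests therefore demonstrate that the
*measurements* are correct and self-consistent — binning conventions,
symmetry handling, thresholds, frame windows — not that the package's
defaults are optimal for any particular real system. On real
trajectories the user still owns alignment, imaging and the choice of
selections.

## Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: pentamers
of ~330 atoms, bilayers of 500–600 lipids over a handful of frames,
100-frame contact scripts, 200-frame breathing series, and 64³ voxel
maps; the full suite runs in about half a minute and the acceptance
script in seconds. All stochastic checks fix seeds explicitly; CSV
output uses 6 significant digits so repeated runs are byte-identical.

## Known limitations

- The mmCIF writer emits a minimal canonical `atom_site` loop (no
  entities, no assemblies); it exists to round-trip coordinates.
- MRC support is MRC2014 mode-2 (32-bit float) with axis
  canonicalisation; other modes are rejected rather than guessed.
- The pore profile is a slab minimum, not a probe fit (see above).
- `measure_disc_diameter()` assumes the disc is the dominant
  above-threshold feature in the slab; heavy noise floors that lift the
  background above mean + 1σ will fragment the component and are the
  user's responsibility to filter first.
- The M4 tilt residue window is configurable and defaults to the
  resolved span 305–322; published figure captions sometimes reference
  residue numbers outside the modelled range, so no attempt is made to
  guess a different window.
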