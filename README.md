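# discmetrics

Structural measurements for membrane proteins in lipid nanodiscs, built
around the comparisons used for pentameric ligand-gated ion channels
(pLGICs): how helix geometry, domain rotation, the surrounding bilayer,
and the scaffold belt itself change with the nanodisc environment.

Nanodiscs — lipid-bilayer patches encircled by a membrane scaffold
protein (MSP) belt, a saposin shell, or an SMA polymer — are the standard
vehicle for cryo-EM of membrane proteins, but the scaffold constrains the
membrane and can bias the protein's conformation. Quantifying that bias
needs a consistent set of measurements across structures, MD
trajectories, and density maps. This package implements them:

- **Pore-axis geometry.** The C5 symmetry axis is determined
  intrinsically from the pore-lining Cα cloud (the principal direction
  maximising five-fold rotational self-agreement). Against it the package
  reports per-residue Cα–axis distances (mean ± SD across the five
  subunits), helix tilt angles `acos(|h·d|)` from turn-smoothed principal
  axes, and a slab-minimum pore radius profile
  `r(z) = min_atoms (d_axis − r_vdW)`.
- **Domain rotation.** After least-squares (Kabsch) superposition on
  transmembrane-domain Cα (residues 201–322 by default), the residual
  best rotation of the extracellular domain is decomposed (swing–twist)
  about the pore axis into a signed twist angle; positive is
  counter-clockwise viewed from the extracellular side.
- **Membrane thickness fields.** Per frame, the instantaneous midplane is
  the mean z of all lipid phosphorus atoms; leaflets are assigned by
  phosphorus height; lipids are binned by the smallest distance from
  their phosphorus to any transmembrane backbone atom (0.3 nm bins) or by
  polar coordinates about the pore (5 Å × π/15 rad cells); thickness is
  the difference of mean leaflet heights, using the phosphate (overall)
  or the glycerol-centre (hydrophobic) marker.
- **Scaffold contacts.** A protein residue is in contact in a frame iff
  any of its atoms is within 4.5 Å (inclusive) of any scaffold atom;
  probabilities are fractions of frames in a trailing window (250 ns at
  200 ps sampling by convention), with a strict >25 % high-contact rule
  and residue-type ratios (nonpolar/polar/charged/aromatic) of the
  scaffold partners.
- **Nanodisc shape and size.** Direct least-squares ellipse fits
  (constraint 4ac − b² = 1) of the scaffold backbone projected onto the
  membrane plane give major/minor diameter time series; cryo-EM maps are
  Fourier low-pass filtered (8 Å, raised-cosine edge) and the disc
  diameter is measured at a 1σ contour as the maximal in-plane extent of
  the largest connected component.

Everything is exercised end-to-end on seeded synthetic generators with
analytic ground truth: a C5 pentamer with parameterisable helix tilts and
domain twist, a finite disc bilayer with a configurable radial thickness
function, a breathing elliptical scaffold belt with scripted contact
events, and voxel maps with known disc radius.

## Worked example

```r
library(discmetrics)

apo   <- make_toy_pentamer(tilt_m4 = 12, ecd_twist = 0,   seed = 42)
bound <- make_toy_pentamer(tilt_m4 = 14, ecd_twist = 1.5, seed = 42)

axis <- compute_pore_axis(apo, select_atoms(apo, "calpha and resid 230:247"))
axis
#> <pore_axis> origin (-0.00, 0.00, -17.00), direction (0.000, 0.000, 1.000)

helix_tilt_angle(bound, select_atoms(bound, "calpha and resid 305:322"), axis)
#> <helix_tilt> mean 14.02 deg (SD 0.00) over 5 subunits

ecd_rotation_angle(apo, bound)
#> <ecd_rotation> axial twist +1.506 deg (total 1.506 deg), TMD rmsd 0.196 A
```

The lipid-facing helix tilt (14°) and the extracellular-domain twist
(+1.5°, counter-clockwise from the extracellular side) are the generator
inputs, recovered by the measurements; the 0.2 Å TMD rmsd reflects the
deliberate 12° vs 14° tilt difference between the two structures.

```r
fs <- make_toy_bilayer_series(n_lipids = 500,
                              thickness_fn = function(d) 38 - 6 * exp(-d / 10),
                              n_frames = 3, seed = 1)
pr <- thickness_vs_distance(fs,
        select_atoms(fs$topology, "backbone and resid 201:322"),
        select_atoms(fs$topology, "resname POPC"), r_max = 34.5)
head(as.data.frame(pr)[, 1:5], 4)
#>   bin_lo_A bin_hi_A   mean_A sd_A n_obs
#> 1        0        3 32.65718    0    30
#> 2        3        6 34.15735    0    78
#> 3        6        9 35.16124    0   114
#> 4        9       12 35.88040    0   114

dm <- make_toy_density_map(disc_radius = 45, seed = 1)
measure_disc_diameter(lowpass_filter(dm, 8))
#> <disc_diameter> 8.98 nm at 1-sigma contour (threshold 0.4557, 14160 voxels)
```

The binned thickness tracks the generating function
`38 − 6·exp(−d/10)` at the bin centres (32.8 Å at 1.5 Å, rising toward
38 Å), and the 45 Å synthetic disc reads back as 9.0 nm to within a
voxel.

For shell use, `inst/scripts/discmetrics` wraps the four pipeline
commands (`structure`, `membrane`, `scaffold`, `mapdiam`) around a YAML
config; outputs are stable CSV/JSON reports with a verbatim config echo.

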