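Package: discmetrics
Title: Structural Metrics for Membrane Proteins in Lipid Nanodiscs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative structural measurements for comparing a pentameric
    ligand-gated ion channel across lipid-nanodisc environments: pore-axis
    determination and helix geometry (per-residue distance to the pore axis,
    helix tilt angles, TMD-anchored superposition and extracellular-domain
    rotation, pore radius profiles), bilayer leaflet assignment and membrane
    thickness fields (radial and two-dimensional polar binning), protein to
    scaffold contact probabilities with partner residue-type ratios, direct
    least-squares ellipse fitting of the scaffold belt with diameter time
    series, and nanodisc diameter measurement on cryo-EM density maps via
    Fourier low-pass filtering and sigma-contour thresholding. Includes
    deterministic synthetic-data generators (pentamer structures, bilayer
    trajectories, scaffold rings, voxel maps) with analytically known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
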