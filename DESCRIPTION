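Package: spatialcells3d
Title: Autoencoder Modelling of Hippocampal Place and Grid Cells in 3D Mazes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates rodent foraging trajectories in flat arenas and four
    three-dimensional maze geometries (aligned and tilted climbing lattices,
    a five-coil helix, and a vertical pegboard), encodes self-motion through
    a head-direction basis and a path-integration layer of displacement
    cosines, and trains a small linear autoencoder whose bottleneck units
    develop place- and grid-cell-like firing. Provides the full battery of
    spatial-cell statistics used to characterise such units: occupancy
    normalised firing-rate maps in 2D bins and 3D voxels, spatial
    information and Skaggs sparsity with circular-shift shuffle nulls,
    rotational-autocorrelogram gridness scores, connected-component firing
    field extraction with principal-axis geometry, centroid-distribution
    and orientation shuffle tests, binary morphological erosion
    connectivity profiles, helix coil unwinding, and pegboard vertical
    layer analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
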