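Package: neurotess
Title: Watertight Neuron Membrane Meshes from Morphological Tracings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs closed, 2-manifold surface meshes of whole neurons from
    compact morphological tracings (SWC). The soma is recovered by deforming a
    tetrahedral icosphere with a static linear finite element model pulled toward
    the first-order neurite insertion points; neurites are swept as quad tubes
    along the traced polylines, stitched at bifurcations and merged with the soma
    into one watertight mesh. A CPU emulation of hardware tessellation refines the
    coarse mesh crack-free, driven by a per-tracing-point importance field, with
    new vertices placed on cubic Hermite centerlines and displaced radially.
    Includes synthetic morphology generation, mesh validation and evaluation
    metrics (volume, Hausdorff distance) and OBJ/OFF/PLY input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
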