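Package: vertseg
Title: Seed-Point Surface Region Growing for Separating Touching Bone
    Segments in Triangle Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic separation of touching bone segments (for
    example individual vertebrae in a thresholded spine surface) on 3D
    triangle meshes. Seed points placed on the surface initiate a
    breadth-first region growing that only crosses an edge when the angle
    between the two vertex normals stays below a connectivity threshold;
    the threshold is raised iteratively, with an undo stack and
    incremental seeding, until every vertex is assigned. Includes the
    standard virtual-surgical-planning front end (Hounsfield-unit
    thresholding of CT-like volumes and iso-surface triangulation), a
    full surface-to-surface evaluation suite (ASSD, AASD, RMS, maximum
    error, 95th percentile, percentage below tolerance, cumulative error
    curves, cutting-plane substructure partition, intraclass correlation),
    and a deterministic generator of ground-truth-labelled synthetic mesh
    phantoms and CT-like volumes that emulate chains of convex lobes
    touching at small contact patches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
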