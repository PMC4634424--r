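Package: somtraj
Title: Self-Organizing Map Recognition of Skeletal Motion Trajectories
Version: 0.1.0
Authors@R: person("somtraj", "developers", role = c("aut", "cre"),
    email = "somtraj@example.org")
Description: Recognition of therapeutic-exercise motion trajectories recorded
    as 20-joint depth-sensor skeletons. Frames are transformed to body-plane
    coordinates and reduced to a 71-dimensional posture descriptor (19 unit
    body-segment vectors plus 14 joint angles), a Kohonen self-organizing map
    clusters postures into basic posture units via U-matrix watershed
    segmentation with shallow-basin merging, motion trajectories become
    fixed-size gray trajectory maps whose shades encode visit order, one
    template per exercise is distilled with a multi-sequence longest common
    subsequence, and unknown trajectories are classified by normalized image
    correlation with threshold rejection. Includes a synthetic multi-subject
    motion generator for twelve coarse full-body exercises with speed, pause,
    rotation, anthropometric and noise perturbations, and a command-line
    pipeline (simulate, train, templates, classify, evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
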