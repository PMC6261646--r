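Package: snorkelr
Title: Quantitative Analysis of Membrane-Snorkeling Basic Residues and
    Intramembrane Protein-Lipid Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for studies of intramembrane ionic
    protein-lipid interactions in single-span membrane proteins such as
    the integrin alphaL-beta2 transmembrane heterodimer.  Provides a
    transmembrane-domain survey of basic (Lys/Arg) residues and their
    distance from the membrane/cytosol border; NMR titration statistics
    including weighted chemical shift perturbation, per-residue peak
    intensity ratios, paired dimerization tests, calcium double-ratio
    profiles that cancel nonspecific salt attenuation, and paramagnetic
    relaxation enhancement depth classification; donor-dequenching FRET
    efficiency summaries; Indo-1 ratiometric free-calcium calibration and
    bicelle composition arithmetic; voxel-based lipid spatial distribution
    functions with membrane-plane projections; and deterministic synthetic
    data generators with recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
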