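Package: fcrel
Title: Reliability and Reproducibility of Individual-Level Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying how reliable and reproducible
    individual-level functional connectivity estimates are as a function
    of scan duration and data-removal strategy.  Implements gray-matter
    sphere-packing parcellation with nearest-center voxel labelling,
    nuisance preprocessing for BOLD region-of-interest series (initial
    volume discard, linear detrend, ideal Fourier bandpass, white
    matter/CSF/motion regression), Fisher z-transformed pairwise
    connectivity with paired task-versus-rest contrasts under false
    discovery rate control, intraclass correlation reliability maps,
    root-mean-square reproducibility and its square-root-of-time scaling,
    cross-subject correlation of connectivity across acquisition
    conditions, and simulated scrubbing-versus-truncation experiments.
    Ships a synthetic multi-subject BOLD cohort generator with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
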