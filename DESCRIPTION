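Package: lungct
Title: Longitudinal Micro-CT Lung Densitometry and Ventilation Mapping
Version: 0.1.0
Authors@R: person("lungct", "developers", role = c("aut", "cre"),
    email = "lungct@example.org")
Description: Quantification pipeline for paired end-inspiratory and
    end-expiratory micro-CT scans of the mouse lung. Computes
    Hounsfield-unit aeration compartments (normo-, hypo- and non-aerated
    fractions), mean lung attenuation, gas and tissue volumes and tidal
    volume per region; maps regional ventilation by Laplacian-prefiltered
    multi-resolution Demons registration and voxel-wise specific gas
    volume (SVg) differences; calibrates percentile thresholds on a basal
    cohort and classifies voxels into normal, low-ventilation and
    fibrosis classes; and orchestrates cohort-level longitudinal
    fold-change analyses. Includes a mass-conserving synthetic thorax
    phantom generator with ground-truth masks, deformations and lesion
    labels for end-to-end validation without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
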