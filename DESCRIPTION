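Package: glymph
Title: Quantification of Glymphatic MRI Markers: DTI-ALPS and Enlarged
    Perivascular Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative assessment of brain glymphatic imaging
    markers from structural and diffusion MRI: diffusion-tensor fitting and
    the DTI-ALPS (diffusion tensor image analysis along perivascular spaces)
    index computed from spherical regions of interest in projection and
    association fiber regions; rule-based segmentation and morphometry of
    enlarged perivascular spaces (EPVS) including the 2 mm minimum-length
    filter, lesion counts, volumes and regional volume fractions;
    segmentation-agreement evaluation (Dice, recall, precision) against
    single raters and their union or intersection; and the accompanying
    statistical battery (normality-gated ANCOVA or Kruskal-Wallis with
    Bonferroni or Dunn post hoc tests, partial and Spearman correlations).
    Includes a fully ground-truthed synthetic phantom generator producing
    single subjects and calibrated multi-group cohorts for validating the
    whole pipeline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
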