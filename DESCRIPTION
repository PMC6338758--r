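Package: flycourt
Title: Quantification of Drosophila Courtship Assays and Genitalia
    Rotation Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify Drosophila melanogaster single-pair mating
    assays. Measures the dorsoventral deviation angle of male genitalia
    from landmark coordinates and classifies it into eight circular
    classes; detects copulation events in assay videos by binarizing
    frames, extracting fly-shaped connected components and calling
    sustained merged-shape intervals; computes courtship latency, the
    courtship index, and copulation and reproduction success rates with
    the standard inclusion rules; and runs the associated statistical
    battery (Fisher's exact test, Kruskal-Wallis with Steel-Dwass post
    hoc, one-way ANOVA with Tukey HSD). Includes an agent-based simulator
    that renders two-fly arena recordings with ground-truth event logs,
    landmark sets at known angles, and outcome tables drawn from known
    per-class success probabilities, so the whole pipeline can be
    exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
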