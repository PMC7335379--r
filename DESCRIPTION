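Package: microtissue
Title: Simulation and Quantification of Micro-Tissue Remodeling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an in vitro tendon micro-tissue remodeling platform:
    seeded generation of synthetic patient cohorts, compacting micro-tissue
    time-lapse image stacks and gel/blot images with ground truth; brightfield
    silhouette segmentation by intensity thresholding with an automatic
    edge-detection fallback; compaction read-outs (relative surface area at
    48 h, intact-versus-released classification with release-time estimation);
    gel and zymograph band densitometry with two-level background correction,
    housekeeping normalization, the MMP2 active-fraction statistic and a
    Tukey-fence loading-control outlier rule; and a regression layer relating
    every read-out to patient age, gender and tendon type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
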