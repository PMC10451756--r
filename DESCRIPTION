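Package: rhizocore
Title: Core Rhizosphere Microbiome Determination from Amplicon Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies the core microbiome of rhizosphere soil communities from
    OTU/ASV relative-abundance tables using three complementary definitions:
    a membership-based method (taxa shared by every sample of a group, ranked
    by mean relative abundance, top-N retained), a composition-based method
    (shared taxa whose standard deviation of relative abundance falls below a
    threshold), and a functional method (taxonomy-to-function rule matching in
    the FAPROTAX flat-file dialect, with exact tests comparing per-group
    assignment percentages). Includes plain tab-separated readers and writers
    for abundance tables, taxonomy lineages and core-set reports, a synthetic
    amplicon-community generator with planted core taxa for method validation,
    and a config-driven pipeline that runs all stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
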