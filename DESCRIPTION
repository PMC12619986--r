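Package: myoxphos
Title: Single-Fiber OXPHOS Phenotyping and Mitochondrial Bioenergetics for
    Skeletal Muscle Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for quantitative studies of mitochondrial function
    in skeletal muscle biopsies. Classifies individual muscle fibers as
    deficient, normal or overabundant for OXPHOS subunits (Complex I NDUFB8,
    Complex IV MT-CO1) relative to a 95% prediction-interval regression on a
    mitochondrial mass marker (VDAC1) fitted on unaffected control fibers, and
    attaches uncertainty to pre/post-intervention changes in class proportions
    via bootstrap, permutation and false-discovery-rate testing. Also extracts
    per-state oxygen fluxes and H2O2 emission rates from event-annotated
    high-resolution respirometry traces (SUIT protocols), computes the acceptor
    control ratio and free radical leak, normalizes immunoblot densitometry
    into an OXPHOS protein content index, summarizes histological integrity
    markers (NCAM+, central nuclei, nuclear clumps, damaged laminin), and ships
    synthetic-data generators that emulate every input so the full pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
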