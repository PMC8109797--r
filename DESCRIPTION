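Package: provmark
Title: Programmatic Literate Reports with Automatic Provenance Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds literate analysis reports (markdown with executable code
    chunks) programmatically from R code, so that pipelines, packages and
    graphical front-ends can maintain a reproducible-research audit trail
    without hand-editing documents. Reports are created with YAML front
    matter and per-chunk execution options, grown one element at a time
    (titles, prose, step-by-step or one-call code chunks), and compiled to
    standalone HTML with captured outputs and figures, a session-information
    section, a BibTeX-resolved reference list and a resources table. A
    wrapper-function factory makes any callable self-tracing: each invocation
    is recorded as a re-executable chunk before the call is performed. A
    bundled synthetic RNA-seq demo pipeline (negative-binomial counts for a
    three-condition, two-replicate design) exercises the whole machinery
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    utils,
    stats,
    grDevices,
    graphics,
    tools,
    yaml,
    evaluate,
    commonmark,
    base64enc
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
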