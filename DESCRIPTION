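Package: dagcall
Title: Port-Linked Workflow Execution and Multi-Caller Somatic Variant
    Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight workflow system and a somatic variant consensus
    layer for cancer genome sequencing analysis.  Workflows are written as
    plain shell command lines with a small markup grammar (<input> ports,
    [output] ports, #MACRO# placeholders), exported to a port-linked JSON
    document, rendered against macro bindings, and executed as a directed
    acyclic graph with parallel launch of independent steps, auxiliary log
    files, and resume-from-error.  The consensus layer merges per-caller
    VCFs for one sample into a caller-evidence-tagged variant list, applies
    the at-least-k-callers candidate rule together with allele-fraction,
    depth, and population-frequency filters, converts candidates to the
    Mutation Annotation Format, and reports mutation-type proportions,
    transition/transversion ratios, and tumor mutation burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    vcfR,
    stats,
    tools,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
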