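Package: gsnarg
Title: Fitness-for-Purpose Argumentation for Biological Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing, validating and rendering
    fitness-for-purpose arguments for computational models of biological
    systems, using a goal structuring notation (GSN) style argument tree of
    claims, strategies, context, assumptions, justifications and evidence.
    Provides a typed argument-graph model with well-formedness validation
    and hierarchical claim numbering, a versioned canonical JSON file
    format, deterministic layered diagram layout with SVG, PNG and DOT
    export, completeness metrics, and a statistical-evidence harness that
    derives per-track cell motility responses (velocity and displacement),
    partitions tracks by proximity to a forming cell aggregation, compares
    groups with the Mann-Whitney U test and attaches the result to the
    argument as an evidence node. Ships a worked argument for an
    agent-based simulation of lymphoid tissue (Peyer's Patch) development
    as an executable example, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    xml2,
    png
Config/testthat/edition: 3
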