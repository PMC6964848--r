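Package: serialferm
Title: Constraint-Based Simulation of Serial Two-Organism Fermentation
Version: 0.1.0
Authors@R:
    person("Serialferm", "Developers", email = "serialferm@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis (FBA) and flux variability analysis (FVA)
    for single-step and serial two-step fermentation processes. Organism
    metabolic models (SBML level 3 with FBC, or a plain tabular dialect) are
    wrapped in a five-chamber envelope (Media, Internal, Growth, Product,
    Waste) with unidirectional transporter reactions; feedstock media are
    dosed on a 1 g dry weight per gDW cells per hour mass basis and product
    yields are reported as percent of input media mass. On top of the
    pipeline sit media sensitivity analysis, media gradient analysis,
    single and pairwise reaction-knockout screening across two organisms,
    and a campaign planner with a local resumable parallel task runner.
    The linear programs are solved by a built-in two-phase simplex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
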