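Package: iceballast
Title: Sea-Ice Ballasting of Carbon Export: Trajectories, Flux Conditioning
    and Settling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how melting sea-ice ballasts
    sinking organic aggregates and conditions carbon export near the ice
    edge. Provides backward-in-time Lagrangian sea-ice tracking over
    prioritized gridded drift products with concentration-based formation
    detection, freezing-degree-day thermodynamic ice thickness and
    formation-depth derivation, ice-edge-distance conditioning of
    sediment-trap particle fluxes, from-scratch nonparametric trend and
    group statistics (seasonal Mann-Kendall, exact Wilcoxon rank-sum,
    Spearman, two-way Type II ANOVA with Tukey HSD), and roller-tank
    settling-velocity analysis. A synthetic-Arctic scenario generator
    supplies gridded drift, concentration, air-temperature and bathymetry
    fields plus trap-cup and particle-track tables with the statistical
    structure the analysis assumes, so the whole chain is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
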