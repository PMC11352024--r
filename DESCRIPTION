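Package: veinflow
Title: Hydraulic Circuit Analysis of Insect Wing Vein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models hemolymph transport through insect wing vein networks as
    steady Poiseuille flow in planar hydraulic resistor circuits. Provides
    nodal (conductance) and mesh (loop-current) Kirchhoff solvers, the
    measured Drosophila cyrtoloma wing vein geometry with its extra-crossvein
    (ECV) topology, virtual ablation and repositioning experiments for
    crossveins, idealized microchannel circuit analogues, allometric scaling
    and crossvein mass estimates, and seeded generators for synthetic ladder
    networks with closed-form reference circuits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
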