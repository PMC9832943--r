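Package: buildplanr
Title: Liquid-Handling Build Plans for Combinatorial DNA Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts combinatorial DNA-assembly design tables (j5-style
    output) into fully specified, machine-checkable liquid-handling plans
    for Golden Gate and homology-dependent (one-pot in vivo assembly and
    separate-PCR AQUA) cloning. Plans an optimal annealing-temperature
    gradient with per-reaction tube placement, computes dilution series and
    reaction mixes from printed final concentrations, pools amplified
    fragments in equimolar ratios, renders deck-setup and thermocycler
    instructions with full item tracking, and validates every plan on a
    virtual deck with exact volume and amount bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
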