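Package: tacswitch
Title: Mechanistic Simulation of Tacrolimus Oral-to-Intravenous Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-blood tacrolimus concentration-time profiles
    under twice-daily oral dosing and continuous intravenous infusion with
    a lumped physiologically based model (two-compartment blood-referenced
    disposition, Qgut-type intestinal availability, well-stirred hepatic
    extraction, organ-site-resolved CYP3A4/CYP3A5 metabolism, and
    competitive inhibition by co-simulated perpetrators such as
    itraconazole). For any clinical scenario - CYP3A5 expression split
    between a liver graft and the native intestine, comedication, reduced
    graft function, or a virtual twin of one patient - the package finds
    the continuous infusion rate matching the oral steady-state exposure
    and reports the PO/IV dose ratio and the Css/Cmin target-conversion
    ratio with population geometric means and 90 percent intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
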