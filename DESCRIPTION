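Package: milksub
Title: Dietary Substitution Modeling of Milk Products in Young Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling micronutrient intake adequacy in young
    children from single-day 24-hour dietary recall data, and for
    simulating the substitution of one milk product by another under
    equal-volume and isocaloric scenarios. Implements the EAR (estimated
    average requirement) cut-point method for prevalence of inadequate
    intake, milk-consumer classification from recall lines, paired
    scenario comparison with exact Wilcoxon signed-rank and Fisher tests,
    and a calibrated synthetic-survey generator emulating the covariate
    and intake structure of a large one-day national dietary survey of
    children aged 12-60 months.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
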