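Package: qdtchoice
Title: Quantum Decision Theory Analysis of Binary Risky-vs-Certain Lottery Choices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for applying quantum decision theory (QDT) to datasets of
    binary choices between a risky lottery and a certain amount in the domain
    of gains. Decomposes choice probabilities into an objective utility factor
    and a subjective attraction factor, aggregates repeated decision tasks by
    utility-factor bins with censoring of degenerate frequencies, tests the
    quarter law (mean |q| = 1/4) at the individual, group and population
    level, compares groups of decision makers with Kolmogorov-Smirnov tests,
    and simulates cohorts of artificial decision makers with controllable
    attraction-factor distributions so that every stage of the pipeline can be
    verified without the original experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
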