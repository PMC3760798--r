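Package: nfkbcbp
Title: NF-kB/IkB Feedback Modelling and RelA-Coactivator Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of the RelA (NF-kB) interaction
    with the CBP/p300 coactivator and its consequences for NF-kB signalling.
    Implements an ordinary-differential-equation model of the IKK-IkB-NF-kB
    negative-feedback module driven by a numerically defined IKK activity
    curve, parameter scans over NF-kB abundance and over the NF-kB-dependent
    IkBa mRNA production rate scored by combined root-mean-square deviation
    against normalized time-course data; one-site isothermal titration
    calorimetry (ITC) forward simulation, nonlinear fitting and
    thermodynamic-linkage consistency checks; chemical-shift-based helical
    population and heteronuclear-NOE flexibility estimation; delta-delta-Ct
    fold induction and four-way grouping of TNFa-responsive genes across
    RelA genotypes; and seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
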