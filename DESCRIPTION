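Package: cbtcea
Title: Markov Cost-Effectiveness Model of Internet-Based Versus Face-to-Face
    Cognitive Behavioral Therapy for Student Anxiety
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A five-state monthly-cycle Markov cohort model comparing guided
    internet-based cognitive behavioral therapy (i-CBT) with face-to-face CBT
    (f-CBT) for university students with mild anxiety symptoms, from a societal
    perspective. Computes discounted direct medical costs, friction-cost
    productivity losses and quality-adjusted life-years per strategy;
    classifies dominance and net monetary benefit; runs one-way sensitivity
    analysis with bisection threshold finding, two-way grid classification
    with frontier extraction, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. An individual-level Monte Carlo
    microsimulation of the identical decision process validates the cohort
    engine, and an eigendecomposition matrix-root utility converts
    transition-probability cycle lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
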