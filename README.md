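# cbtcea

A Markov cohort cost-utility model comparing **guided internet-based
cognitive behavioral therapy (i-CBT)** with **face-to-face CBT (f-CBT)**
for university students with mild anxiety symptoms, from a societal
perspective. The package is aimed at health-economics practitioners who
want a fully scripted, testable counterpart to spreadsheet/TreeAge-style
decision models: every number in the analysis — base case, one-way and
two-way sensitivity analyses with threshold finding, and a 10,000-draw
probabilistic sensitivity analysis with acceptability curves — is
recomputable from one configuration file and one seed.

## The model

A cohort of students with mild anxiety enters a five-state monthly-cycle
Markov model (well, mild, moderate, severe, dead) with a 5-year horizon.
During an initial low-intensity CBT phase (3 monthly cycles) the cohort
stays mild; at phase end it redistributes according to programme-level
recovery/deterioration probabilities, mixed over an *effective* stratum
(accepted × adhered) and a no-intervention stratum. i-CBT differs from
f-CBT through relative differences in acceptance (1.19) and adherence
(0.99) and through course pricing (therapist time × sessions for f-CBT;
a platform overhead plus 22 % of therapist time for i-CBT). Afterwards a
monthly background transition matrix (with anxiety-adjusted mortality)
runs to the horizon.

Each strategy accrues discounted (3 %/year) direct medical costs (CBT
courses, one-time escalation to high-intensity CBT for non-recovered
accepters, monthly outpatient psychiatric care, expected hospitalization
among the severe), friction-cost productivity losses (employed fraction ×
student wage × hours, while moderate/severe), and QALYs
(age-utility × state utility / 12 per cycle). Strategies are compared by
dominance, the incremental cost-effectiveness ratio
ICER = ΔC/ΔE, and net monetary benefit INMB = λ·ΔE − ΔC at a
willingness-to-pay λ = US$46,070/QALY (1× GDP per capita; 3× = 138,210).

A separate individual-level microsimulation of the identical process
(`simulate_individuals()`) validates the cohort engine to within Monte
Carlo error, and `matrix_root()` provides the eigendecomposition
matrix-root used to convert transition probabilities between cycle
lengths.

## Worked example

```r
library(cbtcea)
inputs <- default_model_inputs()   # or load_model_inputs("config.yaml")
fit <- cea_model(inputs)
fit
#> Markov cost-effectiveness model: i-CBT vs f-CBT
#> icbt: direct 4839 + indirect 1500 = total US$ 6338; 2.8410 QALYs
#> fcbt: direct 5001 + indirect 1508 = total US$ 6509; 2.8372 QALYs
#> incremental cost -170.42 US$, incremental QALY 0.00380
#>    intervention dominates (cheaper, more effective)
#>   INMB at WTP 46070: 345.52 US$
```

i-CBT costs US$170 less per student over five years and gains 0.0038
QALYs, so it *dominates* f-CBT: no willingness-to-pay judgement is needed.
The gain hinges entirely on uptake — the QALY difference crosses zero when
the acceptance advantage falls to the reciprocal of the adherence ratio:

```r
find_threshold(inputs, "rr_accept_icbt", "delta_qaly_zero")  # 1.0101
find_threshold(inputs, "rr_adhere_icbt", "delta_qaly_zero")  # 0.8403
```

Probabilistic analysis redraws every input from its beta/triangular
uncertainty distribution:

```r
psa <- run_psa(inputs, n_draws = 2000, seed = 1)
psa
#> Probabilistic sensitivity analysis: 2000 draws (seed 1 )
#>   mean incremental cost -128.6 US$ (95% CI -132.4 to -124.9)
#>   mean incremental QALY 0.00254 (95% CI 0.00243 to 0.00264)
#>   P(i-CBT cost-effective | WTP      0) = 0.959
#>   P(i-CBT cost-effective | WTP  46070) = 0.917
#>   P(i-CBT cost-effective | WTP 138210) = 0.888
plot(psa, "ceac")
```

The mean QALY gain sits below the base case because the adherence-ratio
uncertainty is left-skewed (triangular on 0.84–1 with mode 0.99). Other
entry points: `one_way()` / `tornado()`, `two_way()` (grid + frontier),
`cmd_basecase()` and friends for CSV bundles with run manifests, and
`Rscript inst/cli/cbtcea.R <command>` from a shell.

All structural choices the underlying analysis leaves open — which states
incur the monthly outpatient cost, phase length, the moderate/severe split
of deterioration, escalation recipients, half-cycle correction — are
explicit switches in `structural_config()`; the methods vignette
(`vignettes/markov-cea-model.Rmd`) documents each default and its
rationale.

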