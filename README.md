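# bindnseq

Thermodynamic inference of RNA-binding protein (RBP) sequence specificity
from in vitro affinity-selection data (RNA Bind'n Seq and similar
SELEX-style assays).

Given a selected ("foreground") and an input ("background") read library,
`bindnseq` fits a position weight matrix (PWM) **M** with entries
m<sub>iα</sub> = exp(E<sub>iα</sub>) and a sequence-unspecific binding
log-weight E<sub>0</sub> by maximizing the likelihood of the selected
reads under an explicit binding model. A read S of length L<sub>S</sub>
with windows s is bound with total weight

```
W_S = e^{E(S)} + (L_S - Lw + 1) e^{E0},    e^{E(S)} = Σ_{s∈S} Π_i m_{i,s_i}
```

and, in the unsaturated regime where the protein concentration cancels,
the probability that a sequenced selected read is S is

```
P(S) = f_S W_S / Σ_σ f_σ W_σ
```

with frequency priors f<sub>S</sub> predicted by an order-4 Markov model
trained on the background pool. Fitting alternates a bounded
1-D maximization of E<sub>0</sub> with a posterior reweighting update of
the PWM (expectation-maximization style), classifies runs as
*convergent* (final log-likelihood above initial) and *specific*
(E<sub>0</sub> < 0), and converts fitted likelihoods into dissociation
constants relative to a uniform length-5 reference motif so that motifs
of different lengths are directly comparable. A baseline k-mer enrichment
analysis and a full synthetic-experiment simulator with planted ground
truth round out the pipeline.

## Worked example

Simulate a Bind'n Seq experiment with a planted TGCATG motif
(consensus weight 0.85, E<sub>0</sub> = −8), then recover it:

```r
library(bindnseq)

sim <- simulate_selection(consensus_pwm("TGCATG", weight = 0.85),
                          e0 = -8, n_background = 10000,
                          n_foreground = 10000, seed = 42)

bg_model <- train_markov(sim$background, degree = 4, pseudocount = 1)
fg <- annotate_priors(as_read_library(sim$foreground), bg_model)

fits <- lapply(1:4, function(s) fit_em(fg, lw = 6, seed = s))
best <- fits[[which.max(sapply(fits, `[[`, "final_loglik"))]]
best
#> <em_fit> Lw=6 (random init, seed 4): 12 iteration(s), logL -86328.3388 -> -82258.4412
#>   e0=-7.005 | convergent: TRUE, specific: TRUE
#>   consensus: TGCATG

log_relative_kd(best, fg)
#> # A tibble: 1 × 6
#>   log_kd_rel    lw lw_ref final_loglik reference_loglik consensus
#>        <dbl> <dbl>  <dbl>        <dbl>            <dbl> <chr>
#> 1     -0.472     6      5      -82258.          -86332. TGCATG

pwm_distance(sim$truth$pwm, best$model$pwm)$distance
#> [1] 0.04466851
```

The best of four random restarts recovers the planted consensus exactly
(mean per-position total-variation distance 0.045 after shift alignment).
The negative `log_kd_rel` (natural log) says the fitted motif binds
stronger than the uniform length-5 reference; the fitted
E<sub>0</sub> ≈ −7.0 marks a clearly specific solution (reads out as an
upper bound on the true unspecific weight; see the methods vignette).
`classify_runs(fits)` summarizes convergent/specific fractions across
restarts, `run_sweep()` orchestrates the full
L<sub>w</sub> = 5…15 × (16 random + 4 consensus) design, and
`tidy()`, `glance()` and `autoplot()` expose every result as tibbles and
ggplots. The hexamer enrichment baseline ranks the planted motif first:

```r
et <- enrichment_table(sim$foreground, sim$background, k = 6)
head(dplyr::arrange(et, rank), 3)
#> # A tibble: 3 × 5
#>   kmer   fg_count bg_count log_enrichment  rank
#>   <chr>     <dbl>    <dbl>          <dbl> <int>
#> 1 TGCATG     1437       32           3.77     1
#> 2 CTGCAT      495       32           2.71     2
#> 3 GCATGT      476       35           2.58     3
```

Details of the model, its assumptions, all tunable parameters and known
limitations are in the methods vignette,
`vignettes/thermodynamic-motif-inference.Rmd`.

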