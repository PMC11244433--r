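# traitpart

Partitioning intraspecific and interspecific functional-trait variation in
plant communities.

## What it does, and for whom

Community ecologists running manipulative gradient experiments (nutrient
addition, warming, grazing) face the same decomposition problem: when the
mean trait of a community shifts under a treatment, how much of that shift
comes from **species turnover** (interspecific variation — the species mix
changes, and species differ) and how much from **intraspecific variation**
(the same species express different trait values)? `traitpart` answers this
for individual-level trait measurements (plant height H, leaf area LA, leaf
dry matter content LDMC, specific leaf area SLA, or any positive traits)
taken across treatment plots.

Three layers of analysis:

**Within each community** — abundance-weighted variance indices, with
$a_i$ the relative biomass of species $i$, $\bar x_i$ its plot mean,
$x_{ji}$ individual values and $N_i$ individuals measured:

$$\mathrm{wITV}_{intra}=\sum_i a_i\frac{1}{N_i}\sum_j(x_{ji}-\bar x_i)^2,
\qquad
\mathrm{wITV}_{inter}=\sum_i a_i\left(\bar x_i-\sum_i a_i\bar x_i\right)^2 .$$

**Among communities** — the community trait mean is split into *specific*
(plot-local species means), *fixed* (species frozen at their grand means
pooled over all communities; tracks composition only) and *intra* =
specific − fixed, under both the abundance-weighted mean (CWM) and the
equal-weight mean (CM).

**Decomposition and tests** — one-way treatment ANOVAs on the specific,
fixed and intra series give, per stratum, the identity
$SS_{specific}=SS_{fixed}+SS_{intra}+SS_{cov}$; the covariation term is
positive when turnover and intraspecific shifts reinforce and negative when
they oppose. Treatment effects on every index are tested with one-way
ANOVA, Tukey–Kramer HSD and compact letter displays; productivity (ANPP)
gets the same ANOVA when present.

A seed-deterministic synthetic-community generator with known ground truth
(species turnover, intraspecific shifts, individual noise, species loss,
trait-linked ANPP) supports validation; see `scenario_presets()`.

## Worked example

```r
library(traitpart)
bundle <- run_pipeline(run_config(preset = "paper-like", seed = 1))
bundle$decomposition[, c("trait", "scheme", "percent_fixed",
                         "percent_intra", "percent_cov", "p_specific")]
#>   trait scheme percent_fixed percent_intra percent_cov p_specific
#> 1     H    cwm         55.96          6.25        36.9   2.89e-15
#> 2    LA    cwm         49.59          8.13        39.8   8.61e-12
#> 3  LDMC    cwm          4.49         44.68        27.7   1.14e-04
#> 4   SLA    cwm         16.73         32.87        45.6   1.12e-09
#> 5     H     cm         22.28         30.84        40.2   1.21e-08
#> 6    LA     cm          2.69         61.91        22.4   1.66e-06
#> 7  LDMC    cm          1.66         81.61       -21.8   4.39e-03
#> 8   SLA     cm          2.07        107.12       -25.4   8.52e-06
```

Each row reads: of the total variation in that community-mean series across
the 20 plots, the treatment explains `fixed + intra + cov` percent, split
into the interspecific (fixed), intraspecific and covariation effects. For
height under CWM, 56 % of total variation is turnover-driven and only 6 %
intraspecific, with strong positive covariation (taller species *and*
taller individuals at high N in this scenario); the negative covariations
in the CM rows show turnover and plasticity opposing once species are
weighted equally.

```r
bundle$anpp_anova$anova
#> one-way ANOVA: F(4, 15) = 12.35, p = 0.0001209

bundle$letters[bundle$letters$trait == "H" &
               bundle$letters$index == "witv_inter", ]
#>   trait index      treatment letters
#> 1 H     witv_inter CK        b
#> 2 H     witv_inter N2.5      b
#> 3 H     witv_inter N5        a
#> 4 H     witv_inter N10       a
#> 5 H     witv_inter N20       a
```

Treatments sharing a letter are not significantly different (Tukey HSD,
α = 0.05): here the interspecific height variance within plots is
significantly larger from N5 upward.

With `out_dir` set, `run_pipeline()` writes `within_indices.csv`,
`community_means.csv`, `anova_results.csv`, `tukey_results.csv`,
`letters.csv`, `decomposition.csv`, a Markdown summary and a reproducibility
manifest. A thin command-line front end lives at `inst/cli/traitpart.R`
(`simulate` and `run` subcommands).

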