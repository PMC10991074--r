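# mistkit

Tools for measuring misinformation susceptibility with the Misinformation
Susceptibility Test (MIST) and for building tests like it.

People differ in how well they can tell real news headlines from fabricated
ones, and interventions (media-literacy games, inoculation messages,
accuracy prompts) claim to improve that ability. Quantifying either claim
needs more than a percent-correct: an intervention can "improve fake-news
detection" simply by making people distrust everything. mistkit implements
the **Verification done** scoring framework, which decomposes performance on
a balanced true/false headline test into five quantities:

- **V** — veracity discernment: total items answered correctly, `V = r + f`;
- **r** — real-news detection: real headlines correctly labeled *real*;
- **f** — fake-news detection: fake headlines correctly labeled *fake*;
- **d** — distrust: excess of *fake* labels over the number of fake items,
  `d = max(0, #fake-labels − k_fake)` (over-skepticism);
- **n** — naïveté: excess of *real* labels over the number of real items,
  `n = max(0, #real-labels − k_real)` (over-gullibility).

At most one of `d`/`n` is positive, and on a balanced test
`d − n = f − r`, so a judgment-bias shift is visible as a mirrored
movement of `r` and `f`.

The package is aimed at researchers who (a) administer the MIST and want
norm-referenced scores, and (b) develop or audit headline-judgment scales
and want the full psychometric machinery in one place.

## What's inside

- **Item banks** — the published MIST-20 (with 3PL discrimination `a`,
  difficulty `b`, guessing fixed at `c = 0.5`), the MIST-8 short form, and
  the four-dimension MIST-16, plus JSON read/write and validation for
  custom banks (`builtin_bank()`, `validate_bank()`, `load_bank()`).
- **Scoring and norms** — `score_responses()` / `score_matrix()` for
  Verification-done scores, US/UK general-population norm tables with
  percentile lookups (`score_at_percentile()`, `percentile_rank()`) and
  cohort baseline reports (`cohort_norm_report()`).
- **Item response theory** — the three-parameter logistic model
  `P(θ) = c + (1 − c) / (1 + e^{−a(θ − b)})`: trace lines, item/test
  information, EAP ability scoring, marginal-maximum-likelihood EM
  calibration with `c` fixed (`calibrate_3pl_em()`, a classed fit with
  `print`/`summary`/`coef`/`logLik`/`plot` methods), and anchored
  likelihood-ratio DIF screening.
- **Classical test theory** — maximum-likelihood tetrachoric correlations,
  parallel analysis with column-permutation nulls, principal-axis/ULS
  exploratory factor analysis with varimax rotation, Cronbach's alpha with
  alpha-if-deleted pruning, and a two-factor McDonald's omega report with a
  higher-order (Schmid–Leiman style) decomposition.
- **Exploratory graph analysis** — EBICglasso partial-correlation networks
  (graphical lasso over a penalty path, extended-BIC model selection),
  Walktrap community detection, standardized network loadings, unique
  variable analysis via weighted topological overlap, parametric bootEGA
  (item stability, structural consistency) and the total entropy fit index
  (`ega()`, `boot_ega()`, `tefi()`).
- **Item selection** — the staged EFA/IRT decision tree (loading,
  cross-loading, 3PL-communality and alpha filters, optional DIF screen)
  and discrimination-greedy difficulty-binned final selection
  (`run_decision_tree()`, `irt_final_selection()`).
- **Simulation** — synthetic respondents from a higher-order two-factor 3PL
  with yea/nay-saying bias mixtures, and item pools with planted factors,
  junk, cross-loaders and redundant pairs (`simulate_responses()`,
  `simulate_item_pool()`).
- **Evaluation** — paired pre/post tests per Verification-done dimension
  with `d_z`/`d_av` effect sizes and noncentral-t CIs
  (`paired_change_test()`), incremental-validity regressions, and
  sample-size solvers (`required_n_ttest()`, `required_n_correlation()`).

## Worked example

Score one respondent who mislabels six of the twenty MIST-20 headlines:

```r
library(mistkit)

bank <- builtin_bank("MIST-20")
key <- setNames(bank$items$veracity, bank$items$id)
labels <- key  # start from a perfect response, then miss six items
miss <- c("MIST_28", "MIST_15", "MIST_82", "MIST_87", "MIST_65", "MIST_99")
labels[miss] <- ifelse(key[miss] == "real", "fake", "real")

(scores <- score_responses(bank, labels, respondent_id = "respondent-1"))
#> <mist_scores> 1 respondent(s), k = 20
#>   respondent_id  V r f d n  k k_real k_fake
#> 1  respondent-1 14 6 8 2 0 20     10     10

percentile_rank(builtin_norms("US", "MIST-20"), "V", scores$V)
#> [1] 50

estimate_theta_eap(bank$items, as.integer(labels == key))
#> <EAP theta> -0.451 (posterior SD 0.430, 20 items)
```

Fourteen of twenty headlines are judged correctly (`V = 14`): eight fake
ones caught (`f = 8`) but only six real ones trusted (`r = 6`), and the two
extra *fake* labels register as distrust (`d = 2`, `n = 0`). Against the US
general-population norms a raw `V` of 14 sits at the 50th percentile, and
the item-response model places the respondent about half a standard
deviation below the population mean ability (θ̂ = −0.45), with the usual
short-test uncertainty (posterior SD 0.43).

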