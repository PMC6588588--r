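# pathdistill

Cohort-specific transcription-factor target distillation and pathway
activity scoring.

Curated signaling pathways for immune differentiation programs (Th1,
Th2, T-fh, ...) converge on a master transcription factor — TBX21,
GATA3, BCL6 — and stop at an unmeasurable biological-process node. What
the process is actually doing in a tumor cohort is written in the TF's
target genes, and which targets respond is cohort-specific.
`pathdistill` is for computational biologists who have (1) a curated
pathway with signed edges and routes into a TF, (2) a gene × subject
matrix of log2 tumor/control expression ratios, (3) ChIP-seq peak sets
for the TF, and (4) clinical follow-up, and who want to extend the
pathway with the Up/Down targets that matter *in that cohort* and score
every subject's pathway activity.

## The scores

For a route gene $g_i$ with net sign $s_i$ (product of edge signs to the
TF $g_t$), consistency is $v = s_i\,\mathrm{sign}(g_i)\,\mathrm{sign}(g_t)$.
With empirical per-gene p-values (add-one tail counts against the
cohort) and the plug-in false-discovery estimate
$\mathrm{FDR} = \min(1,\; n\,t_p / n_{pass})$:

* **Route propagation score** of a route with $n_g$ upstream genes:
  $R = \dfrac{\#\{v>0\} - \#\{v<0\}}{n_g}\,(1 - \mathrm{FDR})\in[-1,1]$ —
  how coherently the route transmits into the TF. $R < 0$ flags a TF
  decoupled from its upstream input.
* **Effect score** over $m$ Up and $n$ Down targets (process direction
  estimated by the TF):
  $M = \dfrac{\#\{v>0\} - \#\{v<0\}}{n+m}\,(1 - \mathrm{FDR})\in[-1,1]$ —
  how coherently the TF program reaches its targets.

Distillation selects activated ($R > t_{cu}$) and suppressed
($R < t_{cd}$) sub-cohorts, correlates ChIP-derived candidates with the
TF over their union $C'$, classifies Up ($\rho > t_{gu}$) and Down
($\rho < t_{gd}$) targets, extends the pathway and rescores. Quality
check: $\rho(R, M)$ must be larger over $C'$ than over the whole cohort
(CorC′ > CorC). Evaluation: Kaplan–Meier / log-rank stratification,
threshold sweeps, Th1×Th2-style quadrant analysis, topology-preserving
decoy pathways under a 2-of-3 dissimilarity rule, and cross-cohort
target overlap. See `vignette("pathdistill-methods")` for the full
model and design rationale.

## Worked example

Every stage runs against the built-in synthetic cohort generator, which
plants a known regulatory structure (activated / TF-decoupled /
neutral subjects, 30 Up and 30 Down targets, survival tied to downstream
coherence):

```r
library(pathdistill)

cohort <- simulate_cohort(simulation_config(seed = 3))
fit <- distill(cohort$pathway, cohort$expr, cohort$ptg,
               t_cu = 0.5, t_cd = -0.5, t_gu = 0.3, t_gd = -0.3)
fit
#> <distillation> planted_pathway
#>   C': 78 subjects (36 activated, 42 suppressed)
#>   targets: 30 Up, 30 Down of 100 candidates
#>   CorC = 0.141, CorC' = 0.328 (improved)
```

Of 300 subjects, 78 pass the R-score thresholds; all 60 planted targets
are recovered from the 100 candidates (30 Up, 30 Down) and the
R–M correlation improves from 0.141 (full cohort) to 0.328 (selected
cohort), passing the quality check. The extension carries survival
signal:

```r
groups <- stratify(fit$scores, score = "M", beta = 0)
tidy(logrank_test(cohort$clinical, groups))
#> # A tibble: 1 × 4
#>   statistic    df  p.value     n
#>       <dbl> <dbl>    <dbl> <int>
#> 1      48.6     1 3.13e-12   189
```

Subjects with positive M (coherent downstream program) separate sharply
from the rest (log-rank p ≈ 3e-12 over the 189 subjects with nonzero
M). All ten decoy pathways are rejected by the 2-of-3 rule:

```r
report <- decoy_analysis(cohort$expr, fit$extended, k = 10, seed = 7)
head(tibble::as_tibble(report), 3)
#> # A tibble: 3 × 6
#>   decoy                       t_p wilcox_p correlation criteria_met significant
#>   <chr>                     <dbl>    <dbl>       <dbl>        <int> <lgl>
#> 1 planted_pathway_decoy1 1.75e-16 2.16e-10     0.0434             3 TRUE
#> 2 planted_pathway_decoy2 2.00e-16 3.43e- 9    -0.0542             3 TRUE
#> 3 planted_pathway_decoy3 9.65e-16 6.85e- 9    -0.00395            3 TRUE
sum(report$significant)
#> [1] 10
```

`plot_km()`, `plot_sweep()` and `autoplot()` (on score tables) draw the
corresponding figures; `run_pipeline(run_config(...))` drives the whole
chain from files to a manifest, and `write_cohort()` materializes a
synthetic cohort as pipeline inputs.

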