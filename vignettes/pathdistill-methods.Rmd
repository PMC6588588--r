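---
title: "Route and effect scoring of TF-centred pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Route and effect scoring of TF-centred pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdistill)
```

# The problem

Curated signaling pathways end, for many immune differentiation programs,
at a master transcription factor (TF) — TBX21 for Th1, GATA3 for Th2,
BCL6 for T-fh — followed by a biological-process node that the curation
cannot resolve into genes. Whether that process is actually engaged in a
given tumor, however, is written in the TF's *target genes*, and which
targets respond is cohort- and context-dependent. `pathdistill`
implements a pipeline that (i) scores how coherently each subject's
transcriptome transmits signal along the curated routes into the TF,
(ii) uses the most extreme subjects to distill cohort-specific Up and
Down target genes from ChIP-seq-derived candidates, (iii) extends the
pathway with them, and (iv) asks whether the extension carries clinical
signal (survival stratification) and statistical identity (decoy
pathways).

All expression values are log2 tumor/control ratios: positive means
up in tumor, negative down, zero no change.

# Scores

## Consistency

For a gene $g_i$ with net regulatory sign $s_i \in \{+1,-1\}$ toward the
TF $g_t$ (the product of activation/inhibition edge signs along the route
segment from $g_i$ to $g_t$), the consistency of a subject's values is

$$v(g_t, g_i) = s_i \,\mathrm{sign}(g_i)\,\mathrm{sign}(g_t) \in \{-1, 0, +1\}.$$

A net activator moving with the TF, or a net inhibitor moving against
it, is consistent ($+1$). A value of exactly zero yields $v = 0$ and the
gene counts in neither direction; the rule set only defines the
positive/negative cases, and a zero log-ratio carries no direction.

## Empirical p-values and the FDR weight

Each gene's null distribution $h(s)$ is its own vector of log2 ratios
across the cohort; the p-value of an observed value is the tail area
beyond it, estimated by add-one counting, $(k+1)/(n+1)$, which avoids
zero p-values and any density estimation. The tail follows the gene's
observed direction: upper tail for positive values, lower for negative,
two-sided (capped at 1) at exactly zero. Using the cohort itself as the
reference population is a deliberate choice — the scores are then
self-contained per cohort — at the price of conflating a globally
dysregulated gene with its own null.

With $n$ genes examined at threshold $t_p$, of which $n_{pass}$ fall
below it, the expected fraction of false discoveries is estimated as

$$\mathrm{FDR} = \min\!\left(1, \frac{n \, t_p}{n_{pass}}\right),$$

taken as 1 when nothing passes. The raw ratio is unbounded and undefined
at $n_{pass} = 0$; clamping keeps the downstream scores inside $[-1,1]$
and collapses a subject with no significant evidence to a score of 0
rather than an arbitrary one.

## Route propagation score R

For route $j$ with $n_g$ genes upstream of the TF,

$$R_j = \frac{\#\{v > 0\} - \#\{v < 0\}}{n_g} \times (1 - \mathrm{FDR}_j),$$

with the FDR computed over the route genes' p-values at threshold
$t_{pr}$. The TF itself is excluded from the counts (its consistency with
itself is vacuous). The normalizer is the gene count of the route: the
balance term then lies in $[-1,1]$ and the FDR weight keeps it there.
$R > 0$ means the upstream route and the TF move coherently; $R < 0$
flags a TF that moves *against* what its upstream input predicts —
transcriptional decoupling at the TF.

When a pathway has several routes, each subject keeps all per-route
values, and the scalar R used for sub-cohort selection is the route score
of maximal magnitude (first route on ties). The selection step needs one
R per subject and the strongest route is the one carrying the evidence;
averaging would let an inert route dilute a decisive one.

## Effect score M

The biological process itself is unmeasured; its direction is estimated
by the TF's log2 ratio. Each Up target is consistent when it moves with
the TF, each Down target when it moves against it. Over the
$n_m = |G_u| + |G_d|$ targets,

$$M = \frac{\#\{v > 0\} - \#\{v < 0\}}{n_m} \times (1 - \mathrm{FDR}_m),$$

with the FDR at threshold $t_{pm}$. When every consistent target is also
significant this reduces to the patient-level form
$A_k (1-\mathrm{FDR})/(n+m)$ with $A_k$ the consistent-and-significant
count. M measures downstream coherence: a subject whose TF program is
actively transmitted to its targets scores high whether the pathway is
being driven up or down.

# The distillation algorithm

1. **Score routes.** Compute R for every subject.
2. **Select sub-cohorts.** $C_u = \{R > t_{cu}\}$ (coherently activated)
   and $C_d = \{R < t_{cd}\}$ (TF-decoupled / suppressed);
   $C' = C_u \cup C_d$. Inequalities are strict, exactly as the selection
   rule is stated; ties at a threshold are excluded. $t_{cu} \ge t_{cd}$
   guarantees disjointness.
3. **Correlate.** Pearson correlation $\rho_i$ between each candidate
   target and the TF over $C'$ only. The unselected middle of the cohort
   carries little regulatory contrast and mostly noise; restricting to
   $C'$ is what makes the correlations informative.
4. **Classify.** $G_u = \{\rho_i > t_{gu}\}$, $G_d = \{\rho_i < t_{gd}\}$,
   again strict. Candidates missing from the expression matrix are
   skipped with a warning (ChIP-derived candidate lists routinely exceed
   the measured genes); the TF is never its own candidate. Absolute
   thresholds are the default; `quantile_thresholds()` supports
   quantile-based cutoffs, and `cap_by_fdr()` implements an optional
   FDR-style size cap (retain the top $\lceil (1-f)\,k \rceil$ by
   magnitude), off by default.
5. **Extend.** Attach $G_u$/$G_d$ to the pathway.
6. **Score the extension.** Compute M for every subject.

The quality check compares $\mathrm{Cor}C = \rho(R, M)$ over the full
cohort with $\mathrm{Cor}C'$ over $C'$: a sound extension makes R and M
more coherent over the selected extremes, $\mathrm{Cor}C' > \mathrm{Cor}C$
(strictly, beyond floating-point jitter).

# Evaluation

Survival stratification uses the Kaplan–Meier estimator and the k-group
log-rank test (`survival::survfit` / `survdiff`); the log-rank test is
the standard companion of a KM comparison and is what the package reports
wherever a "KM p-value" is called for. Binary stratification at
threshold $\beta$ puts score $> \beta$ high and $< \beta$ low, excluding
exact ties; `threshold_sweep()` scans $\beta$ over a grid (default
$-1$ to $1$ in steps of 0.1) for both R and M, skipping cells where a
side falls below `min_group` (default 10) subjects. Quadrant analysis
crosses two pathways' M scores (e.g. Th1 $\times$ Th2) into four groups
tested jointly (df = 3). An optional filter excludes subjects event-free
beyond a horizon (default 5 years), focusing the comparison on the
clinically informative window. Stage-stratified analysis repeats a
comparison within each clinical stage and reports untestable stages
explicitly.

Decoy pathways replace every non-process gene (routes, TF and targets)
with distinct genes drawn without replacement from a user universe,
keeping topology, edge signs and target partition sizes. A decoy is
*dissimilar* from the tailored pathway when at least 2 of 3 criteria
hold: two-sample t-test p < $\alpha$, Wilcoxon rank-sum p < $\alpha$,
and $|\rho| <$ `corr_cut` between the score vectors. The correlation
criterion is stated in the dissimilarity direction — a *low* correlation
is evidence that the tailored score vector is not reproduced by chance
relabelling — with cut 0.3 by default; an undefined correlation
(constant scores) counts as not met. A real extension should beat all
decoys; an identical score vector fails all three criteria.

Cross-cohort overlap counts every region of the Venn partition of the
Up (and separately Down) target sets and extracts the common core, which
`restrict_targets()` turns into a restricted-target M score for
comparing cohorts on a shared gene set.

# Tunable parameters

| parameter | meaning | default | domain |
|---|---|---|---|
| `t_pr`, `t_pm` | p-value thresholds inside the route / effect FDR | 0.05 | (0, 1] |
| `t_cu`, `t_cd` | R thresholds selecting $C_u$ / $C_d$ | 0.5 / −0.5 | [−1, 1] |
| `t_gu`, `t_gd` | correlation thresholds for Up / Down targets | 0.3 / −0.3 | [−1, 1] |
| `window` | TSS window for peak mapping (bp) | 2000 | > 0 |
| `mode` | `upstream` (strand-aware) or `both` | upstream | — |
| `idr` | conservative/optimal set combination | intersect | — |
| `beta` | stratification threshold on a score | 0 | [−1, 1] |
| `min_group` | smallest group size tested in a sweep | 10 | ≥ 1 |
| `k`, `alpha`, `corr_cut` | decoy count and criteria | 10 / 0.05 / 0.3 | — |

The 2 kb upstream window reflects promoter-proximal TF binding; widening
it (or using `mode = "both"`) grows the candidate set at the cost of
specificity. Peaks are anchored at their midpoint — deterministic and
available for every BED dialect, unlike summit columns.

# The synthetic cohort generator

`simulate_cohort()` produces the cohorts every pipeline stage is tested
on. It emulates a TCGA-like design: log2 tumor/control ratios for
`n_genes` = 1000 genes over `n_subjects` = 300 subjects, a planted
pathway (2 routes of 4 upstream genes into one TF, one inhibitory edge so
net signs mix), 30 Up and 30 Down planted targets, 40 unregulated decoy
candidates mixed into the candidate set, and right-censored survival.

Subjects come in three states:

* **activated** (15%): upstream route genes shifted by +2 log2 units
  along their net signs, TF shifted +2 — coherent propagation, $R \to +1$;
* **suppressed** (15%): upstream input *present* (route genes shifted as
  above) but the TF mirrored to −2 — decoupling at the TF, $R \to -1$.
  This is the configuration the selection rule $R < t_{cd}$ is built to
  catch: a pathway whose input arrives but whose TF program is shut off.
  A fully mirrored subject (everything down coherently) would score
  $R > 0$ by the consistency rules and is deliberately not what
  "suppressed" means here;
* **neutral** (70%): pathway disengaged, all pathway genes at baseline
  noise.

Planted targets follow $x = \kappa\, a\, t + \varepsilon$ with the TF
value $t$, coupling $\kappa = 1$ (activated), $0.5$ (suppressed — the TF
program is running at reduced output, so target regulation is partial)
and $0$ (neutral — targets revert to baseline). The coefficient $a$ is
solved from the closed-form moments of this mixture so that the realized
Pearson correlation over responsive subjects equals the design values
(+0.7 Up, −0.6 Down); a Monte-Carlo test verifies the realization to
±0.1. The graded coupling is what gives the extension its signature:
M is high for activated, intermediate for suppressed and near zero for
neutral subjects, so R and M correlate over the selected extremes
(CorC′ > CorC) and M tracks downstream activity that R cannot see.

Survival is exponential with log-hazard $-\lambda s_k$, where $s_k$ is
the subject's realized consistency of the planted targets with the TF
(the ground-truth analogue of M) and $\lambda$ = `survival_link` = 2 —
a hazard ratio of about $e^{2\cdot0.7} \approx 4$ between a strongly
coherent subject and baseline, strong but within the range of published
immune-signature effects. Censoring marks a Bernoulli(`censor_rate` = 0.3)
subset, observed at a uniform fraction of their event time. Noise is
Gaussian with SD 1 on the log2 scale; a 4-fold regulatory shift over
1-unit noise is a strong but realistic planted effect. Stage labels,
when requested, follow hazard quantiles.

What the generator does **not** emulate: count-level noise
(negative-binomial sampling, library size), gene-gene correlation beyond
the planted structure, batch effects, informative censoring, or
subjects whose state is partial. Passing tests therefore demonstrate
that the algorithms do what they claim under their own model — planted
targets are recovered, the quality check and the M-vs-R survival
contrast behave as designed, decoys are rejected — not that real TCGA
cohorts would yield any particular gene list.

# Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold is compared; ties are
  excluded, not assigned.
* `sign(0) = 0` makes zero log-ratios neutral in consistency counts and
  routes them to the two-sided p-value.
* FDR clamped to [0,1]; `n_passing = 0` gives FDR 1 and a score of 0.
* The per-subject scalar R takes the max-|R| route, first route on ties
  (routes are in deterministic lexicographic order when enumerated).
* Sub-cohort selection with fewer than 3 subjects warns at selection and
  errors at correlation time, where the quantity becomes undefined.
* Constant vectors: correlation is refused (classification skips the
  gene with a warning; the decoy correlation criterion counts as unmet).
* Route enumeration is a DAG-only fallback; cyclic pathways must declare
  their routes, which are first-class curation objects.
* Test and example problem sizes (300 × 1000 cohorts, 10 seeds for
  recovery/quality properties, 200 seeds for null calibration) were
  chosen to keep any property check under a couple of minutes on a
  laptop while leaving the binomial error of the checked fractions well
  below the margins asserted.

# Known limitations

* The effect score measures *coherence* of targets with the TF, not the
  direction of the biological process; two cohorts can both score
  positive M while one is activated and one suppressed. Directional
  statements need the TF's own sign alongside M.
* Cohort-internal nulls make p-values relative: a gene shifted in every
  subject is its own null and will not look significant.
* Pearson correlation over $C'$ assumes an approximately linear
  TF–target relation on the log2 scale.
* Gene identifiers are case-sensitive symbols with no aliasing layer;
  candidate lists must be harmonized to the expression matrix upstream.
* The sweep reports raw p-values across the grid by design; it is a
  descriptive scan, not a multiplicity-corrected test.
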