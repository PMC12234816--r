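---
title: "Simulating mood-disorder diagnoses and their decision-tree approximations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mood-disorder diagnoses and their decision-tree approximations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodtrees)
```

## The question the package addresses

DSM-IV-TR diagnoses of the three common mood disorders — major depressive
episodes (`mde`), dysthymic disorder (`dys`) and manic episodes (`manic`) —
are count-threshold rules over 15, 11 and 14 binary input symptoms
respectively. Such rules implicitly weight symptoms very unevenly: the two
major-criteria symptoms of a depressive episode are individually necessary,
while each minor symptom only contributes to a count that is censored at its
threshold. `moodtrees` studies a practical consequence: **when symptom
prevalence or between-symptom correlation is high, a handful of heavily
weighted symptoms can stand in for the full criteria with near-perfect
sensitivity and specificity.** The package simulates synthetic populations
over a grid of symptom prevalence and correlation, derives the three
diagnoses exactly from the rules, approximates each diagnosis with a
cross-validation-pruned classification tree, and aggregates the accuracy and
symptom-usage statistics of those trees.

Everything is synthetic: there is no real-world data set of jointly recorded
psychiatric symptoms with the required structure, which is precisely the gap
the simulation explores.

## The diagnostic rules

Symptoms are binary (present = 1). Minor criteria are counted at the *item*
level, where an item is either a single symptom or the disjunction of two
related symptoms (e.g. insomnia *or* sleeping too much forms one item). The
encoded rules are:

* **mde** — both major symptoms (`mde_ma1` depressed mood, `mde_ma2` loss of
  interest) **and** at least 3 of 7 minor items (six OR-pairs plus recurrent
  thoughts of death). The criteria's "at least 5 ... including the two in
  major criteria" is therefore 2 majors + 3 minor items.
* **dys** — the major symptom `dys_ma` (chronic depressed mood) **and** at
  least 2 of 6 minor items. Three of those items (sleep, energy,
  concentration) are shared with the depressive-episode rule, so the two
  diagnoses share six raw symptoms.
* **manic** — irritable mood `man_ma3` is structurally required; with
  exactly one of `man_ma1` (elevated mood) / `man_ma2` (expansive mood)
  present, at least 3 of 7 minor items suffice, otherwise ("mood only
  irritable", or both elevated and expansive) 4 items are required. This is
  the only Boolean reading of the published algebra
  `(1 - ma1*ma2)(ma1 + ma2)`, and it makes the rule deliberately
  non-monotone in `ma1`/`ma2`.

Two readings required a decision. First, the criteria's prose offers
"depressed mood *or* a loss of interest" for the mde major criteria while the
minor-criteria line demands both major symptoms; only the both-majors reading
makes a two-split tree on `mde_ma1`, `mde_ma2` perfectly sensitive, which is
what the high-prevalence simulations show, so both are required here. Second,
the source framework carries *bias variables* — residual information terms
attached to every composite. In this package the diagnoses are deterministic
functions of the symptoms, so every bias term is identically zero and none is
simulated. A consequence worth stating plainly: any published simulation in
which those terms were random quantities will produce noisier diagnoses than
this package does, and a few of its extreme cells (exactly zero diagnoses at
low prevalence, specificity exactly 1 at high prevalence) are not
reproducible under deterministic rules. The tests cover those cells with
structural properties instead (a diagnosis implies its major symptoms; the
accuracy-threshold exceedance profile is monotone).

The rules ship both hard-coded (`diagnosis_rules()`) and as a versioned YAML
document (`inst/extdata/diagnosis_rules.yaml`); a test cross-checks the two.

## The synthetic-cohort generator

`simulate_cohort()` draws all 34 symptoms for `n` subjects from a Gaussian
copula. Within each of two blocks — the 20 depressive/dysthymic symptoms and
the 14 manic symptoms — latent standard normals share an exchangeable
correlation $\rho$; the blocks are independent, matching the design in which
manic symptoms do not correlate with the others. Each latent variable is
thresholded at the $(1-p)$ standard-normal quantile so the binary indicator
has marginal prevalence $p$.

The target correlation is the Pearson (phi) coefficient **of the binary
indicators**, not of the latent normals. `calibrate_latent_correlation()`
inverts the relationship by root finding on the bivariate-normal orthant
probability

$$\phi(\rho) = \frac{P_{11}(\rho) - p^2}{p(1-p)},\qquad
P_{11}(\rho) = \int_t^\infty \varphi(x)\,
\Phi\!\left(\frac{\rho x - t}{\sqrt{1-\rho^2}}\right) dx,\quad t = \Phi^{-1}(1-p),$$

with the integral evaluated by adaptive quadrature and the root located to
$10^{-6}$ in phi (`uniroot` tolerance $10^{-12}$ in $\rho$). At $p = 0.5$
this reduces to the closed form $\phi = \tfrac{2}{\pi}\arcsin\rho$, which the
tests use as an independent check. For equal marginals every
$\phi \in [0, 1)$ is feasible, and $\rho \ge \phi \ge 0$ always, so the
exchangeable latent matrix is positive semi-definite without further checks.

Because the latent correlation is exchangeable and nonnegative, it is
realised exactly by a single common factor per block,
$X_{ij} = \sqrt{\rho}\, W_i + \sqrt{1-\rho}\, E_{ij}$ with per-subject
$W_i$, which costs $O(nk)$ rather than a $k \times k$ Cholesky per draw and
leaves the subjects independent and identically distributed.

**What the generator emulates and what it does not.** It matches the study
conditions: uniform marginal prevalence in $\{0.05, 0.1, 0.3, 0.5, 0.7\}$,
uniform within-block phi in $\{0, 0.1, 0.4, 0.7, 0.9\}$, cohorts of 100,000,
and 100 replicates per cell at full scale. It does *not* emulate
heterogeneous per-symptom prevalences, non-exchangeable correlation,
negative correlation, or any higher-order joint structure beyond the Gaussian
copula's. Passing tests therefore certify the pipeline under exchangeable
copula populations, not the behaviour of the criteria in real clinical data.

## The classification trees

Trees mirror the clinical screening metaphor: split the population on the
single most informative symptom, then recurse. `fit_tree()` delegates
growing, cost-complexity pruning and 10-fold cross-validation to `rpart` —
the standard CART implementation in R — and re-expresses the result in the
package's own node structure (left branch = symptom absent), which supports
prediction, text rendering in the study's node format, and YAML round-trips.

Numerical and procedural choices:

* **Impurity:** Gini, with one candidate cut per (binary) predictor; ties go
  to the earliest catalogue column. Small-instance tests check the root
  split against exhaustive enumeration.
* **Pruning:** the weakest-link path; the complexity value selected is the
  one minimising the 10-fold cross-validated misclassification, with ties
  broken toward the smaller tree. The one-standard-error rule is available
  (`tree_control(one_se = TRUE)`) but is not the default: the reported trees
  at high prevalence keep exactly the two major-criteria splits, which is
  the minimum-error choice.
* **Prediction threshold:** a leaf predicts the diagnosis only when its
  class prevalence strictly exceeds 0.5; an exactly balanced leaf carries no
  evidence of disease and predicts 0.
* **Determinism:** growing and pruning are deterministic; the fold
  assignment is the only seed-dependent element and draws on the
  replicate's seed stream.
* **Degenerate labels:** a cohort in which the diagnosis never occurs yields
  a single-leaf tree with a trivial trace, and the replicate's accuracy
  fields are left undefined rather than imputed.
* **A tree that predicts no positives** while positives exist scores
  sensitivity 0, not undefined — it is a real classification failure, and
  treating it as missing would silently inflate averages.

**Node-size floors and scale.** The reference growth controls are
`minsplit = 20`, `minbucket = 7`, `cp = 0.01` at the full cohort size of
100,000 (`tree_control()` keeps those absolute values). Node-size floors are
sample-size-dependent regularisers: at a reduced cohort size they bind
relatively harder, and at low prevalence the pure leaves that encode "major
symptom plus two further items" hold only a handful of subjects, so a
desk-scale run with the absolute floors collapses rare-diagnosis trees to
the root. The experiment layer therefore defaults to `scaled_control(n)`,
which scales both floors proportionally to the cohort (exactly 20/7 at
100,000 subjects). The complexity floor is already relative to the root risk
and does not scale.

## The experiment grid and its bookkeeping

`run_grid()` runs one replicate per cell × repetition × disorder ×
predictor set, with per-replicate seeds derived from the master seed by a
counter-based scheme so any replicate is reproducible in isolation. The
`own` predictor set offers the disorder's own input symptoms; `extended`
offers all 34 symptoms plus the other two diagnoses as predictors.

`summarize_grid()` pools a complete grid over one margin (prevalence or
correlation) and reports, per level: replicate counts, the count with any
diagnosis, average/max/min/median number of split variables (over
replicates with any diagnosis), average/max/min sensitivity and specificity
(over replicates with defined metrics), the proportion of *all* replicates
whose $\min(\text{sens}, \text{spec})$ exceeds each threshold from 0.99 down
to 0.75 (an undefined metric never exceeds a threshold), and per-variable
usage frequencies. The $\min(\cdot)$ reading of "sen/spe > x" is the
conservative interpretation of the ambiguous row label; the exclusion of
no-diagnosis replicates from accuracy averages follows the 400-of-500
bookkeeping visible in the reported tables.

**Problem sizes.** The package's default grid is the deliberately
desk-scaled study: 25 cells × 10 replicates at n = 20,000 (about half a
minute of CPU), which is what the test suite and the acceptance script run.
The full-scale study (n = 100,000, 100 replicates) is the CLI's `--full`
flag and takes correspondingly longer; single full-scale cohorts are used
where a reported quantity was computed from one population of 100,000.

## Known limitations

* Uniform prevalence and exchangeable correlation are idealisations the
  original design acknowledges; real symptom panels are heterogeneous.
* The generator fixes only marginals and pairwise phi; any mechanism
  matching those is admissible, and higher-order moments are whatever the
  Gaussian copula implies.
* Under deterministic rules, several extreme reported cells (zero diagnoses
  at prevalence 0.05 with independent symptoms; specificity exactly 1 at
  prevalence ≥ 0.5; near-perfect sensitivity at prevalence 0.05 with
  independent symptoms) are unattainable; the package documents and tests
  the structural properties that do hold there instead.
* Exclusion criteria, symptom duration/severity, and DSM-5's merger of
  dysthymia into chronic depression are out of scope.
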