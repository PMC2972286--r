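---
title: "Pathway-level survival analysis: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level survival analysis: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Individual prognostic genes found in one breast-cancer expression cohort
replicate poorly in the next: platforms differ, cohorts differ, and single-gene
survival signals are weak relative to the multiplicity burden of testing
20,000+ genes. `pathsurv` implements the pathway-level alternative: score
each gene's association with censored survival *after adjusting for the
clinical covariates that already explain much of the outcome* (ER status,
tumor size), summarize gene sets with the maxmean statistic under a
restandardized permutation null, select pathways under a generalized
family-wise error criterion, and then turn each selected pathway into a
patient-level score — the pathway risk index (PRI) — that can stratify
survival inside clinically homogeneous cohorts such as ER-positive patients
or a fixed tumor grade.

# Models and procedures

## Cox scans

All survival modelling is Cox proportional hazards with Breslow tie
handling, fit by Newton-Raphson in compiled code (the permutation test
below refits on the order of $10^5$ per-gene models, so per-fit overhead
matters). Separation is caught by a coefficient cap and flagged
non-converged; collinear designs are flagged by a failed information-matrix
solve. `fit_cox()` agrees with `survival::coxph(..., ties = "breslow")` to
at least six decimals on well-posed problems, and with a brute-force
grid-search maximizer of the partial likelihood on tiny instances; both
checks are in the test suite.

Per-gene scans (`scan_genes()`) treat expression as a continuous covariate
— no dichotomization — under four model specifications: the gene alone,
gene + ER status + tumor size, and gene + the AIC- or BIC-selected clinical
model. The reported per-gene p-value is the 1-df partial-likelihood-ratio
test of the gene term. A log-rank test is undefined once continuous
covariates enter the model, and the likelihood-ratio test is its natural
multivariable analogue; the Wald p-value is reported alongside. Genes whose
fits fail keep a row with p = 1 so the multiple-testing denominator stays
fixed. Gene-level multiplicity is controlled by Benjamini-Hochberg at
q = 0.2 (`bh_fdr()`, via `stats::p.adjust`).

## Clinical model selection

`select_clinical_model()` scores candidate covariate sets by AIC
($-2\ell + 2p$) or BIC ($-2\ell + p\log d$, with $d$ the event count — the
standard effective sample size under censoring). Main effects are searched
exhaustively up to 10 candidates (forward-stepwise beyond), then pairwise
interactions among the selected main effects are added greedily while the
criterion improves; ties break toward smaller models, then lexicographic
order, so selection is reproducible. Complete cases are taken once over the
full candidate list rather than per model: information criteria compared
across models are only meaningful on a common likelihood, i.e. a common set
of subjects.

## Gene-set analysis: maxmean with restandardization

For a pathway with member scores $z_1,\dots,z_G$ (covariate-adjusted Wald
z-scores), the maxmean statistic is

$$ S = \begin{cases} s^+ & s^+ \ge s^- \\ -s^- & \text{otherwise}\end{cases},
\qquad s^+ = \tfrac1G\sum_i \max(z_i, 0),\;
s^- = \tfrac1G\sum_i \max(-z_i, 0). $$

Restandardization calibrates $S$ against the *gene catalog*: the
randomization step draws `R` random gene sets of the same size from all
scored genes and standardizes, $z^{restd} = (S - \hat\mu)/\hat\sigma$. The
permutation step permutes whole clinical rows (time, event, covariates)
jointly against the expression columns `B` times and recomputes everything
— including each permutation's own randomization moments, which keeps the
observed and null statistics exchangeable. The two-sided p-value is
$(1 + \#\{b : |z_b| \ge |z^{restd}|\})/(B+1)$, bounded below by $1/(B+1)$.

Permuting whole clinical rows is a deliberate choice: it breaks every
expression–outcome association while preserving gene–gene correlation and
the covariate–outcome relationship, which is exactly the null of interest
("this pathway adds nothing beyond the clinical model"). Sets are
size-filtered to 15–250 genes after intersection with the study's platform,
bounds inclusive; smaller sets are too noisy for a set statistic and larger
ones are uninterpretable. For tiny problems both randomization (all
$\binom{m}{G}$ subsets) and permutation (all $n!$ orderings) can be made
exhaustive, which is how the test suite checks the machinery against a
brute-force enumeration exactly.

Two numerical properties worth knowing: $z^{restd}$ is *exactly* invariant
to rescaling all gene scores by a positive constant (maxmean is positively
homogeneous), but it is **not** invariant to adding a constant to every
score — the randomization SD in the denominator is small, so even modest
location shifts move $z^{restd}$ noticeably. Restandardization tempers but
does not remove location effects; the permutation step is what delivers
valid p-values.

## Pathway selection: generalized Šidàk–Holm

With ~175 pathways and a discovery-oriented analysis, classical FWER is too
strict. `gfwer_sidak_holm()` controls the generalized family-wise error
rate — the probability of *u* = 5 or more false discoveries — at
$\alpha = 0.20$, by a Lehmann–Romano-shaped step-down with Šidàk-form
critical values

$$ c_i = 1 - (1-\alpha)^{u/m} \;(i \le u), \qquad
   c_i = 1 - (1-\alpha)^{u/(m+u-i)} \;(i > u). $$

Rejection proceeds along sorted p-values while $p_{(i)} \le c_i$. The
procedure is monotone (lowering a p-value never shrinks the rejection set)
and its gFWER control under a complete null is verified by simulation in
the acceptance suite.

## Pathway risk index

For subject $j$ and pathway $k$ with genes $i = 1..G_k$,

$$ \mathrm{PRI}(j,k) = \sum_{i=1}^{G_k} I(x_{ij} > \bar x_i), $$

the count of member genes expressed strictly above their mean $\bar x_i$
taken over **all** subjects in the study — even when a sub-cohort is being
stratified — so PRI values are comparable across cohorts.
`cohort_stratified_survival()` then median-splits PRI *within* the cohort
being analyzed (the analysis further stratifies survival within a subset of
patients, so the split respects that subset), labels subjects at or below
the median `low` and above it `high` (a deterministic tie rule that keeps
integer-valued strata balanced), and tests the high-vs-low indicator with a
single-covariate Cox Wald test; the log-rank p and Kaplan–Meier curves are
reported alongside. Cohorts with under 10 subjects or 2 events are refused,
and an all-constant PRI is flagged degenerate with no test. PRI ignores
mixed directions of dysregulation by design — it is a global activity
summary, not a signed enrichment score.

# The synthetic generator

`simulation_spec()` + `generate_multistudy()` produce the ground truth the
tests run on: several cohorts whose gene universes share a configurable
core (the remainder partitioned across studies, mimicking platform
differences), ER status and tumor size per subject, and survival from an
exponential proportional-hazards model — the simplest generator satisfying
the PH assumption every downstream model makes. Pathway signal enters as a
per-subject latent activity $a_j \sim N(0,1)$ added to each enriched
pathway member's expression, with log-hazard contribution
$\beta_{pathway} \cdot a_j$; PRI is then a noisy monotone readout of true
risk, which is exactly the role it plays in the analysis. Censoring is
independent exponential with its rate solved numerically so the expected
censored fraction hits the target.

Defaults were fixed once as plausible multi-study breast-cancer values:
five cohorts of 200, ER-positive prevalence 0.7, tumor size lognormal with
median 2 cm (sdlog 0.5), ER-negative log-hazard 0.6, 0.2 per cm of tumor
size, baseline hazard 0.04 per year, 60% censoring, unit expression noise.
Every (study, purpose) pair draws from its own seeded stream, so cohorts
are bit-reproducible regardless of generation order.

What the generator does *not* emulate: probe-level artifacts, two-color
ratio compression, batch effects, correlated pathway membership, or
non-proportional hazards. Passing tests therefore demonstrate that the
machinery is correct and calibrated under the stated model, not that real
cohorts satisfy that model.

# Validation sizes and numerical choices

The test suite's heavier checks run at sizes chosen to make 20-replicate
power studies practical on one core: two studies of n = 200, 300 genes, 20
pathways of 15–40 genes, B = 200 permutations and R = 200 randomization
sets for signal recovery; 200 replicates of an 80-gene null study for
calibration (permutation p-values and cohort Wald p-values are checked
against uniformity by Kolmogorov–Smirnov distance). Procedural bounds
(gFWER, BH-FDR) use 2000 replicates of pure p-value vectors, where the
procedures are cheap. Newton convergence uses a relative log-likelihood
tolerance of 1e-10 with step halving and a coefficient cap of 15;
permutation p-values use the add-one formula so they are never zero; the
randomization SD is floored at 1e-12 (a degenerate randomization yields
$z^{restd} = 0$ rather than infinity).

# Known limitations

- The per-gene p-value under covariate specifications is a likelihood-ratio
  test; field practice sometimes quotes log-rank p-values, which coincide
  only in the unadjusted two-group case.
- Multiple probes per gene are collapsed by mean before analysis; this is a
  convention, and PRI in particular is sensitive to the collapse rule.
- The restandardized statistic is not location-invariant (see above).
- gFWER control is proved for independent or positively dependent p-values;
  pathway overlap induces dependence the simulation suite does not model.
- The generator's exponential baseline cannot produce crossing hazards; PRI
  direction checks rely on positive gene loadings, matching its design.
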