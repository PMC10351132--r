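---
title: "Methods and design notes for lncpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for lncpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long non-coding RNAs (lncRNAs) can regulate signalling pathways, and in
bulk tumor transcriptomes their co-expression with pathway mRNAs is a
practical handle for finding candidate regulators. Two obstacles make
the naive correlation screen unreliable. First, tumor purity — the
fraction of malignant cells in a bulk sample — drives expression of
essentially every gene, so raw lncRNA–mRNA correlations are confounded.
Second, "is this lncRNA's co-expression concentrated in the pathway?"
is a gene-set question, not a per-gene question, and needs an
enrichment statistic with a calibrated null.

`lncpath` implements this screen and the analyses that typically follow
it: molecular subtyping of samples on the screened lncRNAs, immune
signature scoring of the subtypes, and a multi-lncRNA Cox risk model.
A synthetic cohort generator with planted ground truth makes every
stage testable without external data.

# Association: purity-adjusted partial correlation

For lncRNA $i$ and mRNA $j$ over $n$ samples, with tumor purity $p$,
the first-order partial correlation is

$$PCC_{ij} = \frac{R_{lm} - R_{lp}R_{mp}}
  {\sqrt{(1 - R_{lp}^2)(1 - R_{mp}^2)}},$$

where $R_{lm}$, $R_{lp}$, $R_{mp}$ are the Pearson correlations of
lncRNA with mRNA, lncRNA with purity, and mRNA with purity. This equals
the Pearson correlation of the two residual vectors after regressing
each expression vector on purity — the property the test suite uses as
an independent oracle.

Its two-sided p-value uses the Fisher z normal approximation for a
partial correlation with one adjusting covariate:
$z = \operatorname{atanh}(PCC)\sqrt{n - 4}$, $p = 2\Phi(-|z|)$. The
$n-4$ (rather than $n-3$) reflects the single covariate. A t-based
alternative would differ negligibly at the cohort sizes involved; the
normal form is used because the screen's downstream statistic only
consumes the ranking, which is identical under any monotone transform
of $|z|$.

mRNAs are ordered by the signed rank index

$$RI_{ij} = -\ln(P_{ij})\cdot\operatorname{sign}(PCC_{ij}),$$

descending, with ties broken lexicographically by mRNA id so rankings
are reproducible. Zero-variance genes are excluded (correlation is
undefined for them), not imputed.

# Enrichment and the TES screen

The ranking is tested against the pathway gene set with the classic
weighted Kolmogorov–Smirnov running sum (weight exponent 1): walking
down the RI ordering, a set gene increments the sum by
$|RI|/\sum_{set}|RI|$ and a non-set gene decrements it by
$1/(N - N_{set})$; the enrichment score ES is the signed maximum
deviation from zero (the positive branch is preferred on exact ties).
If every set gene has $|RI| = 0$ the weighted form is undefined and the
implementation falls back to the unweighted (exponent 0) sum with a
warning.

Significance, FDR and the composite statistic
$$TES = (1 - 2p)\cdot\operatorname{sign}(ES) \in [-1, 1]$$
are computed per lncRNA; lncRNAs with $|TES| > 0.99$ and
Benjamini–Hochberg FDR $< 0.05$ (both strict) pass the screen. The raw
permutation p enters TES and the FDR is a separate condition: with the
BH-adjusted p inside TES the FDR condition would be vacuous
($|TES| > 0.99 \iff p_{adj} < 0.005 \Rightarrow FDR < 0.05$), and at
1000 permutations a group of tied minimum p-values could never reach
$|TES| > 0.99$ after adjustment, so the two-condition screen is the
only coherent reading. `tes_p = "adjusted"` switches to the other
convention.

## Why sample permutation is the default null

Two permutation nulls are provided. `permutation_pvalue()` draws random
gene sets of equal size from the ranking — the classic preranked
scheme. `sample_permutation_pvalue()` permutes the lncRNA expression
across samples and recomputes the entire purity-adjusted ranking and ES
per permutation.

Gene-set permutation assumes exchangeable genes. Pathway mRNAs are not
exchangeable: they share regulation (in the generator, a latent
activity with loading $w \sim U(0.5, 1)$ against noise sd 1), so any
lncRNA's *spurious in-sample* correlation with that shared factor
displaces the whole set coherently in its ranking. The shared
displacement has variance $\approx w^2/(w^2 + \sigma^2)$ — independent
of sample size — and random gene sets can never mimic it, so the
gene-set null is anticonservative at any $n$: on null cohorts roughly
40% of lncRNAs passed the screen in our measurements. Permuting the
sample labels of the lncRNA instead preserves the mRNA inter-gene
correlation under the null and restores uniform p-values (planted
lncRNAs still reach the minimum attainable p). `run_tes()` therefore
defaults to sample permutation; the gene-set scheme remains available
for preranked inputs without expression data, with this caveat
documented.

Ordering by RI equals ordering by the partial correlation (the map is
monotone), so each permutation only needs the correlation vector, the
positions of the set genes within it, and $|RI|$ evaluated at the set
genes — this keeps 1000 permutations for 120 lncRNAs on a
200 × 1000-mRNA cohort around a minute.

# Consensus subtyping

Samples are clustered on the screened lncRNAs by PAM (k-medoids,
build + swap on a precomputed dissimilarity, via `cluster::pam`) with
the Spearman-correlation distance $d = 1 - \rho$ (average ranks on
ties). For each $k \in 2..10$, 500 subsamples of 80% of the samples
(drawn without replacement, keyed to sorted sample ids so results do
not depend on input order) are clustered; the consensus matrix entry is
the co-clustering rate among co-sampled replicates.

The number of clusters is chosen by minimizing PAC, the proportion of
consensus entries in the ambiguous band (0.1, 0.9), with the smallest k
winning ties. The older "relative change in area under the CDF" rule is
computed and reported as a diagnostic but not used for the choice: its
value at the smallest k is the raw area itself, which dominates the
curve and systematically elects $k = 2$ even on data with three
well-separated groups (measured: delta 0.50 at $k=2$ vs 0.34 at $k=3$
where PAC was 0.71 vs 0.000). PAC minimization is the published
refinement of exactly this diagnostic. The choice can always be
overridden (`k =` / `--k`).

Cluster labels are renumbered by decreasing size; the naming of
clusters is otherwise arbitrary and nothing downstream depends on it.

# Signature scoring and differential expression

* **ssGSEA** (`ssgsea_score`): per sample, genes are ranked by
  expression (descending, average ranks on ties; walk order ties broken
  by gene id); each signature is scored as the running difference of
  the rank$^\alpha$-weighted in-set ECDF and the unweighted out-of-set
  ECDF, summed along the ranking, with $\alpha = 0.25$. Unnormalized
  scores are invariant to strictly monotone per-sample transforms;
  min–max normalization across samples (the default output) makes
  scores comparable across signatures.
* **Marker means** (`marker_mean_score`): the mean log2 expression of a
  signature's markers — the MCP-counter-style abundance score; linear
  in expression.
* **ESTIMATE-like scores** (`estimate_like_scores`): unnormalized
  ssGSEA of a stromal and an immune set plus their sum. These are
  rank-based analogues, *not* the published trained ESTIMATE transform;
  tumor purity is an input to this pipeline, never derived from these
  scores. The shipped signature GMT
  (`inst/extdata/immune_signatures_synthetic.gmt`) carries small
  canonical-marker placeholder sets (the cytolytic-activity set is
  {GZMA, PRF1}); users should substitute their preferred curated lists.
* **Group tests** (`compare_groups`): one-way ANOVA for three or more
  groups, two-sided Wilcoxon rank-sum for two.
* **One-vs-rest DEG** (`one_vs_rest_deg`): per-gene Welch t-test on the
  log2 values, with the screen $|log2FC| > \log_2(1.2)$ and raw
  $p < 0.05$ (BH FDR reported alongside). This deliberately replaces a
  moderated (empirical-Bayes) t: at the cohort sizes targeted the
  moderation would mostly affect genes near the variance floor, and the
  screen's contribution is its threshold rule.

# The risk model

Candidate lncRNAs are screened by univariate Cox ($p < 0.05$, Wald) on
the training half of a seeded 1:1 split, reduced by Lasso-Cox
(`glmnet`, lambda by 10-fold cross-validated partial-likelihood
deviance; `lambda.min` by default — deliberately liberal, it feeds
passengers to the next stage; `lambda.1se` is available for sparse
selection), then refined by a bidirectional stepwise-AIC search over
unpenalized Cox fits: at each step every single-term removal and
re-addition is scored and the largest AIC decrease taken, stopping at a
local minimum. The final coefficients come from the unpenalized refit
(the only ordering under which a stepwise-selected model has its own
coefficients; the Lasso-path coefficients are recorded for comparison).

The risk score is the exact inner product
$\sum_i coef_i \cdot exp_i$. The median score *on the training set* is
the high/low cutoff and is reused unchanged on test and full cohorts.
Stratified survival is compared with a from-scratch log-rank test
(observed-minus-expected with hypergeometric variance, $\chi^2_1$);
discrimination at 1/3/5 years (365/1095/1825 days) uses the
cumulative/dynamic time-dependent AUC with inverse-probability-of-
censoring weights from the Kaplan–Meier estimate of the censoring
distribution. Cox fits use the Efron tie approximation throughout.
`multivariate_cox()` adds clinical covariates (first level
alphabetically as reference), returns the nomogram linear predictor,
and tabulates binned calibration (decile-mean predicted survival from
the uncentered baseline cumulative hazard vs the Kaplan–Meier estimate
in the bin).

A JSON fixture with the published six-lncRNA cervical-cancer model
(coefficients −0.442, 0.933, 0.333, −0.861, 1.27, 2.104; the two
negative signs follow the surrounding narrative of two protective
lncRNAs) ships in `inst/extdata/` and is the exchange format for
re-evaluation; its median cutoff is unpublished and stored as null.

# The synthetic cohort: a stated world

`generate_cohort()` draws, per sample: purity $p \sim Beta(5, 2)$
(entering all genes linearly on the log2 scale with loading 0.5 after
standardization — the simplest confounder that makes the adjustment
consequential), a latent pathway activity $a \sim N(0, 1)$ carried by
60 of 1000 mRNAs with loadings $w \sim U(0.5, 1)$, and per-gene noise
sd 1. Ten of 120 lncRNAs carry the activity with a common loading $v$;
survival follows an exponential-baseline Cox model
($h_0 = \ln 2 / 1095$ per day) on six of them; three balanced subtypes
shift five marker lncRNAs each (disjoint from the planted set) by +1.5
log2 units; censoring is independent exponential with its rate solved
to a 30% censored fraction; finally all values are shifted by +8
toward a nonnegative log2 scale (survival is generated before the
shift, so the emitted matrix recovers the same coefficients; about 1%
of values remain slightly negative and are deliberately not clamped,
which would distort the correlation structure).

Two calibration subtleties deserve record:

* **Association strength.** The mean purity-adjusted correlation
  between a planted lncRNA and the pathway mRNAs is
  $\mathbb{E}_w[vw/\sqrt{(v^2+\sigma^2)(w^2+\sigma^2)}]$, which has the
  finite ceiling $\mathbb{E}_w[w/\sqrt{w^2+\sigma^2}] \approx 0.59$ at
  the default noise level — slightly *below* the default target 0.6
  (the target is reachable only if the lncRNA were a noiseless readout
  of the activity). The solver therefore clips targets within 5% of
  the ceiling to 0.95 × ceiling (the equation is ill-conditioned
  there), yielding a realized mean correlation ≈ 0.56 at defaults, and
  raises an explicit infeasibility error beyond ceiling + 0.05.
* **Cox coefficients.** Because the risk lncRNAs are drawn from the
  planted associated set, they share the activity and are pairwise
  correlated ≈ 0.9. With equal-signed coefficients (the default,
  all +0.5) the signal concentrates in the shared direction: every
  risk lncRNA is marginally prognostic, the univariate → Lasso →
  stepwise chain succeeds end-to-end, but the linear predictor's sd is
  ≈ 9 and Cox partial-likelihood estimation saturates numerically, so
  joint coefficient *recovery* is not meaningful there. With
  alternating signs (±0.5) the shared component cancels (linear
  predictor sd ≈ 1.2) and the estimator recovers the coefficients —
  that regime is what the recovery tests use. Both regimes use
  $|\beta| = 0.5$.

## What a green test does and does not establish

The generator emulates the confounding structure, the planted-set
geometry, subtype shifts, and proportional-hazards survival — it does
not emulate count-level RNA-seq noise (negative binomial), batch
effects, non-proportional hazards, or realistic pathway topology
(every pathway mRNA loads on one factor). Recovery of planted truth
therefore validates the machinery and its calibration, not performance
on any real cohort; in particular, headline counts from real tumor
cohorts (numbers of screened or prognostic lncRNAs, cluster survival
p-values, DEG counts) are cohort-scale quantities that a desk-scale
synthetic world cannot and does not reproduce.

# Numerical conventions

* Ties: RI and walk orders break ties by gene id; PAM medoid ties
  resolve to the lowest index; cluster labels renumber by size; the
  running-sum extremum prefers the positive branch on exact ties.
* Degenerate inputs error early and name the offender: zero-variance
  vectors, purity-collinear expression, sets absent from a ranking or
  covering it entirely, empty strata, missing model genes.
* p-values are floored at the smallest positive double; permutation
  p-values use the add-one form $(1 + \#exceed)/(1 + B)$ and can never
  be 0.
* All randomness is seed-driven; per-lncRNA and per-replicate seeds are
  drawn from a master seed so results do not depend on iteration
  order. Same seed, same bytes — cohort writes round-trip bit-exactly
  (`%.17g`).
* TSV/GMT/JSON are the only interchange formats; expression is assumed
  already log2-normalized and is never renormalized.

# Known limitations

* The ESTIMATE-like scores are rank-based stand-ins, not the published
  trained transform; purity must be supplied.
* The gene-set permutation null is anticonservative under inter-gene
  correlation (see above); it is kept for preranked-only inputs.
* `stepwise_aic` is a greedy local search; the tests check it lands
  within the top of the exhaustive ranking on small instances, not
  global optimality.
* Time-dependent AUC assumes censoring independent of the score;
  IPCW weights are marginal Kaplan–Meier, not covariate-adjusted.
* The CLI covers the pipeline's main paths; programmatic use offers
  more control (e.g., permutation scheme selection).
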