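---
title: "Linking protein stability and solvent accessibility to missense pathogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking protein stability and solvent accessibility to missense pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabpath)
```

## The scientific question

Most missense variants in genes causing monogenic (Mendelian) disorders are
of uncertain significance. One mechanistic hypothesis is that many
pathogenic substitutions act by destabilising the folded protein: if so, the
predicted folding free energy change

$$\Delta\Delta G = \Delta G_{wt} - \Delta G_{mut}$$

(negative = destabilising, in kcal/mol) should separate pathogenic from
benign variants, and the burial of the mutated residue — its relative
solvent accessibility, RSA in [0, 1] — should add independent signal,
because buried residues are more often structurally critical. This package
implements that analysis chain: curation of a ClinVar-style variant table,
substitution categorisation by chemical character, cutoff-sweep ROC and
Matthews-correlation threshold scans, balanced resampling assessment, an
L2-penalised logistic model on ($\Delta\Delta G$, RSA), and saturation
profiling, with a synthetic generator standing in for the database and the
external predictors.

## Curation model

The curation pipeline mirrors how such variant sets are assembled:

1. **Label policy.** ClinVar-style labels come in four classes. The strict
   policy keeps only `benign`/`pathogenic`; the inclusive policy folds
   `likely_benign`/`likely_pathogenic` into their parent classes. Both
   are exposed via `curation_config(include_likely = )`.
2. **Population frequency.** Benign variants with frequency strictly below
   0.01 and pathogenic variants strictly above 0.01 are excluded (a benign
   call for a variant never seen in populations, or a pathogenic call for a
   common one, is suspect). A frequency of exactly 0.01 survives both
   rules, matching the strict wording "below"/"above"; missing frequencies
   are retained, because real ClinVar records frequently lack one and
   excluding them would gut the table.
3. **Conflict flag.** Records with discrepant clinical significance across
   sources are dropped.
4. **Gene balance.** A gene is kept only when both its benign and its
   pathogenic fraction strictly exceed 10%. This guards the per-gene
   analyses against genes ascertained one-sidedly. We read the criterion
   conjunctively (both fractions), and apply it strictly: a 9:1 gene sits
   exactly at 0.10 and is dropped.

The filter order is fixed (labels, frequency, conflict, gene balance), so
gene balance is computed on records that survived the earlier filters; the
source protocols are ambiguous on this point, and the order affects which
drop bucket a record lands in far more than the final set. `curate()`
returns a report whose counts reconcile exactly
(`n_input = n_output + sum(drops)`), and curation is idempotent.

## Substitution categories

Residues are grouped on four axes: hydropathy (hydrophobic:
A C G I L M F P W V; polar: the rest), size (small:
A C G S N D P T V; large: the other 11), ring character (aromatic:
H F W Y; aliphatic: A I K L M P V — note Lys is kept in the aliphatic
group, following the grouping scheme this analysis adopts even though a
chemist might quibble) and charge (positive: H K R; negative: D E). A
directed substitution belongs simultaneously to one category per axis on
which *both* residues carry a named group — hydropathy and size always
contribute, ring and charge only away from "neither"/"neutral" — so every
substitution has 2–4 categories and no precedence rule is needed. Counts
below ~100 cases per category are too sparse for stable per-category AUCs
and are filtered with a strict `> min_total` rule.

## Threshold evaluation

Scores are oriented so that *lower = more pathogenic* ($\Delta\Delta G$:
destabilising; RSA: buried); the absolute-$\Delta\Delta G$ score uses the
opposite direction. Decisions are `score <= cutoff`.

* **ROC/AUC** sweeps the cutoff over every distinct score; equal scores
  collapse into a single step, which makes the trapezoid AUC identical to
  the concordance probability with ties scoring one half (the package
  carries an independent pair-counting implementation, `auc_by_pairs()`,
  used to verify this equivalence in the tests).
* **MCC scans** evaluate the Matthews correlation coefficient on a fixed
  grid — one-decimal steps over ±5 kcal/mol for $\Delta\Delta G$,
  two-decimal steps over [0, 1] for RSA, matching the granularity at which
  optimal cutoffs are conventionally reported. MCC uses the standard
  binary formula with the 0/0 := 0 convention; ties in the optimum go to
  the smallest-magnitude cutoff, then to the smaller value, so the reported
  threshold is the most conservative of the equally good ones.
* **Balanced resampling** draws $N = \lfloor 0.5\,\min(n_b, n_p)\rfloor$
  records per class without replacement, computes TPR/FPR/FNR/accuracy at
  a fixed cutoff, and repeats 100 times. `compare_methods()` evaluates all
  methods on the *same* drawn sample each repetition, so between-method
  contrasts are paired and sampling noise largely cancels; external
  pathogenicity classifiers enter as precomputed call columns.

## The logistic model

`fit_logistic()` maximises the binomial log-likelihood penalised by
$\|\beta\|^2/(2c)$ with the intercept unpenalised; $c$ is the inverse
regularisation strength. Features are standardised to zero mean and unit
variance on the training data (stored on the model, reapplied at prediction
time) so that one $c$ grid — {0.001, 0.01, 0.1, 1, 10, 100, 1000} — is
meaningful across feature sets. The optimiser is damped Newton–Raphson:
step halving enforces monotone objective decrease far from the optimum, and
the full Newton step is taken once the predicted decrease falls below the
objective's rounding noise, giving quadratic convergence to a gradient norm
of 1e-8. The training protocol balances classes first (downsampling the
majority), then splits 80/20 stratified, selects $c$ by repeated stratified
5-fold cross-validation (maximum mean held-out AUC; ties to the smaller
$c$), refits on the full training portion, and reports AUC and MCC on both
portions. The probability cutoff for MCC is 0.5 — the natural point on a
balanced training set.

## The synthetic generator

The generator produces the statistical structure the analyses above
assume, without emulating any real predictor:

* **Latent $\Delta\Delta G$.** Each variant has one latent "true" value
  drawn from a class-conditional two-component truncated-normal mixture.
  The pathogenic mixture places exactly 70% of its mass strictly below 0
  (components: N(−1.6, 1.2) truncated negative, weight 0.70; N(0.4, 0.8)
  truncated non-negative) — the destabilised fraction reported for real
  pathogenic variants. The benign mixture (45% below 0; N(−0.5, 0.8) /
  N(0.6, 0.9)) overlaps it substantially, which is what keeps single-score
  AUCs in the realistic 0.66–0.78 band rather than at fantasy values.
* **Predictors.** Each predictor column is latent + independent Gaussian
  noise (defaults: 0.6, 1.5 and 0.8 kcal/mol), so predictors are mutually
  correlated through the shared latent value; the 1.5 kcal/mol predictor
  is deliberately weak, and averaging the two good predictors beats any
  single one — the ordering the pipeline is expected to reproduce. One
  predictor is emitted with the opposite sign convention to exercise
  ingestion normalisation.
* **RSA.** Class-conditional Beta laws, pathogenic B(2, 3.8) (mode 0.26,
  buried) and benign B(2.6, 2.1) (mode 0.59, exposed), chosen once to give
  an RSA AUC near 0.78. Coupling to $\Delta\Delta G$ uses a rank-based
  Gaussian copula at correlation 0.1, weak enough that the two features
  contribute near-independently (their pooled correlation stays below 0.3)
  while preserving the exact Beta marginals.
* **Curation truth.** Frequency violations, conflict flags and one-sided
  genes are planted at configurable rates; compliant frequency draws stay
  clear of the 0.01 boundary so the planted set is unambiguous. A sidecar
  records every planted value and each record's survivor status under both
  label policies, computed at generation time by a plain counting pass, so
  curation tests can demand exact set equality rather than counts.

What the generator does *not* model: sequence-dependent predictor error
(noise is homoscedastic and Gaussian), shared bias between predictors,
per-gene effect heterogeneity, and the long-tailed site-frequency spectrum.
Tests passing on this data therefore demonstrate the *machinery* —
filters, metrics, optimiser, protocol — and the qualitative orderings, not
performance on real variant tables.

## Saturation profiling

`enumerate_mutations()` generates the 19·L single substitutions of a
protein (positions with non-canonical residues are skipped and logged —
which is also why real proteome-scale substitution totals are rarely
divisible by 19). Pathogenicity is called at $\Delta\Delta G \le -1.1$
kcal/mol, the optimal-MCC cutoff for this kind of score; the boundary value
is called pathogenic. The module never computes $\Delta\Delta G$ itself —
values arrive from an external predictor or from the synthetic oracle,
which plants a configurable sub-cutoff mass (0.37 by default, the fraction
reported when profiling a real monogenic-disorder proteome).

## Numerical choices and problem sizes

Defaults everywhere were chosen once, as the study conditions: 3000
variants per class in the generator (large enough that binomial error on a
70% fraction is ±2.5% at 3 s.e.), 100 resampling repetitions, 100 CV
repetitions in the full protocol (the bundled analysis scripts use 25 per
model across six models, which leaves the selected $c$ unchanged on data
this size), saturation length 1000 for calibration checks. The test suite
runs the same machinery at smaller n chosen so the whole suite completes in
well under a minute. Known limitations: the logistic model is the only
classifier family; no probability calibration; ROC confidence bands and
paired AUC tests are out of scope; and the curation module does not decide
isoform selection — that is upstream data preparation.
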