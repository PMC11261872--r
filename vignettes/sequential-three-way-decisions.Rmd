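---
title: "Sequential three-way decisions over similarity granulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential three-way decisions over similarity granulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rough3wd)
```

## The model

Three-way decision making classifies each object of a universe $U$ into one
of three regions with respect to a concept $X \subseteq U$: accept
(POS), reject (NEG), or defer (BND).  In the decision-theoretic rough-set
formulation the assignment compares a concept-membership probability
$\Pr(X \mid c)$ with a pair of thresholds $(\alpha, \beta)$,
$0 \le \beta < \alpha \le 1$:

$$
c \in \mathrm{POS} \iff \Pr(X \mid c) \ge \alpha, \qquad
c \in \mathrm{NEG} \iff \Pr(X \mid c) \le \beta,
$$

and BND otherwise.  The thresholds are not free parameters: they are induced
by a $3 \times 2$ loss matrix $\lambda_{a s}$ (cost of action
$a \in \{P, B, N\}$ in state $s \in \{X, X^c\}$) through the Bayesian
minimum-risk rules.  Solving $R(a_P \mid p) \le R(a_B \mid p)$ and
$R(a_N \mid p) \le R(a_B \mid p)$ for $p$ gives

$$
\alpha = \frac{\lambda_{PN}-\lambda_{BN}}
             {(\lambda_{PN}-\lambda_{BN})+(\lambda_{BP}-\lambda_{PP})},
\qquad
\beta  = \frac{\lambda_{BN}-\lambda_{NN}}
             {(\lambda_{BN}-\lambda_{NN})+(\lambda_{NP}-\lambda_{BP})}.
$$

These closed forms are derived, not quoted, so `thresholds_from_losses()` is
guarded by a brute-force equivalence test: for randomly drawn valid loss
matrices, the threshold rule and the minimum-risk rule must agree at every
point of a dense probability grid.  Risk ties are broken in the order
P over B over N — the unique order consistent with the boundary-inclusive
comparisons ($\ge \alpha$, $\le \beta$) of the threshold form.

```{r}
loss <- loss_matrix(0, 1, 4, 4, 1, 0)
thresholds_from_losses(loss)
```

## Sequential classification

A single pass usually leaves a non-empty boundary.  Sequential
decision-theoretic rough sets re-classify the deferred objects level by
level: the boundary of level $i$ becomes the universe of level $i+1$,
$U_{i+1} = \mathrm{BND}_i$, the concept is restricted to it,
$X_{i+1} = X_i \cap \mathrm{BND}_i$, and POS/NEG accumulate by union.
The classical engine (`seq_dtrs()`) granulates each level with an
equivalence partition (identical attribute values), which in practice means
dropping attributes between levels — and with them, information.

The generalized engine (`gseq_dtrs()`) keeps all attributes at every level.
Instead of coarsening the attribute set, it granulates the max-normalized
table with similarity classes

$$
S_\xi(c) = \{\, y \in U : S(c, y) \ge \xi \,\}, \qquad
S(c, y) = 1 - \frac{\sum_l |f(c, a_l) - f(y, a_l)|}
                    {\sum_l \bigl(f(c, a_l) + f(y, a_l)\bigr)},
$$

a Bray–Curtis-style ratio of sums.  These classes overlap, forming a
covering rather than a partition, so the membership probability generalizes
to the covering-based rough membership function: over all classes $S$
containing $c$ (one candidate class per owner object), take the ratios
$|S \cap X_i| / |S|$ and aggregate by minimum, maximum, or average.  The
average is the default — it is the most stable of the three and is the one
the sequential engine is designed around; minimum and maximum are exposed
for sensitivity analysis and testing.  On a partition all three collapse to
the classical $|[c] \cap X| / |[c]|$, and at $\xi = 1$ the whole engine
degenerates to the classical one — a bridge property the test suite checks.

Two scope rules matter and are easy to get wrong:

* **Classes are computed over the full universe at every level**, never over
  the shrinking sub-universe.  Only the numerator concept $X_i$ shrinks.
  This is what makes the worked five-object example below reproduce.
* **Class denominators are full class sizes**, even when some class members
  have already been classified at earlier levels.

```{r}
fix <- example_fixture("fiveobj_gseq")
fit <- gseq_dtrs(fix$table, xi = fix$xi, thresholds = fix$thresholds)
summary(fit)
accumulate_regions(fit)
```

The run exhausts the boundary in three iterations; the per-level grid is
available as `level_counts(fit)` and the full per-object trace as
`as.data.frame(fit)`.

## Tunable parameters

* `xi` (per level, in $(0, 1]$): similarity resolution.  Larger values give
  smaller, purer classes.  The worked example uses an increasing schedule
  (0.59, 0.6, 0.7): refining the granulation between levels is what breaks
  the membership ties that a fixed granulation would carry forever.
  $\xi = 0$ is disallowed (every class would be $U$); $\xi = 1$ is admitted
  for the degenerate-limit bridge.
* `alpha0`, `beta0`, `step`: the linear threshold schedule
  $\alpha_i = \alpha_0 - (i-1)\,\mathrm{step}$,
  $\beta_i = \beta_0 + (i-1)\,\mathrm{step}$, truncated before
  $\alpha_i \le \beta_i$.  A wide initial gap with a small step defers more
  and iterates longer; `sensitivity_sweep()` quantifies the trade-off.
* `mode`: membership aggregation, default `"average"` (see above).
* `force_assign` (default off): a terminal non-empty boundary is a valid
  outcome — abstention is the point of the third region — but users who
  need a dichotomous answer can force the leftovers to POS/NEG by majority
  membership.

## Numerical choices and degenerate inputs

* All region comparisons are boundary-inclusive exactly as in the rule
  form: $p \ge \alpha$ accepts, $p \le \beta$ rejects.
* Similarity of two all-zero attribute vectors is defined as 1 (they are
  identical; the 0/0 ratio is resolved by that limit).
* Max-normalization of an all-zero column yields zeros with a warning: a
  constant column is similarity-inert either way.
* Negative attribute values are rejected, not shifted — the ratio-of-sums
  similarity assumes nonnegativity, and any shift is a modelling decision
  that belongs to the user.
* The decision attribute is binary; the positive label is declared, never
  guessed.  Row order of the input is the canonical object order.
* Memberships are exact rational arithmetic evaluated in doubles; worked
  values such as $13/18 = 0.7\overline{2}$ are reproduced to full double
  precision.

## The synthetic generator

`generate_clinical_table()` emulates the role of a clinical feature table
with a binary outcome: a chosen number of informative attributes whose
class-conditional means differ by `separation` noise-scale units, plus
noise attributes identically distributed in both classes, all drawn from
normals truncated at zero by clipping.  The baseline mean is
$2 \times$ `noise_scale` so the negative class sits away from zero —
under a ratio-of-sums similarity, values near zero inflate relative
differences and would make even same-class objects look dissimilar.
Defaults (n = 100, 3 informative + 2 noise attributes, separation 5,
positive fraction 0.5) describe a well-separated cohort; at that
separation a run with the schedule $(\alpha_0, \beta_0, \mathrm{step}) =
(0.9, 0.1, 0.0175)$ and $\xi = 0.75$ recovers the true labels almost
perfectly, and the test suite requires at least 95% of objects to land in
the label-matching region.  The $\xi = 0.75$ default sits midway between
the expected within-class and between-class similarities under these
defaults.

What the generator does *not* emulate: real clinical marginals (skewness,
categorical mixtures, missingness), correlated attributes, or label noise.
Passing the recovery test therefore shows the engine separates separable
classes through the similarity granulation — not that any particular
clinical dataset would be classified with that accuracy.

Problem sizes throughout the test suite (hundreds of random loss matrices,
coverings of up to ten objects, tables of 10–100 rows) were chosen so that
each property is exercised across its combinatorial range while the whole
suite stays interactive.

## Design decisions on genuinely open points

* **Owner-based class enumeration.**  "All classes containing $c$" is read
  as one candidate class per object $y$ with $c \in S_\xi(y)$; set-equal
  classes owned by different objects each contribute a term.  This is the
  only reading that reproduces the worked value
  $\Pr(X_1 \mid c_1) = (1/2 + 1/2)/2 = 0.5$, where both terms come from the
  equal classes of $c_1$ and $c_2$.
* **Level-2 concept of the worked example.**  The five-object walk-through
  contains an inconsistent intermediate listing of $X_2$; applying the
  definition $X_2 = X_1 \cap \mathrm{BND}_1 = \{c_1, c_3\}$ reproduces all
  printed level-2 and level-3 regions, so the engine follows the
  definition.
* **Explicit-partition input for the classical engine.**  The
  twelve-patient fixture's three granulations do not satisfy refinement
  monotonicity and cannot be generated from any single attribute table;
  `seq_dtrs()` therefore accepts explicit partitions as first-class input,
  and the fixture ships them as givens.
* **Cumulative accuracy.**  Abstaining classifiers admit several accuracy
  notions; `classification_accuracy()` reports accuracy over the objects
  classified so far (deferred objects excluded from the denominator,
  `NA` before anything is classified).  This is an interpretation, flagged
  as such in its documentation.  Accuracy monotonicity across levels is
  reported, never asserted: it is an empirical tendency, not a theorem.

## Known limitations

* Binary decisions only; multi-class tri-partitions are out of scope.
* One similarity kernel (ratio of sums); cosine or Gaussian kernels would
  slot into `similarity_matrix()` but are deliberately not offered.
* No missing-value handling or imputation.
* The classifier is transductive: it partitions the supplied universe, and
  there is no out-of-sample `predict()` rule.
* Attribute-reduct search is intentionally absent — avoiding reduction is
  the generalized engine's reason to exist.
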