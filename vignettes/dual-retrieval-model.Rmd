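---
title: "Dual-retrieval modeling of three-test free recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-retrieval modeling of three-test free recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualrecall)
```

## The model

`dualrecall` analyses categorized-list free recall experiments in which every
studied item is tested on three successive recall tests, so that each item
contributes one of $2^3 = 8$ correct/error patterns (`EEE` … `CCC`, with test
1 as the most significant bit). The dual-retrieval model explains these
patterns with two dissociated retrieval routes, following the fuzzy-trace
distinction between verbatim and gist memory traces:

* **Direct access** (probability $D$): the item's verbatim trace can be
  retrieved, and while that state holds the item is recalled with certainty.
  After test 1, and again after test 2, the state survives with probability
  $1 - F$; once lost, the item is unrecallable on all remaining tests. The
  verbatim route therefore produces only the patterns `CCC`
  ($D(1-F)^2$), `CCE` ($D(1-F)F$) and `CEE` ($DF$).
* **Reconstruction plus familiarity** (probability $(1-D)R$): when direct
  access fails, the item may be reconstructable from gist. A reconstructed
  item is output on test $t$ when it passes a familiarity judgment,
  independently with probability $J_t$; this route reaches all 8 patterns
  with probability $\prod_t J_t^{c_t}(1-J_t)^{1-c_t}$.
* **No usable trace** (probability $(1-D)(1-R)$): the item is never recalled.

Two structural choices deserve comment, because the pattern equations can be
set up in more than one way. First, a single forgetting rate $F$ is shared by
both inter-test intervals. Second, items whose direct access is forgotten do
*not* re-enter the reconstruction route. Both choices follow the parameter
definitions the model was built around, and they are what gives the model
exactly $8 - 1 - 6 = 1$ residual degree of freedom, so that the goodness-of-fit
statistic is $G^2(1)$. Test-varying forgetting, item heterogeneity, and more
than three tests are out of scope.

The assumptions worth keeping in mind: items are independent and identically
distributed given a condition's parameters, and items are pooled across the
participants of a condition. Participant heterogeneity is ignored — each
condition gets one parameter vector — which matches how such condition-level
fits are usually reported but means the $G^2$ test is a test of the pooled
multinomial, not of any individual participant.

## Estimation and inference

`drm_fit()` maximizes the multinomial log-likelihood over
$[10^{-6}, 1-10^{-6}]^6$ with L-BFGS-B and analytic gradients, from a fixed
midpoint start plus `n_starts` (default 20) Latin-hypercube starts; ties
between starts within $10^{-9}$ in the objective are broken by the
lexicographically smaller parameter vector, so a fit is a deterministic
function of the data and the seed. Fit is summarized by
$G^2 = 2\sum_k O_k \ln(O_k / n\hat\pi_k)$ on 1 df, with the conventions
$0\ln 0 = 0$ and expected probabilities floored at $10^{-12}$ inside the
logarithm; an expected probability of exactly zero under observed mass makes
the statistic infinite, with a warning. Estimates within $10^{-4}$ of the box
bounds are flagged `boundary`; their p-values still use $\chi^2(1)$, the
conventional (if anticonservative) practice, with the flag as the caveat.

Cross-condition hypotheses are tested with `drm_lr_test()`:
$\Delta G^2 = G^2(\text{joint fit, parameter equated}) -
[G^2(a) + G^2(b)]$ on 1 df. The 11-parameter joint fit is warm-started at the
free optima with the shared parameter averaged, in addition to the random
starts. Small negative $\Delta G^2$ (within $10^{-6}$, optimizer noise) is
floored at zero; anything more negative raises an error rather than being
silently clipped, since it means the free fits were not at their optima.
`fit_conditions()` runs the whole battery — per-condition fits plus, within
each list organization, the three condition pairs (item vs none, list vs
item, list vs none) for all six parameters. The battery reports raw p-values,
because these are planned single-df comparisons; Holm-adjusted values are
available behind `holm = TRUE`.

## Category clustering (ARC)

`arc()` scores one test's recall output order. With $n_i$ items recalled from
category $i$, $N = \sum_i n_i$, $k$ recalled categories and
$m = \max_i n_i$, the number of adjacent same-category repetitions $R$ is
compared with its chance expectation $E(R) = \sum_i n_i^2/N - 1$,
$\max R = N - k$, and $\min R = 0$ if $N + 1 \ge 2m$, else $2m - N - 1$:

$$\mathrm{ARC} = \begin{cases}
\dfrac{R - E(R)}{\max R - E(R)} & R > E(R)\\[1ex]
\dfrac{R - E(R)}{E(R) - \min R} & R < E(R)
\end{cases}$$

The piecewise formula is silent at $R = E(R)$; both numerators are zero
there, so we define ARC $= 0$, the chance-clustering anchor. ARC is reported
as undefined — never an exception, and excluded from condition means with a
logged count — when $N \le 1$, $k = 1$, or the applicable denominator is
zero. Before scoring, repeated recalls of a word within a test are collapsed
to their first occurrence and intrusions are dropped; the literature rarely
states either rule, so both are explicit here and the deduplication happens
in the scorer where it can be audited.

## The synthetic experiment generator

`generate_experiment()` emulates a 2 (list organization: blocked, randomized)
× 3 (JOL condition: item, list, none) between-participants design: 240
participants allocated to the six cells balanced within one, 40 study words
composed of 8 exemplars from each of 5 taxonomic categories, item JOLs on a
0–100 scale, list JOLs as integers 0–8 attached to each list's final word,
and three-test recall. Blocked orders present each category contiguously;
randomized orders are rejection-sampled (up to 10,000 tries) so that no more
than 3 consecutive words share a category, then cut into five 8-word lists.

Defaults are chosen to be realistic for this paradigm:

* `true_params`: one parameter vector per cell, with direct access around
  0.25–0.42, forgetting 0.05–0.10, reconstruction 0.10–0.20 and familiarity
  judgments rising across tests. The randomized item-JOL cell's $J_1$ (0.54)
  is elevated over its no-JOL counterpart (0.34) — the familiarity-driven
  JOL-reactivity signature this pipeline is designed to detect.
* `list_jol_means`: 4.89 (blocked) vs 3.73 (randomized), SD 1.19/1.06 —
  list-level predictions are sensitive to organization.
* `item_jol_mean = 50, item_jol_sd = 25`: mid-scale with wide spread;
  condition-level item-JOL means are not well pinned down empirically, so
  these are free parameters of the generator.
* `clustering_weight = 0.5`: the recall output order follows a
  category-biased sequential draw — with this probability the next output
  stays in the current category when possible, otherwise it is uniform over
  the remaining recalled items. 0 reproduces the permutation null
  (mean ARC ≈ 0), 1 forces perfect contiguity (ARC = 1); 0.5 yields the
  moderate clustering typical of randomized categorized lists.

Deliberate simplifications, which bound what green tests show about real
data: recall outcomes are independent across items and participants given the
cell's parameters (no serial-position effects, no participant random
effects); JOL values do not feed back into recall (any reactivity is encoded
in the cell-specific `true_params`, i.e. the *task*, not the rating, carries
the effect); and word tokens are synthesized as `<category>_<index>` unless a
lexicon is supplied. A pipeline that is well calibrated on this generator has
been shown to handle the multinomial sampling noise of the design, not
participant heterogeneity or item effects.

## Scoring and screening

`score_recall()` normalizes typed responses (lower-case, trimmed, internal
whitespace collapsed), matches them to study words exactly or at edit
distance ≤ `tolerance` (default 1, nearest match, ties to the first-listed
study word), consumes each study word at most once, collapses within-test
duplicates and logs intrusions. `outlier_filter()` implements the screening
rule exactly as it is usually printed: exclude participants whose mean recall
exceeds their cell's *median* plus 1.5 IQR — upper-sided and median-anchored,
which is not the same as Tukey's quartile-anchored fences; a symmetric
variant sits behind `symmetric = TRUE`. Quartiles use linear interpolation
(`quantile()` type 7), which published reports rarely state; cells with fewer
than 4 participants are left unscreened with a warning.

## Reporting

`one_way_anova()` and `pairwise_lsd()` implement the planned behavioral
comparisons: a fixed-effects one-way ANOVA per list organization on test-1
recall with MSE and partial eta squared, followed by Fisher's LSD —
deliberately unadjusted pairwise t tests on the ANOVA's pooled error term,
with Cohen's $d = (M_a - M_b)/\sqrt{MSE}$. The clustering follow-up is a
one-tailed pooled-variance t test comparing test-1 ARC between the item-JOL
and no-JOL randomized cells. ARC is computed per test but reported for test 1
by default, where output-order strategy is least contaminated by earlier
retrievals. A full factorial mixed-model ANOVA over organization × JOL × test
is routine with standard software and is intentionally not reimplemented;
`run_recall_analysis()` notes per-test one-way analyses instead.

## Numerical and test-design notes

The test suite checks the likelihood against an independent path-enumeration
oracle (1,000 random parameter vectors, exact to $10^{-12}$), the
chance-repetition formula against Monte-Carlo permutation (within 3 MC
standard errors), parameter recovery (mean signed bias under 0.02 per
parameter over 200 replicates of 4,000 items), the equality test's type-I
rate (within [0.03, 0.07] over 2,000 null replicates of 320 items each),
Kolmogorov–Smirnov uniformity of the null p-values at a sample size where the
$\chi^2(1)$ asymptotics apply (1,000 replicates of 2,000 items — at 320
items the test is mildly anticonservative, which the type-I band already
tolerates), and detection
of the seeded $J_1$ effect at the design's cell size (~1,600 items). These
problem sizes are the package's chosen verification scale: large enough for
the asymptotics the tests rely on, small enough that the whole suite runs in
a few minutes on one core.

## Known limitations

Condition-level pooling ignores participant heterogeneity; hierarchical or
Bayesian multinomial-processing-tree estimation is future work, as are
bootstrap confidence intervals, other clustering indices (RR, MRR, LBC), and
semantic-similarity response matching. Boundary estimates keep the
$\chi^2(1)$ reference despite its known conservatism issues at the boundary.
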