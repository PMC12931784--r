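---
title: "Consensus-aware fuzzy FMEA: models and methods in zefmea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-aware fuzzy FMEA: models and methods in zefmea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zefmea)
```

## The problem

Failure Mode and Effects Analysis (FMEA) prioritises the failure modes of a
process by scoring each on Severity (S), Occurrence (O) and Detection (D).
The classical Risk Priority Number, RPN = S × O × D on integer 1–10 scales,
has well-known defects: it treats the three factors as equally important,
ignores how confident an expert is in a rating, and ignores whether the
rest of the panel agrees with it.  `zefmea` implements an integrated
alternative for expert-panel assessments such as medicinal plant
extraction, where judgments are linguistic, uncertain, and of uneven
credibility:

1. ratings are **triangular fuzzy numbers** (TFNs) bound to linguistic
   terms;
2. each rating carries a fuzzy **reliability** term, and the pair forms a
   Z-number; a group **consensus vote** (agree/disagree/neutral) further
   moderates the reliability, forming a ZE-number;
3. criterion weights come from the fuzzy **Best–Worst Method** (BWM);
4. failure modes are ranked by **MABAC** (Multi-Attributive Border
   Approximation area Comparison), i.e. by their signed fuzzy distance
   from a per-criterion geometric-mean border.

## Fuzzy algebra

A TFN $(l, m, u)$, $l \le m \le u$, has the piecewise-linear membership
peaking at $m$.  The package implements the standard extension rules

$$A \oplus B = (l_1{+}l_2,\, m_1{+}m_2,\, u_1{+}u_2), \qquad
  A \ominus B = (l_1{-}u_2,\, m_1{-}m_2,\, u_1{-}l_2),$$
$$A \otimes B = (l_1 l_2,\, m_1 m_2,\, u_1 u_2), \qquad
  A \oslash B = (l_1/u_2,\, m_1/m_2,\, u_1/l_2),$$

with $\otimes$ and $\oslash$ restricted to nonnegative (resp. strictly
positive) operands — every in-scope quantity is nonnegative except the
MABAC distances, which only use $\ominus$.  Subtraction deliberately
widens the interval, so `a - a` is not zero but a symmetric TFN with
centroid zero.  Two defuzzifiers are exposed:

* **GMIR** (graded mean integration), $(l + 4m + u)/6$ — used for crisp
  reliability values and for the weight-normalisation constraint;
* **centroid**, $(l + m + u)/3$ — the default for final scores.

The split is an explicit design decision: GMIR applied to the reliability
terms reproduces the bundled case study's converted decision matrix where
the centroid does not (for the very-high term $(0.7, 1, 1)$, GMIR gives
0.95 while the centroid gives 0.90), whereas the centroid applied to the
recorded final score triples reproduces both recorded defuzzified score
columns to ±0.01, which GMIR does not.  Both operators are available
everywhere via the `method`/`defuzzifier` arguments.

## Linguistic scales

Three built-in scales (`builtin_scales()`), each configurable and loadable
from YAML/JSON (`read_scale()`):

* **importance** (six terms EI…AI, for BWM comparisons), each term with a
  consistency index CI used by the consistency ratio;
* **reliability** (VL (0,0,0.3) … VH (0.7,1,1)) on $[0,1]$;
* **rating** (seven terms on the 0–10 S/O/D axis): VL (0,1,2), L (1,2,3),
  ML (2,3.5,5), M (4,5,6), MH (5,6.5,8), H (7,8,9), VH (8,9,10).

The rating scale is *reverse-engineered*: the source study never prints
it.  It was identified by dividing converted decision-matrix cells by the
scalar implied from their votes and reliabilities; e.g. the (VL, VL) cell
of A12/TM3 prints $(0, 0.76, 1.52) = 0.760 \cdot (0, 1, 2)$, and
$0.760 = \sqrt{b^*}$ for that row's vote.  It is shipped as an ordinary
configurable scale.

## Reliability and consensus

For a judgment with rating TFN $A$ and reliability TFN $B$:

1. $b = \mathrm{GMIR}(B) \in [0,1]$ (`crisp_reliability()`);
2. the panel vote $(Y, N, \theta)$ out of $n$ gives the consensus ratio
   $R = (Y - N)/(n - \theta) \in [-1, 1]$ (`consensus_ratio()`); the vote
   must balance, $Y + N + \theta = n$, and $\theta = n$ (all neutral) is
   an error, not a silent zero;
3. the adjusted reliability is
   $b^* = b(1+R)$ for $R<0$, $b$ for $R=0$, $1-(1-b)(1-R)$ for $R>0$
   (`adjust_reliability()`) — continuous at $R = 0$ and nondecreasing in
   $R$;
4. the judgment becomes the plain TFN $\sqrt{b^*}\, A$ (`z_to_fuzzy()`).

The square-root discount is the standard Z-number-to-fuzzy conversion; it
commutes with defuzzification
($\mathrm{GMIR}(\sqrt{b^*}A) = \sqrt{b^*}\,\mathrm{GMIR}(A)$), which the
test suite checks as a property.  The "Z" pipeline variant is the same
chain with the consensus step skipped ($b^* = b$).  Votes are accepted
either per expert-row (one triple moderating that expert's whole S/O/D
row, the convention of the bundled study) or per cell, by adding a
`criterion` column to the vote table.

## Criteria weighting: fuzzy BWM

Each expert names a best and a worst criterion and gives Best-to-Others
and Others-to-Worst vectors of importance terms.  `solve_fuzzy_bwm()`
finds fuzzy weights $\tilde w_j$ minimising the scalar $\xi$ bounding
every componentwise deviation
$|\tilde w_B \oslash \tilde w_j - \tilde a_{Bj}|$ and
$|\tilde w_j \oslash \tilde w_W - \tilde a_{jW}|$, subject to
$\sum_j \mathrm{GMIR}(\tilde w_j) = 1$ and $0 < l_j \le m_j \le u_j$.
The consistency ratio is $CR = \xi^*/CI$ with CI taken from the
best-to-worst term; $CR < 0.1$ is conventionally acceptable.  Panels that
violate classical BWM conventions (e.g. a best-to-worst term weaker than
other entries) are *not* rejected at validation: consistency is judged by
CR afterwards, matching how the bundled panels were collected.

Numerical choices:

* the minimax program is solved over an unconstrained parametrisation
  $l_j = e^{a_j}$, $m_j = l_j + b_j^2$, $u_j = m_j + c_j^2$, rescaled by
  the total GMIR so the sum-to-one constraint holds exactly (GMIR is
  linear); ordering and positivity are therefore enforced by
  construction, and the representation can reach degenerate (crisp)
  weights exactly;
* 32 seeded multi-starts: one crisp seed from the GMIR ratios of the BO
  vector (exact for consistent crisp inputs, giving $\xi^* = 0$ without
  any iteration), the rest Dirichlet-type perturbations of it; each start
  runs Nelder–Mead, and the incumbent is polished by restarts until
  stagnation.  With a fixed `seed` the result is bit-reproducible;
* the weighting of the bundled case study treats the comparison vectors
  as fully reliable (no reliability pre-scaling).  Where reliability
  should enter the weighting stage is genuinely underdetermined — the
  comparison table carries no reliability annotations — and the solved
  weight *orderings* already match the recorded per-expert weights
  (TM1: D>S>O, TM2: S>O>D, TM3: O>D>S) without any pre-step, so the
  simpler contract was adopted.  Exact weight values are not
  reproducible in principle, since the original solver and its settings
  are unknown; the test suite therefore pins the sum-to-one invariant,
  the orderings, and crisp-limit exactness against a grid-search oracle
  rather than individual cells.

Per-expert weights are combined by `aggregate_expert_weights()`:
componentwise arithmetic mean, rescaled so the GMIRs sum to one.

## Ranking: fuzzy MABAC

Given an initial matrix of fuzzy cells (30 failure modes × S, O, D in the
bundled study):

1. **Normalization** (`normalize_matrix()`): column-wise min–max on each
   component, $x \mapsto (x - x^-)/(x^+ - x^-)$ with $x^-$ the column
   minimum of lower bounds and $x^+$ the column maximum of upper bounds;
   cost criteria reflect the column and swap bounds.  All three FMEA
   criteria are benefit-type (higher score ⇒ higher risk).  Min–max is
   used because it reproduces the recorded normalized matrix exactly,
   while the divide-by-column-max rule printed in the source's
   methodological text does not; the latter is still available via
   `method = "max"` for fidelity experiments.  A constant column
   normalizes to 0 with a warning.
2. **Weighting** (`weight_matrix()`):
   $\tilde v_{ij} = \tilde w_j \otimes (\tilde C \oplus \tilde n_{ij})$
   with the standard MABAC constant $\tilde C = (1,1,1)$, keeping all
   cells strictly positive.
3. **Border** (`compute_baa()`): componentwise geometric column mean
   $\tilde g_j = (\prod_i \tilde v_{ij})^{1/m}$.
4. **Distances** (`compute_distances()`):
   $\tilde q_{ij} = \tilde v_{ij} \ominus \tilde g_j$.
5. **Scores and ranks** (`score_and_rank()`):
   $\tilde S_i = \sum_j \tilde q_{ij}$, defuzzified by the centroid;
   ranks descend in the crisp score, rank 1 = most critical.  Ties break
   by the larger modal value $m$ of $\tilde S_i$, then by input order —
   deterministic and documented.

Properties verified in the suite: normalization maps every column onto
$[0,1]$ touching both ends; ranks are invariant to positive affine
rescaling of columns; componentwise dominance is never rank-reversed; and
on degenerate (crisp) inputs the whole pipeline agrees with an
independent brute-force classical MABAC implementation to $10^{-10}$ on
randomly drawn 5 × 3 instances.

## The bundled case study

`case_study()` ships the complete extraction-process assessment: the
30-mode failure catalog in six categories, 270 linguistic judgments and
90 panel votes (three decision-makers, panel size 12), the three
comparison vectors, the recorded per-expert fuzzy weights, the initial
fuzzy decision matrix of record, and the recorded normalized and final
score tables used as cross-checks.  The initial matrix is shipped
verbatim rather than recomputed because it is not derivable from the
recorded per-expert cells by mean aggregation; its provenance in the
source material is unstated, so it is the input of record and
`assemble_matrix()` is validated on synthetic data instead.

Three curation notes (all visible in the loader's documentation):

* one vote triple (A30, TM2) printed as (5, 4, 1), which sums to 10
  rather than the fixed panel size 12 and contradicts its own recorded
  consensus ratio of −0.11; it is stored as (4, 5, 3), which satisfies
  both and equals the other two experts' triples in that row;
* two reliability entries printed as terms that do not exist on the
  five-term reliability scale ("ML", "MH"); both are stored as "M", the
  term whose conversion reproduces the corresponding recorded converted
  cells;
* the recorded converted decision matrix (the per-expert ZE cells) is
  **not fully reproducible** from the recorded linguistic inputs under
  any single consistent conversion rule.  Two independent effects are
  visible by direct arithmetic.  First, the crisp reliabilities implied
  by zero-consensus rows differ from every standard defuzzifier: e.g.
  the (M, M) cell of A5/TM1 with a balanced vote prints
  $0.7183\cdot(4,5,6)$, implying $b = 0.7183^2 = 0.516$, not GMIR's 0.5
  (similarly ≈0.35 for L and ≈0.733 for H, against 0.30 and 0.70).
  Second, a minority of cells were evidently computed from different
  linguistic terms than the ones printed alongside them (e.g. the
  A13/TM1 severity cell equals the ML conversion though the input prints
  M).  The package implements the principled rule (GMIR) rather than
  emulating unexplained constants; the corresponding whole-table
  reproduction test documents the discrepancy by failing at its stated
  2% tolerance, while the cells whose inputs are self-consistent
  reproduce closely and the spot-anchor cell reproduces exactly.

Because the normalized reference table was computed by the original
authors *before* rounding the initial matrix to two decimals, recomputing
from the printed matrix leaves a handful of cells differing in the last
printed digit (e.g. $(7.67-0.33)/9 = 0.8156$ against a printed 0.81 that
came from $7.6\overline{6}$); table-reproduction comparisons therefore
use an absolute tolerance of 0.01 — one spacing of the printed decimals.

## Synthetic panels

`generate_panel()` draws complete sessions for testing and calibration.
Defaults mirror the study conditions: 30 alternatives, 3 decision-makers,
panel size 12.  Profiles: `uniform` (flat term and vote draws),
`dominant-alternative` (one planted alternative rated from the top three
terms, everything else from the bottom four — the suite checks the
planted mode wins rank 1 in ≥95 of 100 seeded runs), `consensus-high`
(vote probabilities 0.75/0.10/0.15) and `consensus-low` (0.40/0.40/0.20;
paired seeds give strictly smaller mean |R| than `consensus-high`).
Reliability terms are drawn with weights 1:2:3:3:2 over VL…VH, the
mid-heavy pattern of real panels.  All-neutral votes are resampled to
keep the consensus ratio defined.  The generator emulates categorical
linguistic data and multinomial votes only; it does not emulate
correlated experts, criterion-specific rating styles, or systematically
biased panels, so passing tests say nothing about robustness to those.

## Problem sizes and budgets

The suite runs the full 30 × 3 case study end to end, 100 random crisp
5 × 3 instances for the classical-MABAC equivalence, 100 Dirichlet
weight perturbations for rank robustness (gamma draws with shape
$40\,\mathrm{GMIR}(w_j)$, i.e. a concentration that keeps perturbations
within realistic disagreement between panels), a $10^{-3}$-resolution
simplex grid search as the crisp BWM oracle, and exhaustive vote
enumeration up to $n = 12$.  These sizes were chosen as the smallest that
exercise every property with comfortable margins.

## Known limitations

* Exact reproduction of the recorded per-expert weight *values* and of
  the recorded converted decision matrix is out of reach for any
  implementation, for the reasons above; orderings, invariants and the
  final ranking ends are the stable reproduction surface.
* The recorded intermediate weighted and distance tables of the source
  study print internally non-monotone triples (components out of order),
  indicating column scrambling in the source; they are deliberately not
  reproduction targets and are not shipped.
* Fuzzy arithmetic is restricted to the operations the pipeline needs;
  there is no α-cut interval arithmetic, and no trapezoidal or type-2
  fuzzy numbers.
* The BWM solver is a multi-start local method.  For the 3-criteria
  panels it is verified against a grid oracle; for many more criteria
  the start budget may need raising (`n_starts`).
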