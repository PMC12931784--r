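# zefmea — consensus-aware fuzzy FMEA risk prioritization

`zefmea` is an R package for prioritising the failure modes of a process
when the evidence is a panel of experts speaking in linguistic terms with
uneven confidence.  It was built around risk assessment of medicinal
plant extraction (sample handling, extraction conditions,
instrumentation, analytics, operators, biology/environment), but the
machinery is generic Failure Mode and Effects Analysis (FMEA) for any
alternatives × criteria problem.

## The model

Classical FMEA scores each failure mode by the Risk Priority Number
RPN = S × O × D (severity, occurrence, detection, each 1–10), which
ignores criterion importance, expert confidence, and panel agreement.
`zefmea` replaces it with a four-stage pipeline:

1. **Fuzzy ratings.** Linguistic terms map to triangular fuzzy numbers
   (TFNs) $(l, m, u)$ with the usual extension arithmetic.
2. **ZE-number reliability.** Each rating $A$ carries a fuzzy reliability
   term $B$; the panel votes $(Y, N, \theta)$ on the judgment.  With
   $b = (l + 4m + u)/6$ the graded mean of $B$ and consensus ratio
   $R = (Y - N)/(n - \theta)$, the adjusted reliability is
   $b^* = b(1{+}R)$ if $R<0$, $b$ if $R=0$, $1-(1-b)(1-R)$ if $R>0$,
   and the judgment becomes the plain TFN $\sqrt{b^*}\,A$.
3. **Fuzzy Best–Worst weights.** Each expert's Best-to-Others /
   Others-to-Worst comparison vectors feed a minimax program
   $\min \xi$ s.t.
   $|\tilde w_B \oslash \tilde w_j - \tilde a_{Bj}| \le \xi$,
   $|\tilde w_j \oslash \tilde w_W - \tilde a_{jW}| \le \xi$,
   $\sum_j \mathrm{GMIR}(\tilde w_j) = 1$, with consistency ratio
   $CR = \xi^*/CI < 0.1$ deemed acceptable.
4. **MABAC ranking.** Min–max normalization, weighting
   $\tilde w_j \otimes (1 \oplus \tilde n_{ij})$, geometric-mean border
   approximation area $\tilde g_j$, signed fuzzy distances
   $\tilde q_{ij} = \tilde v_{ij} \ominus \tilde g_j$, centroid-defuzzified
   total scores, ranks descending (rank 1 = most critical).

A complete 30-failure-mode case study (3 decision-makers, 12-member
voting panel) ships with the package, along with a seeded synthetic panel
generator and a small CLI (`inst/exec/ze-fmea`).

## Worked example

```r
library(zefmea)

# one ZE judgment: rating M with reliability M, panel votes 8/2/2 of 12
ze_convert("M", "M", Y = 8, N = 2, theta = 2, n = 12)
#> <tfn[1]>
#> [1] (3.578, 4.472, 5.367)
```

The rating term M is (4, 5, 6); its reliability (crisp value 0.5) is
pushed up to $b^* = 0.8$ by the strongly agreeing vote ($R = 0.6$), and
the cell is discounted by $\sqrt{0.8} \approx 0.894$.

```r
cs  <- case_study()                                # packaged study
w   <- aggregate_expert_weights(cs$expert_weights) # mean fuzzy weights
round(gmir(w), 3)
#> [1] 0.344 0.300 0.356                            # S, O, D

res <- run_ze_pipeline(cs$initial_matrix, weights = w)
head(as.data.frame(res)[order(res$rank), ], 3)
#>    alternative        S_l       S_m      S_u     score rank
#> 2           A2 -0.3660251 0.3633182 1.062610 0.3533010    1
#> 10         A10 -0.3945088 0.3131142 1.007087 0.3085642    2
#> 9           A9 -0.4333514 0.3079509 1.037772 0.3041240    3
```

Inappropriate sample preparation (A2) tops the ranking and inaccurate or
malfunctioning equipment (A12) is ranked least critical (rank 30), with
scores being centroid-defuzzified total distances from the border
approximation area: positive = above the border (critical), negative =
below.

## Command line

```sh
ze-fmea run --fixture --out report/          # rank the bundled study
ze-fmea run --judgments j.csv --votes v.csv --comparisons c.csv --variant ze --out report/
ze-fmea synth --alternatives 30 --experts 3 --panel 12 --seed 7 --profile consensus-high
ze-fmea weights --comparisons c.csv
```

Exit codes: 0 success, 2 validation error, 3 solver failure.  Every
output directory contains a `manifest.json` (package version, config,
seed, input checksums) sufficient to reproduce the run.

See the methods vignette (`vignettes/zefmea-methods.Rmd`) for the full
model description, numerical choices, data-curation notes on the bundled
tables, and known limitations.
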