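---
title: "Methods: automated scoring, stratification and reporting of public health indicator tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated scoring, stratification and reporting of public health indicator tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthpipe)
options(healthpipe.log_level = "ERROR")
```

healthpipe turns a unit-level public health indicator table — administrative
units in rows, heterogeneous numeric indicators in columns, typically served
page by page from an open-data REST API — into a ranked composite score, a
k-means stratification, exploratory correlations and t-tests, a rule-based
narrative, and a timestamped Word report, all from one command. This vignette
documents the statistical model, the tunable parameters, the numerical
choices, and what the synthetic test bed does and does not demonstrate.

## The pipeline model

Five stages run in a fixed order, each consuming only the previous stage's
typed output and the configuration:

1. **Ingestion.** Pages of CSV are requested at offsets 0, `page_size`,
   2·`page_size`, … until a page returns fewer rows than requested. Transient
   failures (connection errors, timeouts, HTTP 5xx) are retried up to
   `max_attempts` times with exponential backoff (`base · 2^(attempt−1)`
   seconds, default base 1 s, no jitter — deterministic retry timing is worth
   more here than thundering-herd protection, since one client talks to one
   endpoint). HTTP 4xx is treated as misconfiguration and never retried.
2. **Preprocessing.** Column names are harmonised (lower case, underscores,
   collision suffixes), cells are coerced to numbers (thousands separators
   and `%` suffixes stripped; a fixed missing-token set), aggregate summary
   rows such as "India" or "Total" are removed by case-insensitive label
   match, all-missing columns are dropped, remaining gaps are median-imputed,
   and configured features (regions, ratios, differences) are derived. A row
   audit (counts in/out, imputed cells, dropped columns) is carried on the
   result.
3. **Analysis.** See below.
4. **Interpretation.** Conditional-logic rules convert results to sentences.
5. **Reporting.** A WordprocessingML document is assembled programmatically
   with the narrative, ranking/cluster/correlation/test tables and embedded
   figures, under a collision-safe timestamped filename.

## Composite score

For indicators $x_{ij}$ (unit $i$, indicator $j$) the pipeline computes
z-scores with the **population** standard deviation,

$$z_{ij} = \frac{x_{ij} - \bar x_j}{\sigma_j}, \qquad
  \sigma_j = \sqrt{\tfrac1n \sum_i (x_{ij}-\bar x_j)^2},$$

an unweighted polarity-adjusted mean $c_i = \tfrac1d \sum_j s_j z_{ij}$ with
$s_j \in \{+1,-1\}$, and the linear rescale

$$\mathrm{score}_i = 100 \cdot \frac{c_i - \min_k c_k}{\max_k c_k - \min_k c_k}.$$

The divisor-$n$ standard deviation matches the behaviour of the standard
machine-learning scaler convention; the choice cancels in the ranking but is
fixed so tests can assert exact values. The rescale forces the best unit to
exactly 100.0 and the worst to exactly 0.0 on every non-constant input —
which is why a reported top score of 100.0 is a structural property of the
method, not a finding about any particular dataset. Polarity defaults to +1
("higher is better") for every indicator and is overridable per indicator in
configuration: inferring polarity from data would silently encode analytical
judgements the analyst never made. Ranks use competition ("min") ranking, so
tied units share the smaller rank. A fully degenerate composite (all units
identical) maps everyone to 50.0 with a warning rather than failing, so
report generation still completes.

## Stratification

Units are clustered on the polarity-adjusted z-matrix with k-means under
squared Euclidean distance: k-means++ seeding driven by a fixed seed,
`n_restarts` independent restarts keeping the lowest within-cluster sum of
squares (WCSS), Lloyd iterations until the maximum centroid shift falls
below `tol` or `max_iter` is reached, and empty clusters repaired by seizing
the point farthest from its centroid. Defaults: k = 3 (an a-priori
interpretability choice — high/middle/low tiers — not a data-driven model
selection), seed = 42, 10 restarts, `max_iter` 300, `tol` 1e-6. The
implementation is deliberately explicit rather than delegated so that
seeding, restart policy and degenerate-case repair are part of the tested
contract; on easy instances it agrees with `stats::kmeans`, and on small
instances (n ≤ 9) it attains the global optimum found by exhaustive
enumeration of partitions, which the test suite checks.

## Correlation and testing

Pearson correlation is computed per unordered pair of configured columns,
with a two-sided p-value from the t distribution with n − 2 degrees of
freedom; |r| = 1 reports the smallest representable positive p rather than
zero. Two-sample comparisons use the Welch test (unequal variances,
Welch–Satterthwaite degrees of freedom); paired comparisons test post − pre
differences with df = n − 1. All tests are two-sided and exploratory, and
**no multiple-comparison adjustment is applied** — the outputs demonstrate
pipeline mechanics, not confirmatory epidemiology. Degenerate inputs are
handled explicitly: constant vectors are a correlation error, both-groups
zero variance is a test error (or t = 0, p = 1 when means agree), and a
constant nonzero paired difference is reported as an infinite statistic.

## Interpretation rules

Significance wording uses a strict threshold, p < α with α = 0.05 by
default; p exactly equal to α reads "not significant". Correlation strength
bands on |r| are weak < 0.3 ≤ moderate < 0.5 ≤ strong, direction comes from
the sign of r (exactly zero r avoids both direction words). Numbers in
narrative are rounded to two decimals (scores to one). Statements are
emitted in a fixed order — ranking, cluster tiers, correlations, tests —
with alphabetical tie-breaks throughout, so the narrative is a pure function
of the analysis bundle; the test suite asserts byte-identical narratives
across runs. Templates are plain strings with `{placeholder}` slots, loadable
from YAML; rendering fails loudly on an unresolved placeholder so a broken
template can never reach a report silently.

## Synthetic data: what it emulates, and what it does not

The generator draws `n_units` (default 37, the number of Indian states and
union territories in a mid-2010s national table) rows from a multivariate
normal with configurable means, standard deviations and correlation matrix,
then applies the mess real open-data tables exhibit: counts rounded and
floored at zero, percentages clamped to 0–100, cells blanked completely at
random (default rate 0.05 — sporadic, not systematic, missingness), large
counts formatted with thousands separators, dirty headers, and appended
aggregate rows whose cells are column sums, so an accidentally retained
national row is detectable by magnitude. The default indicator set mirrors
the vocabulary of Indian health-facility statistics (functioning sub-health
centres and primary health centres, ANM and specialist staffing, 24×7 PHC
coverage in two consecutive DLHS survey rounds) with a dependence structure
in which facility counts co-move (r = 0.5), survey rounds track each other
(r = 0.7), and coverage trades off mildly against staffing (r = −0.3).

MCAR missingness was chosen because median imputation is
mechanism-agnostic at this scale and no missingness mechanism is implied by
the data source being emulated. What passing tests on this bed demonstrate
is *mechanical* correctness — lossless pagination, exact audits, correct
statistics, deterministic outputs. They do not demonstrate robustness to
non-normal marginals, informative missingness, unit-name drift between
releases, or schema changes — real-data hazards that are out of scope of
the generator by design.

## Numerical and design choices

- **Median for even counts** is the mean of the two central values (the
  conventional definition).
- **Unit-column resolution**: the first harmonised name among a candidate
  list (`state`, `state_ut`, `states_uts`, `unit`), else the first mostly
  non-numeric column. Unparseable numeric tokens become missing (then
  imputed) and are counted, rather than aborting a run: the tool exists to
  replace error-prone manual cleaning, so it must absorb stray footnote
  markers.
- **All-missing columns are dropped** (with an audit entry) rather than
  fatal, keeping single-command runs robust.
- **Cluster scatter axes**: the two highest-variance standardised columns;
  since standardisation equalises variances, this devolves to the first two
  columns — a deterministic tie-break, documented rather than hidden.
- **Report determinism**: figures render at fixed size and DPI, images embed
  at a fixed 16 cm width, and tables derive from the already-serialised
  analysis outputs, so two runs on the same input differ only in the
  timestamped filename and the printed generation time.
- **Problem sizes in the test suite** follow the demonstration conditions:
  37 units × 6 indicators for end-to-end checks, 100 random instances for
  the closed-form oracles, 200 seeds for planted-correlation recovery, and
  n = 8 for the exhaustive clustering oracle — small enough to enumerate
  exactly, large enough to be non-trivial.

## A worked run

```{r run, eval = FALSE}
fixture <- system.file("extdata", "synthetic_health_indicators.csv",
                       package = "healthpipe")
cfg <- list(input = list(fixture_path = fixture),
            report = list(output_dir = "healthpipe_output"))
manifest <- run_pipeline(cfg)
manifest
```

The run manifest records the config and input digests, the row audit
(39 rows in, 37 analysed for the packaged fixture), per-stage timings and
the report path, and is also written as JSON next to the report.

## Limitations

The pipeline targets small, aggregated administrative tables (tens of rows);
nothing is streamed or chunked. The rule engine's templates encode one
reporting style and require customisation for other audiences. Statistical
outputs are exploratory by construction — unweighted composites, a-priori
k, unadjusted p-values — and the tool is a decision-support aid, not an
inference engine.
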