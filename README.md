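# healthpipe

Single-command analytics for unit-level public health indicator tables.

Public health analysts repeatedly turn the same kind of raw input — an
administrative-units × indicators table served page by page from an
open-data REST API, with messy headers, string-formatted numbers, sporadic
gaps, and national "Total" rows mixed in — into the same kind of output: a
ranked composite score, a stratification of units into performance tiers, a
few exploratory correlations and tests, and a narrated Word report. Done by
hand, that workflow is slow, error-prone and irreproducible. healthpipe
automates the whole cycle as five deterministic stages behind one command:

    ingest → preprocess → analyze → interpret → report

## The method

For indicators $x_{ij}$ (unit $i$, indicator $j$), each indicator is
standardised with the population standard deviation,
$z_{ij} = (x_{ij} - \bar{x}_j)/\sigma_j$, combined as an unweighted
polarity-adjusted mean $c_i = \frac{1}{d}\sum_j s_j z_{ij}$
($s_j \in \{+1,-1\}$), and rescaled linearly so scores span exactly
$[0, 100]$:

$$\mathrm{score}_i = 100\,\frac{c_i - \min_k c_k}{\max_k c_k - \min_k c_k}.$$

Units are stratified with k-means (k = 3 a priori, Euclidean distance,
k-means++ seeding, fixed seed, best of 10 restarts) on the standardised
indicator profile. Pearson correlations (two-sided p from the t
distribution with n − 2 df) and Welch / paired t-tests are exploratory; no
multiple-comparison adjustment is applied. A conditional-logic rule engine
converts the results into deterministic narrative sentences (strict
α = 0.05; |r| bands weak < 0.3 ≤ moderate < 0.5 ≤ strong), and the report
stage assembles an OOXML .docx — narrative, ranking/cluster/correlation
tables, embedded figures — under a timestamped filename.

Ingestion handles `offset`/`limit` CSV pagination with exponential-backoff
retry (base · 2^(attempt−1), 5 attempts) for transient failures.
Preprocessing harmonises column names, coerces "1,234"- and "12%"-style
strings to numbers, drops aggregate rows ("India", "All India", "Total"),
median-imputes gaps, derives configured features, and keeps a row-count
audit trail. A seeded synthetic-data generator and an in-process mock API
(flaky on request) make every stage testable fully offline.

## Worked example

The package ships a 39-row synthetic demonstration fixture (37 state-level
unit rows plus "India" and "All India" summary rows, six facility/staffing
indicators, ~5% missing cells):

```r
library(healthpipe)
fixture <- system.file("extdata", "synthetic_health_indicators.csv",
                       package = "healthpipe")
manifest <- run_pipeline(list(input = list(fixture_path = fixture),
                              report = list(output_dir = "hp_out")))
print(manifest)
#> <run_manifest>
#>   report: hp_out/report_20260925_190837.docx
#>   rows: 39 in -> 37 analysed (10 cells imputed)
#>   total: 0.79 s
head(as.data.frame(manifest$bundle$scores), 3)
#>                  unit     score rank
#> Mizoram       Mizoram 100.00000    1
#> Tripura       Tripura  81.93973    2
#> Chandigarh Chandigarh  80.34042    3
manifest$narrative[[1]]
#> [ranking_top] Mizoram recorded the highest composite score (100.0).
```

The audit line shows the two aggregate rows were removed (39 → 37) and ten
missing cells were median-imputed; the top unit scores exactly 100.0 because
the rescale pins the best and worst units to 100 and 0 on any non-constant
input. The narrative, cluster tiers and correlation sentences land verbatim
in the generated .docx, alongside the tables and figures.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/healthpipe.R fixture --out demo --seed 42
Rscript inst/cli/healthpipe.R validate --config cfg.yaml
Rscript inst/cli/healthpipe.R run --config cfg.yaml
```

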