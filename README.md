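# cescore — severity and need scoring for complex emergencies

Humanitarian donors have agreed that need should drive funding allocations,
yet no common, transparent system for comparing the severity of complex
emergencies (CEs) exists. `cescore` implements a simple composite index that
makes the comparison explicit and auditable. It is aimed at analysts in
donor agencies and humanitarian organisations who need to rank ongoing CEs
from readily available country-level indicators.

## The model

Eight indicators — four measuring **vulnerability** (development/health:
GNI per capita at PPP, adult literacy, child underweight, …) and four
measuring **exposure** (the crisis footprint: numbers and proportions of
uprooted people and of people in need) — are classified against
per-indicator cut-offs into three ordinal levels carrying fixed weights:

| level      | weight | colour |
|------------|--------|--------|
| low/medium | 0.5    | yellow |
| high       | 1.0    | orange |
| extreme    | 1.5    | red    |

The two dimensions are summed separately and multiplied:

```
severity = (sum of 4 vulnerability weights) x (sum of 4 exposure weights)
```

Each dimension sum lies in [2, 6], so severity lies in **[4, 36]**.
Multiplying by the number of people in need (in millions, from UN appeals)
gives the **need score**:

```
need = severity x people-in-need (millions)
```

Cut-offs are configuration, not code: they ship as an editable YAML file
(`inst/extdata/default_model.yaml`) with documented provisional values.
Missing indicator values leave the score unresolved by default (`strict`
policy); an explicit `impute_extreme` policy substitutes the extreme level,
recording every substitution — the documented exception for contexts known
to be dire. The package also renders the standard reports (country ×
indicator heat maps with blank cells for unavailable data, and score bar
charts binned yellow/orange/red), checks the severity ranking against
excess-mortality rates with Spearman's rank correlation plus a rank-window
concordance count, and generates synthetic panels with known ground truth.

## Worked example

```r
library(cescore)

rec <- list(country = "Ukraine-like", assessment_date = "2015-01",
  gni_per_capita_ppp = 8500, adult_literacy = 99, child_underweight = 2,
  life_expectancy = 71, uprooted_number = 60000, uprooted_proportion = 0.2,
  people_in_need_number = 500000, people_in_need_proportion = 1.1,
  people_in_need_millions = 1.0)
score_country(rec)[, c("vulnerability_sum", "exposure_sum",
                       "severity_score", "need_score")]
#>   vulnerability_sum exposure_sum severity_score need_score
#> 1                 2            2              4          4
```

All eight values fall in the mildest bin, so each weight is 0.5, both
dimension sums are 2, and severity is 4 — the lowest attainable score; with
1 million people in need the need score is also 4. A dire context with one
missing vulnerability value, scored under the imputation policy:

```r
som <- list(country = "worst-observed", assessment_date = "2015-01",
  gni_per_capita_ppp = NA, adult_literacy = 20, child_underweight = 40,
  life_expectancy = 45, uprooted_number = 2.5e6, uprooted_proportion = 22,
  people_in_need_number = 3e6, people_in_need_proportion = 38,
  people_in_need_millions = 3.2)
score_country(som, policy = missing_policy("impute_extreme"))
#>   vulnerability_sum exposure_sum severity_score need_score imputed_indicators
#> 1                 6          5.5             33      105.6 gni_per_capita_ppp
```

Three vulnerability indicators classify extreme and the missing GNI value is
imputed extreme (vulnerability sum 6 = 4 × 1.5); exposure has three extreme
levels and one high (5.5), giving severity 6 × 5.5 = 33.

From the shell, the same workflows run via the bundled launcher:

```sh
CLI="$(Rscript -e 'cat(system.file("cli","cescore.R",package="cescore"))')"
Rscript "$CLI" simulate --out-dir demo --countries 16 --years 3 --seed 7
Rscript "$CLI" score    --input demo/panel.csv --out demo/scored.csv
Rscript "$CLI" heatmap  --input demo/panel.csv --out demo/heatmap.html
Rscript "$CLI" validate --input demo/panel.csv --mortality demo/mortality.csv
```

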