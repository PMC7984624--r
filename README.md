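# bedbench

Benchmarking regional hospital capacity and inpatient activity: the four
classical bed-management indicators, Barber-Johnson efficiency zones,
AvLOS-based Case-Mix and Performance indices against a pooled multi-region
benchmark, and the combined efficiency × complexity classification — for
anyone comparing hospital systems across regions (health-services
researchers, capacity planners) from Eurostat-style regional extracts.

## What it computes

For a region with `B` beds over `T` days, `D` discharges and `O` occupied
bed-days (derived as discharges × average length of stay):

```
BOR = O / (B·T)      bed occupancy rate          (fraction, printed as %)
AvLOS = O / D        average length of stay      (days)
BTO = D / B          bed turnover                (patients/bed/period)
TOI = (B·T − O) / D  turnover interval           (days a bed stands empty)
```

linked by the identities `AvLOS + TOI = T/BTO` and `BOR = AvLOS·BTO/T`.
Regions are classified on the Barber-Johnson diagram against the bands
`1 < TOI < 3` and `75% < BOR < 85%` (GREEN both in, RED both out, YELLOW
otherwise) with Euclidean distance from the centroid (TOI = 2, BOR = 80%).

Complexity and performance are scored against a benchmark pooled over all
regions (reference stays `AvLOS_j^REF`, shares `s_j`, overall stay
`AvLOS_ALL^REF = Σ_j s_j AvLOS_j^REF`):

```
CMI = Σ_j AvLOS_j^REF · (d_j^STR / d_ALL^STR) / AvLOS_ALL^REF
PI  = Σ_j AvLOS_j^STR · (d_j^REF / d_ALL^REF) / AvLOS_ALL^REF
```

with strict quadrants at 1 (GREEN: CMI > 1 & PI < 1, YELLOW: CMI ≤ 1 &
PI < 1, ORANGE: CMI > 1 & PI ≥ 1, RED otherwise). Zones × quadrants give a
12-cell combined grid. Around this core: an Eurostat bulk-TSV reader/writer,
region inclusion rules, per-100k rates, percent changes, coefficients of
variation, country min–max spans, and a seeded synthetic-panel generator
with exact ground truth.

## Worked example

```r
library(bedbench)
library(dplyr)

# one hospital system: 100 beds, 4000 discharges, 28000 occupied bed-days
ind <- compute_indicators(tibble(beds = 100, discharges = 4000,
                                 occupied_days = 28000))
classify_bj(ind) |> select(bor, avlos, toi, bto, zone, centroid_distance)
#>     bor avlos   toi   bto zone  centroid_distance
#> 1 0.767     7  2.12    40 GREEN              3.29
```

Occupancy is 76.7%, each bed turns over 40 patients a year and stands empty
2.12 days between them — inside both efficiency bands, so the region is
GREEN, 3.29 units from the centroid (TOI in days, BOR in percentage points).

```r
b <- build_benchmark(tibble(specialty = c("A", "B"),
                            discharges = c(500, 500), avlos = c(4, 10)))
s <- tibble(specialty = c("A", "B"), discharges = c(200, 800),
            avlos = c(5, 12))
compute_cmi(s, b); compute_pi(s, b); classify_quadrant(1.2571, 1.2143)
#> [1] 1.257143
#> [1] 1.214286
#> [1] ORANGE
```

The structure tilts its mix toward the long-stay specialty (CMI 1.26 > 1)
but keeps patients longer than the benchmark expects (PI 1.21 > 1): complex
cases managed with low performance, the ORANGE quadrant.

The full pipeline on a synthetic four-country panel:

```r
sp <- gen_panel(synthetic_config(countries = c(DE = 4, ES = 4, FR = 4, IT = 4),
                                 years = c(2012, 2017), seed = 2026))
dir <- tempfile(); export_fixture(sp, dir)   # Eurostat-dialect TSV fixtures
rep <- run_pipeline(dir)
rep$classification |>
  select(geo, year, bor, toi, zone, cmi, pi, quadrant, cell_id) |> head(4)
#>   geo    year   bor   toi zone     cmi    pi quadrant cell_id
#> 1 DE01   2012 0.551  4.39 RED    0.833 0.899 YELLOW   BJ:RED|Q:YELLOW
#> 2 DE01   2017 0.698  2.93 YELLOW 1.10  0.838 GREEN    BJ:YELLOW|Q:GREEN
#> 3 DE02   2012 0.653  2.61 YELLOW 0.816 0.836 YELLOW   BJ:YELLOW|Q:YELLOW
#> 4 DE02   2017 0.774  2.13 GREEN  1.17  0.849 GREEN    BJ:GREEN|Q:GREEN

rep$zone_distribution |> filter(year == 2017, country == "IT")
#>    year country class      n   pct
#>    2017 IT      GREEN      3    75
#>    2017 IT      YELLOW     1    25
#>    2017 IT      RED        0     0
```

Each region-year gets its indicators, zone, centroid distance, CMI/PI with
quadrant and PI/CMI ratio, and combined cell; per-country tables count
regions per class with integer percentages, and two-year panels add
per-region percent changes of the per-100k bed rate. `write_report()` emits
everything as CSV/JSON (plus the two diagrams via `plot_bj()` and
`plot_quadrants()`), and the recovered labels match the generator's ground
truth exactly because noise-free placements are algebraically exact.

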