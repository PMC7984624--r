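---
title: "Methods: bed-management indicators, efficiency zones and case-mix benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bed-management indicators, efficiency zones and case-mix benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedbench)
library(dplyr)
```

## The problem

Regional health systems are routinely compared on two questions: *how
efficiently are hospital beds used*, and *how complex is the case load each
region treats, and at what performance*. `bedbench` implements both analyses
for panels of regions (typically European NUTS-2 regions observed in two
reference years), from raw Eurostat-style extracts to a combined
classification per region, with a synthetic-data generator that makes the
whole chain testable without any external download.

## Bed-day accounting

For a region with $B$ beds observed over $T$ days (default $T = 365$; leap
years are deliberately ignored), $D$ discharges and $O$ occupied bed-days,
the four classical indicators are

$$\mathrm{BOR} = \frac{O}{BT}, \qquad
  \mathrm{AvLOS} = \frac{O}{D}, \qquad
  \mathrm{BTO} = \frac{D}{B}, \qquad
  \mathrm{TOI} = \frac{BT - O}{D},$$

the occupancy rate (a fraction; printed as a percentage), the average length
of stay, the bed turnover (patients per bed per period) and the turnover
interval (mean days a bed stands empty between patients). Two identities
follow immediately and are enforced as invariants throughout:

$$\mathrm{AvLOS} + \mathrm{TOI} = \frac{T}{\mathrm{BTO}}, \qquad
  \mathrm{BOR} = \frac{\mathrm{AvLOS}\cdot\mathrm{BTO}}{T}.$$

Eurostat publishes discharges and average lengths of stay, not occupied
bed-days, so $O$ is **derived** as $\sum_j d_j \cdot \mathrm{AvLOS}_j$ over
ICD-chapter specialties where chapter data exist (`mode = "specialty"`), or
as $D \cdot \mathrm{AvLOS}_{\mathrm{tot}}$ otherwise. The two agree exactly
when the total AvLOS is the discharge-weighted chapter mean; where chapters
are missing the specialty sum is the more conservative choice because it
never invents stay-days for unreported chapters.

`invert_indicators()` is the exact algebraic inverse: given
$(\mathrm{BOR}, \mathrm{TOI}, B)$ it returns
$\mathrm{AvLOS} = \mathrm{TOI}\cdot\mathrm{BOR}/(1-\mathrm{BOR})$ and
$D = BT(1-\mathrm{BOR})/\mathrm{TOI}$. The degenerate pair
$\mathrm{BOR}=1,\ \mathrm{TOI}=0$ is geometrically valid but leaves $D$
undetermined; it returns `NA` with a warning rather than guessing.

## Barber-Johnson zones

The Barber-Johnson diagram plots TOI (abscissa) against AvLOS (ordinate).
Points of constant occupancy lie on rays through the origin with slope
$\mathrm{BOR}/(1-\mathrm{BOR})$; points of constant turnover lie on lines
$\mathrm{AvLOS} + \mathrm{TOI} = T/\mathrm{BTO}$. The efficiency target is
the band $1 < \mathrm{TOI} < 3$ days and $0.75 < \mathrm{BOR} < 0.85$, with
centroid $(\mathrm{TOI}=2, \mathrm{BOR}=0.80)$. Regions are classified
GREEN (both indicators in band), RED (both outside) or YELLOW (exactly one
inside).

Numerical choices worth stating:

* **Boundaries are strictly open.** A region with TOI exactly 3.0 is
  *outside* the band. This matches the strict inequalities in which the
  bands are conventionally quoted, and it means ties simply cannot occur in
  zone assignment. (One published table prints the TOI band as "3<TOI<1",
  an obvious typo for 1<TOI<3; the package follows the consistent form.)
* **Centroid distance** defaults to the literal Euclidean distance with TOI
  in days and BOR in percentage points (`mode = "raw"`). Because the two
  axes carry different units, a `"band"` mode is offered that divides each
  deviation by its half-band-width (1 day; 5 percentage points), making one
  unit mean "one band" on either axis. The raw mode is the default because
  it is the plain reading of "Euclidean distance from the centroid";
  nothing downstream depends on the choice.
* BOR is held as a fraction everywhere internally and only formatted as a
  percentage in outputs — the one representation that makes the distance
  metric and the threshold configuration unambiguous.

## Case-Mix and Performance indices

Let a *benchmark* consist of per-specialty reference stays
$\mathrm{AvLOS}_j^{REF}$, reference discharge shares
$s_j = d_j^{REF}/d_{ALL}^{REF}$ and the overall reference stay
$\mathrm{AvLOS}_{ALL}^{REF}$. For a structure with discharge shares
$w_j = d_j^{STR}/d_{ALL}^{STR}$ and stays $\mathrm{AvLOS}_j^{STR}$:

$$\mathrm{CMI} = \frac{\sum_j \mathrm{AvLOS}_j^{REF}\, w_j}
                      {\mathrm{AvLOS}_{ALL}^{REF}}, \qquad
  \mathrm{PI} = \frac{\sum_j \mathrm{AvLOS}_j^{STR}\, s_j}
                     {\mathrm{AvLOS}_{ALL}^{REF}}.$$

CMI asks whether the *mix* is tilted toward specialties with long reference
stays (complexity, > 1 = above benchmark); PI asks whether the *stays* are
longer than the benchmark expects at its own mix (> 1 = lower performance).
The benchmark is pooled from all regions of all study countries, separately
per year: reference discharges are sums, reference stays are
discharge-weighted means.

Three design decisions were genuinely open and are resolved as follows:

* **The overall reference stay** is defined as the share-weighted mean
  $\mathrm{AvLOS}_{ALL}^{REF} = \sum_j s_j \mathrm{AvLOS}_j^{REF}$. This is
  the unique definition under which the neutrality invariants hold exactly:
  a structure with benchmark-equal mix has CMI = 1, and one with
  benchmark-equal stays has PI = 1, both to machine precision.
* **Missing specialties.** Both indices are computed over the specialties
  shared between structure and benchmark, with the relevant share vector
  renormalised on that shared set, while the denominator
  $\mathrm{AvLOS}_{ALL}^{REF}$ always comes from the full benchmark.
  Treating missing chapters as zero-length stays would silently deflate
  both indices; renormalisation plus a reported `coverage` fraction (share
  of the region's discharges carried by the shared specialties) keeps the
  restriction visible instead.
* **Quadrant boundaries are strict**: equality with 1 counts as outside the
  target, consistent with the "CMI > 1, PI < 1" convention. The quadrants
  are GREEN (CMI > 1, PI < 1: complex cases, efficiently managed), YELLOW
  (CMI ≤ 1, PI < 1), ORANGE (CMI > 1, PI ≥ 1) and RED (CMI ≤ 1, PI ≥ 1).

The combined classification crosses the three zones with the four quadrants
into a 12-cell grid with deterministic identifiers; any coarser grouping of
cells is supplied by the user as a mapping, not hard-coded, because
published groupings vary.

## Dispersion summaries

Percent changes are reported rounded to the nearest integer with halves away
from zero (the convention under which 834 → 800 prints as −4%). The
coefficient of variation defaults to the sample (n−1) standard deviation
over the mean — the safer choice for region counts in the tens — with a
population-sd switch; it is computed on per-100k rates, not raw counts, so
that regions of different size are comparable. Min–max spans break ties by
lexicographic region code, and "increasing" regions across two years means
strictly increasing: equality does not count.

## The synthetic generator

`gen_panel()` emulates the Eurostat extracts with full ground truth. Its
defaults are the study conditions: 78 regions in four countries (DE 16,
ES 19, FR 22, IT 21 — the counts of the published study frame), years 2012
and 2017, bed rates 250–900 per 100k and populations 0.5–8 million
(the ranges published for European NUTS-2 regions), ten ICD-chapter-like
specialties with reference stays evenly spaced over 3–12 days, a zone mix
of 45/20/35% GREEN/YELLOW/RED approximating the published distribution, and
a uniform quadrant mix.

Placement works backwards through the package's own algebra:

1. Zone and quadrant labels are assigned by largest-remainder
   apportionment — exact per zone, apportioned within zones for quadrants,
   so all 12 cells are populated whenever counts allow — then shuffled over
   regions.
2. A (CMI, PI) pair is drawn on the intended side of 1 with a margin of
   0.04, and a (BOR, TOI) pair inside the intended open box with a margin
   of $10^{-3}$. The two pairs are coupled: a structure hitting
   (CMI, PI) against the reference benchmark has total AvLOS
   $= \mathrm{CMI}\cdot\mathrm{PI}\cdot\mathrm{AvLOS}_{ALL}^{REF}$, which
   must equal the AvLOS implied by (BOR, TOI). The sampler therefore
   rejects (BOR, TOI) candidates until the implied TOI lands in the
   intended band.
3. PI is hit exactly by uniform scaling of the reference stays (PI is
   linear in the structure stays). CMI is hit by an exponential tilt of the
   reference shares, $w_j(\theta) \propto s_j e^{\theta \mathrm{AvLOS}_j^{REF}}$;
   the tilted CMI is continuous and strictly increasing in $\theta$, so
   bisection converges — to $10^{-6}$ within a 60-step budget in the
   contract, in practice in ~20 steps. The stays are then rescaled by
   the (tiny) CMI bisection residual so the region's total AvLOS matches
   its placed diagram coordinates exactly rather than to $10^{-6}$.
4. The ground-truth table records both the intended labels and the labels
   the finished panel itself implies — indicators recomputed from the data,
   CMI/PI scored against the panel's own pooled per-year benchmark, exactly
   as the pipeline will score them. The pooled benchmark is not the
   generator's reference benchmark (pooling tilted regions shifts it by
   well under 1% at the default mixes), which is why the margins exist:
   with `noise_sd = 0` the intended and derived labels coincide, and the
   derived labels are the authoritative ground truth in every case.
5. Optional multiplicative lognormal noise (`noise_sd` as sdlog) is applied
   to specialty discharges and stays *after* placement — counts and
   durations are positive, so a multiplicative model is the natural one —
   and labels are then re-derived. Noise draws that would push a region's
   occupied bed-days beyond its bed capacity are redrawn (truncation),
   with a final rescale as a guard. Label agreement with the intended
   placement degrades monotonically in `noise_sd`, which the test suite
   checks over a seed ensemble.

The margin of $10^{-3}$ on diagram coordinates exists so that the
17-significant-digit TSV serialisation can never flip a strict-inequality
label on re-ingestion.

What the generator does *not* emulate: real covariance between bed stocks,
demography and case mix; secular trends between the two years; reporting
artefacts other than the `":"` missing-value sentinel. A pipeline that
recovers 100% of synthetic labels is therefore validated as an
*implementation* (algebra, serialisation, classification rules), not as
evidence about any real region.

## Problem sizes and determinism

The synthetic recovery check runs 100 regions stratified over all 12 cells
through export, re-ingestion and the full pipeline; the identity and
inversion suites use 1,000 random draws each; index agreement against an
independent term-by-term oracle uses 500 random instances of up to six
specialties. One seed drives all sampling, so every run is reproducible
bit for bit; `scripts/acceptance.R` re-derives its seed for the recovery
panel from the command-line seed.

## Known limitations

* The CMI here is AvLOS-based by construction. It is a proxy for complexity,
  not a DRG-weighted case-mix; where stays are shortened by day-surgery
  substitution the index reads as "less complex".
* Occupied bed-days derived from discharges × AvLOS inherit any
  inconsistency between the published totals and chapter sums; the package
  prefers chapter sums and reports coverage rather than reconciling.
* The pooled benchmark makes the indices relative: adding or removing a
  country moves every region's CMI and PI. This is inherent to the method,
  not a defect, but comparisons across differently pooled runs are
  meaningless.
* `compare_region_classifications()` reports match/mismatch against
  published per-country counts rather than asserting them, because
  reference extracts are revised over time.
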