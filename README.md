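# qsarscreen

Build, validate and deploy multiple-linear-regression QSAR models for
small-molecule activity data — the classical workflow used to model
inhibitors of IL-1β production (pIC50 of pyridazine derivatives) and to
screen designed analogues *in silico*.

## Who this is for

Medicinal and computational chemists who have (or can compute) a
compound-by-descriptor table with an activity column and want the full
chain of custody of a defensible MLR QSAR: descriptor pruning, a
representative training/prediction split, descriptor subset selection
with cross-validated fitness, internal and external validation with the
accepted decision rules, a chance-correlation check, and
applicability-domain-aware predictions for new candidates.

## What it computes

**Descriptors** (from 3D structures, SDF V2000 or built in code):

- Radial distribution function codes
  `g(r) = f · Σ_{i<j} A_i A_j exp(−B (r − r_ij)²)` over all atom pairs,
  with carbon-scaled atomic weights `A` (unweighted, mass, van der Waals
  volume, Sanderson electronegativity, polarizability);
- Moran (`MATS`) and Geary (`GATS`) autocorrelations of an atomic
  property over the molecular graph at a topological lag;
- `C-005`, the Ghose–Crippen count of methyl groups on electronegative
  atoms (O, N, S, P, Se, halogens).

Quantum-chemical, logP and surface-area descriptors are accepted as
precomputed columns; the package does not compute them.

**Pipeline**: constant/near-constant removal; collinearity filtering
(`|r| > 0.9`, keeping the better activity correlate); Kennard–Stone
max–min-distance training/test splitting; stepwise MLR (partial-F enter
0.05 / remove 0.10); genetic-algorithm selection (binary chromosomes,
population 100, mutation ramping 0→1 %, crossover 90→60 %, elitism,
leave-one-out RMScv fitness); OLS fitting with `R²`, adjusted `R²`, `F`,
`SE`, and LOO `Q²`/`RMScv`/`PRESS` via the exact hat-matrix shortcut.

**Validation**: Golbraikh–Tropsha external rules (`Q² > 0.5`,
`R²_pred > 0.6`, through-origin `R₀²`/slopes), Roy's
`rm² = r²(1 − √|r² − R₀²|) > 0.5`, Y-randomization, and the
leverage applicability domain with warning threshold `h* = 3(k+1)/n`
(Williams-plot data and ggplot2 figures included).

## Worked example

Everything is testable without external data: the synthetic generator
plants a known linear signal (defaults mirror a 46-compound study with
an 8-descriptor model) plus the nuisance structure a raw descriptor
matrix carries.

```r
library(qsarscreen)

sim <- simulate_qsar_data(n_descriptors = 40, seed = 1)
prepped <- remove_collinear(remove_constant(sim$data), threshold = 0.9)
split <- kennard_stone_split(prepped, n_train = 35)
train <- prepped[split$set == "train", ]
test  <- prepped[split$set == "test", ]

ga <- ga_select(train, population_size = 100, max_generations = 200,
                seed = 1)
ga
#> <qsar_ga> best RMScv = 0.8491 after 26 generations (converged)
#>   selected: X001, X002, X004, X005, X007, X008, X036, X040

glance(ga$model)
#> # A tibble: 1 × 9
#>       n     k r.squared adj.r.squared statistic sigma q2.loo rmscv press
#>   <int> <int>     <dbl>         <dbl>     <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1    35     8     0.844         0.795      17.5 0.720  0.707 0.849  25.2

ext <- external_validate(test$pIC50, predict(ga$model, test))
ext
#> <qsar_external> n = 11
#>   R2pred = 0.829  R02 = 0.771  R'02 = 0.506
#>   k = 0.980  k' = 0.999  rm2 = 0.629 (rm2' = 0.358)
#>   pass: r2_pred, r0_close, slope, rm2

tropsha_check(glance(ga$model)$q2.loo, ext)
#> # A tibble: 4 × 2
#>   rule                          pass
#>   <chr>                         <lgl>
#> 1 Q2 > 0.5                      TRUE
#> 2 R2pred > 0.6                  TRUE
#> 3 R02 close to R2pred           TRUE
#> 4 slope k or k' in [0.85, 1.15] TRUE

head(screen_candidates(ga$model, test), 3)
#> # A tibble: 3 × 4
#>   candidate_id predicted_pIC50 leverage reliable
#>   <chr>                  <dbl>    <dbl> <lgl>
#> 1 cmp018                  8.97    0.285 TRUE
#> 2 cmp038                  7.20    0.353 TRUE
#> 3 cmp042                  6.97    0.329 TRUE
```

The GA recovered an 8-descriptor model explaining 84 % of the training
variance with `Q² = 0.71`; on the 11 held-out compounds it predicts with
`R²_pred = 0.83`, passes all four Tropsha rules and the `rm²` criterion,
and every prediction sits inside the leverage domain
(`h* = 3·9/35 = 0.77`), so the ranked screening table is reliable
end to end.  `y_randomize()` (not shown) confirms scrambled activities
collapse `R²`/`Q²`; `plot_williams()` and the `autoplot()` methods draw
the standard diagnostics.

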