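# rumenfiber

Analysis toolkit for in-situ rumen fiber degradation experiments paired
with 16S rRNA gene community profiles — the kind of study where ground
forage is incubated in nylon bags in the rumen of cannulated animals,
residues are weighed at fixed withdrawal times, and the bacterial
community of the same animals is sequenced to ask *which taxa travel
with fiber digestion*.

The package covers the full quantitative chain:

* **Digestion kinetics.** Least-squares fit of the negative exponential
  model *D(t) = a + b(1 − e^(−ct))* per animal × season × diet ×
  substrate unit, with physical constraints (a, b ≥ 0, a + b ≤ 105 %,
  c ∈ [0, 0.5] h⁻¹), a c-profile grid plus multi-start polish to defeat
  the local minima caused by the missing 0-h observation, and the
  predicted 120-h extent. Rate and extent of NDF, cellulose and
  hemicellulose give the six-response matrix.
* **Fraction arithmetic.** Cellulose = ADF − lignin, hemicellulose =
  NDF − ADF, with the detergent nesting validated.
* **Marker digestibility.** Whole-tract apparent digestibility from
  lignin as an indigestible marker, with intake-weighted diet ratios;
  negative values flagged, never clipped.
* **Community tables.** Lineage-typed taxon tables (TSV), clade-level
  aggregation that conserves per-sample mass, Shannon (nats), Chao1 and
  Good's coverage (counts only).
* **Influence censoring.** Per-taxon Cook's distances of a kinetic
  response regressed on sequence proportions; taxa exceeding
  F(df₁, df₂; 1−α) are removed (adaptive (2, n−2) or fixed df).
* **PLS association.** From-scratch NIPALS PLS1/PLS2 with standardization,
  leave-one-out PRESS component selection, VIP scores
  (Σ VIP² = p), and signed 95th-percentile genus lists.
* **Synthetic data.** A generator that emulates the crossover design
  (8 animals × 2 seasons × 2 diets, 2 substrates, withdrawals at
  24–120 h, 80 genera in 10 phyla, two dominant phyla at 90 % expected
  mass, planted genus effects on the rate, rare high-leverage taxa), so
  every stage is testable without any sequence download.

## Worked example

```r
library(rumenfiber)

# printed feed composition: hay, ash-free kg/kg DM
hay <- feed_composition(DM = 0.875, NDF = 0.700, ADF = 0.379,
                        lignin = 0.061, N = 0.0756)
derive_fractions(hay)
#>     cellulose hemicellulose
#>         0.318         0.321

# fit one in-situ time course (% NDF digested at the six withdrawal times)
t6 <- c(24, 36, 48, 72, 96, 120)
d  <- c(28.1, 35.9, 42.6, 51.2, 56.5, 59.3)
f  <- fit_digestion_curve(t6, d)
f
#> <kinetics_fit> a = 3.590 %, b = 60.392 %, c = 0.02154 /h, ext120 = 59.43 %
predict_digestion(f, c(0, 48, 120))
#> [1]  3.59 42.51 59.43

# lignin-marker digestibility: diet ratio weighted by DM intakes
r_diet <- diet_ratio(0.700 / 0.061, 0.24 / 0.02, dmi_forage = 3.31,
                     dmi_supplement = 0.335)
r_diet
#> [1] 11.52362
apparent_digestibility(5.0, r_diet)   # feces NDF:lignin of 5.0
#> [1] 0.56611  (kg/kg; the fraction of NDF disappearing across the tract)
```

Here `a` is the instantly disappearing fraction, `c` the fractional
digestion rate of the slow pool (0.0215 h⁻¹ is typical of a low-quality
grass fiber), and `ext120` the model's predicted digestion at 120 h.

End-to-end on synthetic data:

```r
res <- run_pipeline(sim_config(seed = 1), "run1")
res$clade_comparison     # % of the six responses explained per clade level
pipeline_report("run1")  # plain-text summary (kinetics, clades, genus lists)
```

## Command line

```sh
Rscript inst/scripts/rumenfiber simulate --out data --seed 7
Rscript inst/scripts/rumenfiber fit-kinetics --timecourses data/timecourses.csv --out fits.csv
Rscript inst/scripts/rumenfiber diversity --table data/counts.tsv --out div.csv
Rscript inst/scripts/rumenfiber filter --table data/taxon_table.tsv \
    --responses responses.csv --response-col NDF_rate --alpha 0.05 --out censored.tsv
Rscript inst/scripts/rumenfiber run --out run1 --seed 7
Rscript inst/scripts/rumenfiber report --run run1
```

## Documentation

The methods vignette (`vignettes/rumenfiber-methods.Rmd`) describes the
model and its assumptions, the optimiser, the censoring and selection
rules, what the synthetic generator does and does not emulate, and the
design decisions taken where conventions were open.
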