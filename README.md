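# peptidrift

Quantitative analysis of how a groove-binding drug remodels the peptide
repertoire presented by an MHC class I molecule.

Certain drugs (abacavir bound inside HLA-B\*57:01 is the paradigm) slot into
the peptide-binding groove of a specific HLA allotype and change which
self-peptides it selects. T cells then see "altered self", which can erupt
as life-threatening drug hypersensitivity. `peptidrift` is for
immunopeptidomics and MHC biochemistry labs who have the numeric outputs of
the standard experiments around this question — targeted-MS transition
areas, fluorescence-polarisation plate-reader traces, pulse-chase gel
densitometry, label-free proteome intensity matrices — and want the
downstream statistics done reproducibly.

## What it computes

**MRM time-course classification.** Per sample, peptide abundance is the
summed area of detected transitions normalised to the β2-microglobulin UV
peak (the per-sample yield of purified class I complexes); per condition,
replicates are averaged and each peptide's profile is scaled to its maximum
mean. The drug-impact category comes from the OLS slope *s* of normalised
abundance against exposure hour:

- *inhibited*: s < −0.02 h⁻¹
- *dependent*: s > +0.02 h⁻¹, undetected before exposure (≥ 2 of 3
  untreated replicates)
- *facilitated*: s > +0.02 h⁻¹ with pre-exposure signal, or
  constant-exposure signal more than twice the untreated signal
- *minimal impact*: otherwise

**FP binding kinetics.** Channel counts convert to millipolarisation via
mP = 1000(S − G·P)/(S + G·P); association fits
mP(t) = b + A(1 − e^(−k t)) and dissociation
mP(t) = b + A e^(−k_off t) (Levenberg–Marquardt, baseline fixed at the
50 mP unbound level by default), plus per-condition enhancement factors
(mean percentage of the intrinsic trace).

**Pulse-chase quantitation.** Maturation as % EndoH-resistant material,
100·EHR/(EHR+EHS); thermostability as IgG-normalised recovery relative to
the 4 °C lane, 100·(MHC_T/IgG_T)/(MHC_4/IgG_4).

**Null-proteome test.** Filter → log2 → left-shifted normal imputation
(downshift 1.8 sd, width 0.3 sd) → moderated statistic d = Δ/(se + s0) with
s0 = 1 → exact-permutation FDR at 5 %.

A synthetic-data generator with planted ground truth stands in for
instrument data, so the whole pipeline is testable offline; generator
defaults mirror the study design the package was built around (58 peptides
in 4 categories, triplicates over 0–16 h plus constant exposure, a
2,306-protein 3 vs 3 proteome).

## Worked example

```r
library(peptidrift)

sim      <- gen_mrm_dataset(mrm_sim_config(seed = 1))
profiles <- quantify(sim$transitions, sim$b2m)
calls    <- classify_peptides(profiles)
summarise_categories(calls)$category_counts
#> # A tibble: 4 × 2
#>   category        n
#>   <chr>       <int>
#> 1 inhibited       6
#> 2 minimal        20
#> 3 facilitated     8
#> 4 dependent      24
```

The counts are the four impact classes recovered from a noisy (CV 0.2)
synthetic 58-peptide cohort. Individual calls carry the fitted slope and the
rule that fired:

```r
head(calls[, c("peptide", "category", "slope", "rule_fired")], 4)
#> # A tibble: 4 × 4
#>   peptide category    slope rule_fired
#>   <chr>   <chr>       <dbl> <chr>
#> 1 pep001  inhibited -0.0568 slope_negative
#> 2 pep002  inhibited -0.0532 slope_negative
#> 3 pep003  inhibited -0.0539 slope_negative
#> 4 pep004  inhibited -0.0515 slope_negative
```

A slope of −0.057 means that peptide lost about 5.7 % of its peak
normalised abundance per hour of exposure. Binding kinetics work the same
way — simulate or load traces, then fit:

```r
traces <- gen_fp_trace(fp_sim_config(seed = 1), "association")$traces
fit_fp_traces(traces, "association")[, c("condition", "k_per_h", "half_life_h")]
#> # A tibble: 4 × 3
#>   condition k_per_h half_life_h
#>   <chr>       <dbl>       <dbl>
#> 1 abacavir   0.491        1.41
#> 2 both       1.51         0.461
#> 3 intrinsic  0.0982       7.06
#> 4 tapasin    0.797        0.870
```

Here intrinsic loading is slow (half-life ~7 h) and the drug, the chaperone
tapasin, and the combination accelerate it in that order — the planted
rates were 0.1/0.5/0.8/1.5 h⁻¹. `run_pipeline(pipeline_config(seed = 1),
out_dir = "run1")` runs all four stages and writes tidy CSV outputs plus a
manifest; `make_report()` turns a run into figures. See the vignette
(`vignettes/peptidome-remodelling.Rmd`) for the models, parameter meanings
and design decisions.

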