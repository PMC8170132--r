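---
title: "Measuring drug-induced remodelling of an MHC class I immunopeptidome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring drug-induced remodelling of an MHC class I immunopeptidome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Some small-molecule drugs bind inside the peptide-binding groove of
particular MHC class I allotypes (abacavir inside HLA-B\*57:01 is the
canonical case) and thereby change which self-peptides the molecule selects
and presents. The immune system can read the resulting "altered self" as
foreign, with severe hypersensitivity as the clinical consequence.
`peptidrift` implements the quantitative machinery needed to characterise
such remodelling from four complementary experiments:

1. **Targeted MS time courses** (`quantify()`, `fit_slope()`,
   `classify_peptides()`): tracking a panel of known peptide ligands by MRM
   transitions while drug exposure time increases, and sorting each peptide
   into one of four impact categories.
2. **Fluorescence-polarisation binding kinetics** (`fit_association()`,
   `fit_dissociation()`, `enhancement_factor()`): measuring how the drug
   and/or the loading chaperone tapasin change the association and
   dissociation rates of individual peptides in vitro.
3. **Pulse-chase gel quantitation** (`percent_endoh_resistant()`,
   `thermostability_recovery()`): asking whether the drug changes the bulk
   maturation rate or thermal stability of the MHC molecule itself.
4. **A null-proteome comparison** (`proteome_compare()`): verifying that
   observed peptidome changes are not explained by changes in source-protein
   abundance.

Each analysis stage starts from the numeric tables an instrument or its
vendor software produces (transition peak areas, channel count rates, band
densitometry, LFQ intensity matrices); upstream signal processing such as
peak integration, spectral searching or gel image segmentation is out of
scope.

## MRM quantitation and the four-way classification

For each (peptide, condition, replicate) sample, abundance is the summed
peak area of the detected transitions divided by the sample's
β2-microglobulin UV peak area — the light chain released by every purified
class I complex, so its peak is a per-sample measure of total HLA yield.
Undetected transitions contribute zero rather than an imputed value,
mirroring the binary presence/absence treatment of targeted MS data.
Replicates are averaged per condition and the profile is divided by its
maximum condition mean (the constant-exposure condition included), so the
peak of each profile is exactly 1 and profiles are comparable across
peptides of very different ionisation efficiency.

An ordinary least-squares slope of mean normalised abundance against
exposure hour is fit over the time course (0–16 h by default; the
constant-exposure condition never enters the regression). The rule set is:

| category    | rule                                                        |
|-------------|-------------------------------------------------------------|
| inhibited   | slope < −0.02 h⁻¹                                           |
| dependent   | slope > +0.02 h⁻¹ and undetected at t = 0 in > half the replicates |
| facilitated | slope > +0.02 h⁻¹ with pre-exposure signal, **or** constant-exposure signal > 2× the untreated signal |
| minimal     | otherwise                                                    |

Design choices worth stating explicitly:

* **Regression on condition means**, not individual replicates, is the
  default (`fit_to = "replicates"` switches), because the classified
  quantity is the mean profile; with balanced replicates the slope is
  identical either way.
* **Boundary handling**: the thresholds are strict inequalities on both
  sides, so a slope of exactly ±0.02 falls into *minimal*. The tests locate
  the boundary to 10⁻⁴ h⁻¹ rather than asserting float equality at it.
* **"Zero at t = 0"** is operationalised as "no transition detected in more
  than half of the untreated replicates" (≥ 2 of 3 in the triplicate
  design).
* The constant-exposure condition participates in max-normalisation and in
  the two-fold exception but never in the slope.

`summarise_categories()` adds the category counts and the C-terminal residue
tally — the anchor position whose preference the drug shifts from aromatic
(Trp/Phe/Tyr) towards small aliphatic (Ile/Leu/Val) residues.
`precursor_mz()` computes the monoisotopic m/z of the protonated drug ion
(287.2 for C14H18N6O at charge 1) used to monitor drug co-purification.

## Fluorescence-polarisation kinetics

Binding of a fluorescent (TAMRA-labelled) peptide to the MHC molecule slows
its tumbling and raises polarisation, reported in millipolarisation units
via mP = 1000 (S − G·P)/(S + G·P) (`mp_from_channels()`); the grating factor
G corrects the sensitivity difference between the parallel and perpendicular
detection channels. An unbound peptide is taken to sit at 50 mP, and
`fraction_to_mp()` maps a bound fraction linearly onto polarisation between
that baseline and the fully bound level.

Kinetics are modelled as single exponentials:
mP(t) = b + A(1 − e^(−kt)) for association and
mP(t) = b + A e^(−k_off t) for dissociation. Pseudo-first-order behaviour
is a defensible default because the labelled peptide is sub-stoichiometric
to receptive MHC in these assay designs; the baseline is fixed at 50 mP by
default but co-fittable (`fix_baseline = FALSE`). Fits use
Levenberg–Marquardt least squares initialised from a log-linearised rate
estimate. Two degenerate inputs are handled explicitly rather than fitted:

* a flat association trace (span above baseline below `no_binding_min`,
  default 10 mP) is flagged **no binding** — with no amplitude the rate is
  unidentifiable;
* a dissociation trace that decays by less than 5 % of its starting
  amplitude across the window is flagged **slower than resolvable** and only
  an upper bound on k_off is reported. Half-lives of hundreds of hours are
  real in this system, so refusing a point estimate is the honest output.

`enhancement_factor()` compares a condition trace (with chaperone, drug, or
both) to the intrinsic trace: each time point's polarisation ratio is
expressed as a percentage and averaged. Time points are matched exactly when
the plate schedules coincide (the expected case) and otherwise by nearest
neighbour within 1 % of the trace span.

## Pulse-chase quantitation

Maturation is read out as the percentage of EndoH-resistant material,
100·EHR/(EHR+EHS): resistance to endoglycosidase-H digestion marks
glycoproteins that have moved past the ER/cis-Golgi. Thermostability is the
percentage of MHC recovered after a thermal challenge relative to the 4 °C
lane, after normalising each lane's MHC band to its IgG heavy-chain loading
control: 100·(MHC_T/IgG_T)/(MHC_4/IgG_4). Both quantities are invariant to
any common rescaling of a lane's bands (exposure time, image scaling).
Recoveries above 100 % can arise under densitometry noise and are reported
with a warning, never clamped. Band tables are assumed background-corrected
by the densitometry software.

## The null-proteome comparison

LFQ protein intensities are cleaned (decoys, contaminants,
modification-site-only entries removed; proteins quantified in fewer than
three samples dropped), log2 transformed, and completed by left-shifted
normal imputation: missing values in sample s are drawn from
Normal(mean_s − 1.8·sd_s, (0.3·sd_s)²). The width 0.3 and downshift 1.8 are
the conventional defaults of the software ecosystem this mirrors; they are
exposed as parameters and the imputation note below applies. Each protein is
then scored with a moderated statistic d = Δ/(se + s0), where Δ is the
difference of group means, se the pooled-variance standard error, and s0 a
fudge factor (default 1) that damps artefactually small variances — with
s0 = 0, d is the ordinary two-sample t statistic, and that identity is
tested. Significance is decided by permutation: for the 3 vs 3 design all
distinct sample relabellings are enumerated exactly, the estimated FDR at a
threshold is the mean permuted count of |d| above it divided by the observed
count, the estimate is made monotone in the threshold (q-value convention),
and the smallest threshold with estimated FDR ≤ 5 % defines the cut.

Two interpretation decisions are recorded as such, both switchable:

* the "slope" of the published significance curve is read as the s0 fudge
  factor of the SAM-style moderated statistic, the standard meaning in the
  software named by the source analyses;
* the identity relabelling (and its mirror) is excluded from the permutation
  set, leaving the 9 non-trivial distinct splits of a 3 vs 3 design. Keeping
  it would floor every FDR estimate at 1/10 — the identity permutation
  reproduces the observed counts exactly — making a 5 % target unattainable
  and the test unable to call anything, including large planted effects.

A calibration limit follows directly and is worth knowing: with only nine
exact permutations the FDR estimate has 1/9 resolution, and on pure null
data the observed labelling is exchangeable with the other nine splits, so
in about one run in ten the top-ranked null protein exceeds every permuted
value and is called at estimated FDR 0. The realised false-positive
*proportion* stays far below the 5 % target (one call in thousands of
proteins), which is the property the module's test suite asserts; a
per-run guarantee of zero calls is not achievable with an exact 3 vs 3
permutation null at this target.

## The synthetic-data generator

Every stage is exercised against generated data with planted ground truth;
no instrument data is required anywhere in the package.

* **MRM** (`gen_mrm_dataset()`): the default cohort is 58 peptides in the
  4-category design of the motivating study (6 inhibited / 20 minimal / 8
  facilitated / 24 dependent), in triplicate at 0/2/4/6/12/16 h plus a
  constant-exposure condition simulated at each trajectory's asymptote.
  Trajectories are exponential decays (rate 0.15 h⁻¹) or saturating rises
  (rate 0.12 h⁻¹; facilitated peptides start at 20 % of plateau, dependent
  peptides at exactly zero). Transition areas carry multiplicative lognormal
  noise (CV 0.2 by default — the source experiments do not report a
  replicate noise magnitude, so this is a chosen working value, not a claim
  about the study) and scale with the sample's β2m yield; areas below the
  detection floor are reported absent. Planted C-terminal residues follow
  the reported anchor composition so residue tallies are testable.
* **FP** (`gen_fp_trace()`): the perpendicular channel is held at a constant
  count level and the parallel channel solved from the model mP, because
  plate readers report mP rather than raw counts, making the absolute count
  level arbitrary. Gaussian noise is added to both channels, with the
  channel sd calibrated per time point (delta method) so the propagated mP
  noise has the magnitude the user specifies in mP units.
* **Gels** (`gen_pulsechase_gels()`): band pairs are constructed from
  planted EHR fractions and per-temperature survival fractions under
  lognormal noise, with IgG loading-control bands for thermostability lanes.
* **LFQ** (`gen_lfq_matrix()`): 2,306 proteins (the quantified-proteome
  scale of the motivating comparison) in a 3 vs 3 design; between-protein
  log2 intensities ~ N(26, 2), within-protein replicate sd 0.2, and
  missing-not-at-random dropout from a logistic left-censoring model so the
  downstream left-shifted imputation is exercised as intended.

What the generator does *not* emulate — chromatographic peak shape,
interference between transitions, batch effects, heteroscedastic
intensity-dependent LFQ noise, real biological correlation between
proteins — bounds what passing tests show: they demonstrate that the
implemented procedures are correct and well calibrated under their own
stated models, not that those models capture every artefact of real
instrument data.

## Problem sizes and numerics

The test suite runs the study-scale designs directly: 58-peptide cohorts
over 20 seeds for classifier recovery, 50-seed simulate–fit round trips for
both rate constants at 2 mP noise, and 20-seed null plus 20-seed spike-in
runs of the full 2,306-protein proteome chain. Non-linear fits converge in
milliseconds on traces of 50–100 points; the whole suite completes in a few
minutes on one core. Slope fitting is plain OLS (`lm`), checked against the
closed-form estimator to 10⁻¹⁰; exponential fits are checked by noiseless
round trips to 10⁻⁶ relative. All generators are deterministic given a
config and seed, and `run_pipeline()` records the seed and every derived
sub-seed in its manifest so any number in the output tree can be reproduced.

## Worked example

```{r example}
library(peptidrift)

cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")
res$mrm$summary$category_counts
make_report(res, out_dir = "run1/report")
```

## Known limitations

* The classifier consumes per-condition means; replicate-level regression is
  available but uncertainty in the slope is not propagated into the category
  call.
* Single-exponential kinetics only; traces with genuine multi-phase
  behaviour will show structured residuals (inspect the `fitted` column).
  A two-phase model was considered and deliberately deferred: the data the
  package targets do not constrain it.
* The permutation FDR is exact but coarse for 3 vs 3 designs (nine splits);
  larger designs switch to sampled relabellings.
* Equilibrium affinities (K_D) are not estimated — the assays measured here
  are kinetic only.
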