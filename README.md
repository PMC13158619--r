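# screenfunnel

Staged hit calling for cell-based luciferase reporter screens.

High-throughput reporter screens rarely end at "which wells lit up".
A typical campaign — here modelled on an *HMOX1*-luciferase screen for
functional BACH1 inhibitors — proceeds through a funnel: plate-level
quality control, normalisation against on-plate controls, a
control-derived activation cut-off, a dose–response efficacy filter
against a reference inhibitor, and a cytotoxicity counter-screen that
removes compounds whose apparent activity is a stress artefact.
`screenfunnel` implements that funnel as composable, tibble-first R
functions, plus a synthetic screen generator with planted ground truth so
the entire analysis can be developed, tested and demonstrated without
wet-lab data.

It is intended for screening scientists and computational biologists who
need a reproducible, scriptable version of the plate-to-candidate
pipeline, and for anyone who wants a realistic test bed for benchmarking
hit-calling rules.

## The statistics at the core

For each 384-well plate (one blank column, one 16-well column each of
DMSO, hemin and CDDO controls, 320 test wells at 10 µM):

- **Blank correction** — subtract the median of the media-only wells.
- **Plate-normalised fold change** —
  FC(well) = corrected(well) / median(corrected DMSO wells on that plate).
- **Robust Z′** on blank-corrected control luminescence,

  rZ′ = 1 − 3·(MAD₊ + MAD₋) / (median₊ − median₋),

  with hemin as positive (+) and DMSO as negative (−) control and MAD the
  *raw* median absolute deviation (no 1.4826 consistency constant).
- **Signal-to-background** — SB = mean₊ / mean₋.
- **Activation cut-off** — the mean fold change of the CDDO wells (a
  non-specific NRF2 activator; ≈ 2.5): a primary hit must beat the
  non-specific inducer, mean FC over two replicates strictly > cut-off.
- **Efficacy benchmark** — the lower edge of the hemin response,
  mean − 3·SD of hemin fold changes (≈ 7.8). Each hit's 8-point
  concentration–response (0.01–30 µM) is fitted with a 4-parameter
  logistic FC(c) = bottom + (top − bottom)·cʰ/(EC50ʰ + cʰ), and the
  minimal effective concentration (MEC) solving FC(c) = benchmark is
  obtained analytically; compounds needing more than 10 µM fail.
- **Viability gate** — compounds whose viability (fraction of the DMSO
  control) at their MEC is below 70 % are excluded; survivors are the
  final candidates.

A qPCR module computes comparative ΔΔCt fold changes
(FC = 2^(−ΔΔCt), normalised to HPRT1) and applies a rule-based
signature call separating functional BACH1 inhibition (HMOX1, ZNF469,
HTRA3 induction) from bare NRF2 activation (AKR1B10 only).

## Worked example

```r
library(screenfunnel)

led <- run_screen_pipeline(generator_config(seed = 1))
led
#> screened:          2046 compounds
#> primary hits:      34 (mean FC > 2.497, CDDO-derived)
#> efficacy pass:     13 (reach 8.427-fold at <= 10 uM)
#> final candidates:  4 (viability >= 70% at effective conc.)
#> thresholds:        activator_cutoff = mean(CDDO FC) over 224 wells; benchmark = mean - 3*sd(hemin FC) over 224 wells
#> plate QC (rZ' / SB):
#>   P1 rep 1: rZ' = 0.610, SB = 13.55 [pass]
#>   P1 rep 2: rZ' = 0.710, SB = 13.46 [pass]
#>   ...
```

The simulated campaign screens 2046 compounds on 7 plates × 2
replicates. All 14 plate-replicates pass QC (rZ′ ≥ 0.5, SB well above
background). The CDDO-derived cut-off comes out at 2.497-fold and the
hemin benchmark at 8.43-fold for this seed; 34 compounds exceed the
cut-off, 13 reach the benchmark at ≤ 10 µM, and 4 survive the 70 %
viability gate — exactly the planted inactive / weak / potent / toxic
structure of the generator (`planted_counts(led$truth)`).

Individual stages are ordinary functions on data frames:

```r
lib   <- generate_truth_library(generator_config(seed = 1))
wells <- simulate_screen(lib$truth, generator_config(seed = 1))
fc    <- fold_change_normalise(blank_correct(wells))
plate_qc(wells |> blank_correct())          # per-plate rZ', SB
derive_thresholds(fc)                       # 2.5 / 7.8-style thresholds

d   <- simulate_dose_response(lib$truth, compounds = "C0258", seed = 1)
fit <- fit_hill(d)
tidy(fit)                                   # bottom / top / ec50 / hill
min_effective_concentration(fit, 7.8)       # MEC in µM
autoplot(fit, benchmark = 7.8)              # curve + benchmark line
```

`tidy()`, `glance()` and `autoplot()` methods are provided for fits and
for the pipeline ledger; `parse_plate_matrix()`, `parse_plate_long()`
and `load_manifest()` read the plate-reader and manifest CSV dialects
for measured data, which enter the same pipeline via
`run_screen_pipeline(data = list(wells = ..., dose = ..., viability = ...))`.

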