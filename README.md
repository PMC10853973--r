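# glycoCE

Collision-energy (CE) optimization analysis for N-glycopeptide tandem
mass spectrometry.

## What problem this solves

In beam-type CID/HCD, the collision energy that best fragments an
N-glycopeptide depends on the species — and on what you want out of the
spectrum. Engines that score the peptide backbone (Byonic, pGlyco
peptide score) peak at roughly **twice** the energy of engines that
score the glycan (pGlyco glycan score, GlycoQuest), because glycosidic
bonds dissociate far more easily than amide bonds. Instruments pick CE
from m/z alone; structural covariates (peptide hydrophobicity, mobile
protons, glycan mass / sialylation) shift the per-species optimum by
several eV around that line.

glycoCE takes CE-resolved search-engine score tables (one report per
LC-MS/MS run across an energy sweep, e.g. 6.25–175% of a reference line
in 6.25% steps) and:

- extracts the per-species **optimal CE** as the center $\hat\mu$ of a
  Gaussian $s(E)=A\,e^{-(E-\mu)^2/2\sigma^2}$ fitted to each
  score-versus-energy curve (damped nonlinear least squares, with
  eligibility filters on score thresholds and consecutive identified
  settings);
- models the optimum per score channel: linear m/z trendlines,
  ANCOVA-style general linear models with a homogeneity-of-slopes gate,
  and an L1-regularization path with an empirical minimal-feature rule;
- quantifies the score gain of a **smart CE** — predicting the energy
  from {m/z, total mass, glycan mass, peptide-only m/z, hydrophobicity},
  all obtainable online — over the classical m/z-only rule, per species
  and for the bottom fifth of species by baseline score;
- **simulates** the whole sweep experiment (structured cohorts,
  engine personas, lognormal peak scores, detection-threshold
  missingness, within-run duplicates), so the complete pipeline runs and
  is testable without any instrument data.

The default instrument model is 50 eV at m/z 600 → 135 eV at m/z 2000
(linear, 200 eV hardware ceiling).

## Worked example

```r
library(glycoCE)

sim    <- synthetic_cohort(n = 150, seed = 1)      # simulate the sweep
tab    <- aggregate_best_per_run(sim$records)      # best match per run
curves <- build_curves(tab)                        # score-vs-energy curves
optima <- fit_optima(curves)                       # Gaussian centers

curves[[1]]
#> <score curve> ACGCEDNFTPPDLDIELR|HexNAc(4)Hex(5)|3 [byonic] 21 points, CE 27.9-139.7 eV
fit_gaussian(curves[[1]])
#> <gaussian fit> A=596  center=82.465 eV  sigma=30.130 eV  (n=21, converged)

d <- optima[optima$channel == "byonic", ]
fit_trendline(d$mz, d$optimal_ce_ev, "byonic")
#> <trendline byonic> CE = 0.0629 * m/z + 6.41  (R2 = 0.921, n = 125)
g <- optima[optima$channel == "glycoquest", ]
fit_trendline(g$mz, g$optimal_ce_ev, "glycoquest")
#> <trendline glycoquest> CE = 0.0323 * m/z + 1.85  (R2 = 0.819, n = 112)

evaluate_gain(curves, optima, sim$features, "byonic", mode = "loo")
#> <gain report> byonic (loo, n = 125)
#>   mean gain:            +4.6%
#>   bottom-quintile gain: +5.1%
```

Reading the output: the peptide-centric channel's optimum climbs
~0.063 eV/Th; the glycan-centric channel needs about half that energy
(0.032 eV/Th) — the two-regime structure that motivates per-channel CE
choice. The smart multivariate CE prediction buys a +4.6% mean score
over the m/z-only rule on this cohort, more for the species that
started with low scores.

Or run everything (simulate → ingest → fit-curves → model →
evaluate-gain, resumable, checksummed, seed-deterministic):

```r
run_pipeline(validate_config(NULL))   # writes glycoce_run/
```

A YAML config controls the calibration, sweep grid, eligibility policy,
modeling options and seed; see `validate_config()`.

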