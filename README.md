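# dvos

Simulation and analysis of **dynamic vascular optical spectroscopy (DVOS)**
recordings for detecting **peripheral arterial disease (PAD)** in diabetic
cohorts — where the standard ankle-brachial index loses sensitivity because of
arterial calcification.

A thigh cuff is inflated through five one-minute phases (baseline, 60 mmHg,
recovery, 100 mmHg, recovery) while four laser wavelengths (670/780/808/850 nm)
and two photodetectors sample foot tissue at 2.56 Hz. Venous occlusion blocks
outflow while arterial inflow continues, so tissue hemoglobin pools at a rate
set by distal arterial patency. The package implements the full measurement
chain and the statistics used to judge its diagnostic value, plus a calibrated
synthetic cohort generator so that every stage is testable without patient
data (the clinical recordings are not public).

## What it computes

From each reconstructed trace (modified Beer–Lambert inversion,
ΔOD(λ,t) = [ε_HbO·ΔHbO + ε_HbD·ΔHbD]·L·DPF, after SNR ≥ 4 channel screening
and zero-phase 2nd-order Butterworth filtering at 0.51 Hz), four parameters
per occlusion pressure:

| parameter | definition | units |
|---|---|---|
| ΔHbO | max occlusion HbO − mean HbO over the 5 s pre-inflation | µmol/L |
| HF | max least-squares HbT slope over six 5-s windows in the first 30 s, reported as the steepest-interval rise | µmol/L per 5-s interval |
| VO₂ | max HbD slope × 0.5376 (4 O₂/Hb, 22.4 mL/mmol, per min, per 100 mL) | mL O₂/100 mL/min |
| Tp | time HbT spends above 90% of its occlusion maximum, from the rising crossing to the first falling crossing after deflation | s |

Group comparison uses Mann–Whitney U at the Bonferroni threshold
0.05/8 = 0.00625; classification uses one logistic model per parameter
adjusted for age, diabetes duration, hypertension duration, sex, BMI and
smoking, evaluated by stratified fivefold cross-validation with pooled
out-of-fold ROC/AUC and a 0.50 probability threshold.

## Worked example

```r
library(dvos)
run <- run_pipeline(run_config(seed = 42))   # 118 PAD + 118 non-PAD, ~6 s
run
#> <dvos_run> 236 subjects (0 excluded); pooled AUC (hf_60) = 0.9453

subset(run$table1, pressure == 60)[, c("parameter", "mean_nonpad", "mean_pad",
                                       "p_value", "significant")]
#>   parameter mean_nonpad mean_pad  p_value significant
#> 1 delta_hbo      6.9459   2.0931 3.65e-23        TRUE
#> 2        hf      2.4647   0.8214 2.98e-33        TRUE
#> 3       vo2      0.0722   0.0378 1.85e-15        TRUE
#> 4        tp     21.7901  15.9534 2.92e-07        TRUE

run$cv$hf_60$pooled$confusion
#>         predicted
#> truth    nonPAD PAD
#>   nonPAD    103  15
#>   PAD        15 103
```

Every synthetic subject carries latent ground-truth feature targets drawn
from the calibration table (`inst/extdata/calibration_v1.tsv`, the printed
group mean ± SD of each parameter); the run above recovers the non-PAD HF
calibration mean of 2.48 µmol/interval as 2.465 and separates the groups far
below the 0.00625 threshold. The ΔHbT–ΔHbO correlation emerges from the
additive identity HbT = HbO + HbD rather than being imposed
(`run$spearman`: ρ ≈ 0.96 at 60 mmHg).

Stages are also exposed as CLI verbs operating on documented text formats:

```sh
Rscript -e 'dvos::dvos_cli()' simulate --seed 1 --out runs/demo --n-pad 5 --n-nonpad 5
Rscript -e 'dvos::dvos_cli()' reconstruct --in runs/demo --out runs/demo
Rscript -e 'dvos::dvos_cli()' features --in runs/demo --out runs/demo
Rscript -e 'dvos::dvos_cli()' analyze --in runs/demo --out runs/demo
```

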