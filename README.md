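# pnmsDCE

Probabilistic nested model selection (PNMS) for pharmacokinetic analysis of
dynamic contrast-enhanced (DCE) MRI.

## What it does, and for whom

In DCE-MRI of brain tumors, each voxel's contrast-agent concentration trace
ΔR1(t) is conventionally described by the simplest supported member of a
nested hierarchy of Patlak-family models:

```
Model 1:  C_t(t) = vp · C_a(t)                                (normal vasculature)
Model 2:  C_t(t) = vp · C_a(t) + Ktrans ∫ C_a(λ) dλ           (leakage, no back-flux)
Model 3:  C_t(t) = vp · C_a(t) + Ktrans ∫ C_a(λ) e^{−Kep(t−λ)} dλ  (leakage + back-flux)
```

with `C_a` the arterial input function, `vp` the plasma volume fraction,
`Ktrans` and `Kep` (1/min) the forward/reverse transfer constants and
`ve = Ktrans/Kep` the interstitial volume fraction. Conventional nested
model selection (NMS) fits all three per voxel and picks a single label by
sequential partial F-tests at a 95% confidence level. But voxels contain
admixtures of vasculature, so this package also implements the
probabilistic variant: a batch-trained 8×8 hexagonal Kohonen
self-organizing map (SOM) over shape-normalized ΔR1 profiles, whose
NMS-labeled hit maps yield per-voxel probabilities `(P1, P2, P3)` of each
nested model, 50%-threshold model regions, and probability-weighted
(model-averaged) permeability maps:

```
vp     = (P1·vp_M1 + P2·vp_M2 + P3·vp_M3) / (P1+P2+P3)
Ktrans = (P2·Kt_M2 + P3·Kt_M3) / (P2+P3)
ve     = Ktrans / Kep_M3
```

It is aimed at quantitative-imaging researchers who want a reproducible,
tested reference implementation of the NMS/PNMS pipeline, complete with a
synthetic phantom generator (the published animal cohort is not public) and
a subject-level nested cross-validation harness reporting Dice similarity
and mean percent differences (MPD = 100·(PNMS−NMS)/NMS).

## Worked example

```r
library(pnmsDCE)

grid <- timeGrid()            # 400 frames, 1.55 s apart, bolus at ~60 s,
aif  <- makeAIF(grid)         # first 20 frames excluded from analysis

## one synthetic "animal": 32x32x3 voxels, SNR 20
study <- simulateStudy(phantomSpec(noiseSd = 0.05), grid, aif)
study
#> SyntheticStudy 'A01': 32 x 32 x 3 x 400 frames; labels M1 = 2448, M2 = 240, M3 = 384

## conventional nested model selection
nms <- fitVolume(study)
nms
#> NMSVolumeResult: 32 x 32 x 3 volume, 3072 voxels in mask (CL = 95%)
#>   labels: M1 = 2343, M2 = 373, M3 = 356

## SOM -> neuron probabilities -> voxel probabilities -> averaged maps
profiles <- excludeAndNormalize(
  matrix(study@dr1, prod(dim(study@mask)), nFrames(grid)), grid)
som <- batchTrain(profiles, somConfig())
tab <- neuronProbabilities(
  computeHitMap(som, profiles, modelLabels(nms)[brainMask(nms)]), som)
pv  <- voxelProbabilities(study, som, tab)
pnmsParameterMaps(nms, pv)
#> AveragedParameterMaps: 32 x 32 x 3; mean vp = 2.543%, mean Ktrans = 0.0375 /min
```

The label counts show what hard selection does at SNR 20: most true Model-2/3
voxels are found, a few spill across the nested boundaries — exactly the
instability model averaging is meant to soften. A full cross-validated
comparison over a 12-animal cohort:

```r
cohort <- makeCohort(12, phantomSpec(noiseSd = 0.05), grid, aif, seed = 1)
report <- runNestedCV(cohort, k = 3, seed = 1)
report
#> EvaluationReport (k = 3 folds)
#>   DSC Model 2: 0.780 [0.772, 0.793]
#>   DSC Model 3: 0.907 [0.902, 0.916]
#>   MPD vp = 2.16%, Ktrans = 24.65%, ve = -54.78%
```

Dice coefficients compare the PNMS 50%-threshold regions with the NMS
regions on held-out animals: agreement is high for both leaky models and
higher for Model 3 than Model 2, the same qualitative ordering reported for
the animal data. The MPD rows quantify how far the model-averaged
parameter means sit from the hard-selection means on each technique's own
regions.

The same pipeline is scriptable end to end (YAML config, deterministic
seeds, NIfTI/CSV/JSON artifacts):

```sh
Rscript inst/scripts/pnms_pipeline.R --config inst/extdata/default_config.yaml \
        --stage all --out pnms_out --seed 1
```

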