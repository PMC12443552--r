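# synthCBV

Synthesis of cerebral-blood-volume (CBV) perfusion maps from arterial spin
labeling (ASL) and standard structural MRI, for cohorts in which modalities
are missing subject by subject.

## The problem

CBV maps from dynamic susceptibility contrast MRI (DSC-MRI) help separate
brain-tumour recurrence from treatment response, but they require a rapid
gadolinium bolus ("bolus effect") that many post-radiotherapy patients
cannot receive.  ASL measures perfusion without contrast, at lower
resolution and SNR.  `synthCBV` is for imaging researchers who want to
*translate* ASL cerebral-blood-flow maps plus standard sequences (T1WI,
T2WI, T2-FLAIR, ADC, post-contrast T1WI) into bolus-independent synthetic
CBV maps — and to do so on realistic archives where only a fraction of
scans carry ASL, and available sequence combinations vary per scan.

## The model

An *incrementable* 3D encoder–decoder: one convolutional encoder `E_m` per
input modality, one shared decoder `D_CBV`.  With `a_m ∈ {0,1}` the
availability flag of modality `m` and `S_m` its image, the synthetic CBV
map is

    S_CBV = D_CBV( Σ_m a_m E_m(S_m) / Σ_m a_m )

— the bottleneck feature maps of the present modalities are averaged and
decoded.  Setting `a_m = 0` is bit-identical to omitting the modality (the
test suite asserts this), so a single model trained once — with per-epoch
random modality dropout — serves all 16 benchmark combinations of
ASL-CBF with {T1, T2, T2-FLAIR, ADC} (17 with the post-contrast row), and
every archived scan can contribute to training whatever sequences it has.
A fixed-combination baseline encoder–decoder of matched architecture is
included for comparison; unlike the incrementable model it must discard
every training subject missing one of its modalities.

Training follows the reference protocol: MAE loss inside the brain
bounding box, Adam at learning rate 0.001, a constant epoch budget with no
validation set, and a random 3:1 train:test split (patient-level by
default).  Evaluation is SSIM (reported in percent) and PSNR (dB, with
quality bands: >40 very good, 30–40 good, 20–30 bad, <20 very bad)
computed over the bounding box of each brain.  Since no public cohort of
co-registered multi-contrast MRI with quantitative CBV exists, the package
ships a phantom generator whose ground-truth CBV is a known function
(`v^1.2`) of a latent vascularity field `v`, with ASL-CBF a noisy reading
of `v` — so the whole pipeline is testable end to end and synthesis
quality has a known target.

The network layers (3D convolutions via im2col + BLAS, hand-derived
backpropagation, Adam) are implemented in the package itself; see the
methods vignette (`vignettes/cbv-synthesis-methods.Rmd`) for the
architecture, all tunable parameters, and design rationale.

## Worked example

Generate a phantom cohort in which a quarter of the subjects lack ASL,
train the incrementable model, and evaluate a held-out subject:

```r
library(synthCBV)

params <- phantomParams(grid = c(16, 16, 16), nLesions = 0L,
                        noiseSd = 0.02, aslFraction = 0.75, seed = 1)
cohort <- makeCohort(params, 16)
parts  <- splitCohort(cohort, ratio = 3, level = "patient", seed = 1)

fit <- trainIEDN(initIEDN(iednConfig(levels = 2, baseChannels = 8, seed = 1)),
                 parts$train, trainConfig(epochs = 100, seed = 1))
round(lossHistory(fit$report)[c(1, 100)], 4)
#> [1] 0.2261 0.0227

evaluateSubject(fit$model, parts$test[[1]])
#> MetricResult: SSIM 65.51%, PSNR 19.66 dB (very_bad)

df <- comboResults(sweepCombinations(fit$model, parts$test))
df[c(1, 16), c("combo", "n", "ssim_mean", "psnr_mean")]
#>                         combo n ssim_mean psnr_mean
#> 1                     ASL-CBF 2  76.22321  20.60504
#> 16 ASL-CBF+T1+T2+T2-FLAIR+ADC 2  72.20400  20.47930
```

The mean training MAE falls from 0.23 to 0.023 over 100 epochs.  The
held-out metrics are modest because this demo is deliberately tiny (16³
voxels, 12 training subjects, a minute of CPU): each `MetricResult` is the
SSIM/PSNR of the synthetic against the ground-truth CBV over that
subject's brain bounding box, and each sweep row evaluates the *same*
trained model restricted to one modality combination via its presence
flags.  At the package's full experiment scale (32³ phantoms, 200
epochs) the test suite asserts held-out mean SSIM of at least 0.85, and
the acceptance script prints the value it measures for your seed.  Note
the sweep: at this scale ASL alone can outscore the full combination — the
phantom's CBV is a function of the latent that ASL measures directly, so
mean-fusion with weaker structural latents can dilute it; the methods
vignette discusses when the real-data "more inputs help" trend does and
does not transfer to phantoms.

A command-line entry point wraps the same functions
(`inst/cli/iednsynth`): `phantom`, `train`, `synthesize` (with `--drop
aslcbf` to simulate absent ASL), `evaluate`, and `sweep` subcommands, each
writing a JSON run manifest for replay.

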