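# FAIRmbf

Quantitative myocardial perfusion mapping from **FAIR arterial spin
labeling** (flow-sensitive alternating inversion recovery), for
researchers working on contrast-agent-free cardiac perfusion MRI and
its postprocessing.

FAIR compares a short-axis image acquired after a slice-selective
inversion (*control*) with one acquired after a nonselective inversion
(*tagged*): in-flowing arterial blood is inverted only in the tagged
case, so the difference encodes tissue perfusion. With double gating
(inversion and readout triggered to the same cardiac phase in adjacent
cycles) and separate inversion times for the averaged control and
tagged images, myocardial blood flow per pixel is

```
MBF = 1/(2 M0) * [ (C / TI_C) e^(-TI_C/T1)  -  (T / TI_T) e^(-TI_T/T1) ]
```

with `T1` the blood longitudinal relaxation time (1700 ms at 3 T),
converted to ml/g/min. The package implements the full postprocessing
pipeline around that formula — ROI cropping, within-series rigid
registration (mean squares), inversion-time correction
`I_corr = M0 + (I - M0) e^(dTI/T1)`, series averaging, registration of
the averages to M0 (mutual information), quantification — plus:

* a **synthetic short-axis phantom** with known ground truth: annular
  left-ventricular myocardium at diastolic or systolic wall thickness,
  inversion-time jitter, per-breath-hold rigid motion, thermal noise,
  and physiological noise that grows with the excess of the readout
  window over the cardiac rest period;
* **evaluation metrics**: temporal SNR from six per-pair MBF maps,
  analyzable-pixel counts, regional (septal/anterior/lateral/inferior)
  summaries;
* a **three-protocol comparison** — diastolic parallel-imaging FAIR
  (`FAIR-PI2_D`), systolic parallel-imaging FAIR (`FAIR-PI2_S`) and
  systolic compressed-sensing FAIR (`FAIR-CS3_S`) — with one-way ANOVA
  and paired post-hoc t-tests;
* NIfTI + JSON-sidecar I/O and a command-line interface.

See the methods vignette (`vignettes/fair-asl-methods.Rmd`) for the
models, assumptions and design decisions.

## Worked example

Simulate one synthetic subject with the diastolic protocol, run the
pipeline, and quantify:

```r
library(FAIRmbf)

spec <- PhantomSpec(seed = 11)          # true MBF 1.5 ml/g/min
prot <- fairProtocol("FAIR-PI2_D")
sim  <- simulateSeries(spec, prot)      # 6 control + 6 tagged + M0

prep <- preprocessSeries(sim$series)    # crop, register, TI-correct, average
myo  <- FAIRmbf:::cropMatrix(sim$truth@myoMask, sizePx = 64)
map  <- mbfMap(prep@controlAvg, prep@taggedAvg, prep@m0,
               prep@tiControlMs, prep@tiTaggedMs, t1Ms = 1700, myo = myo)
map
#> MBFMap: 64x64 px, 428 myocardial px (428 valid)
#>   myocardial MBF 1.146 +- 0.725 ml/g/min

pairs <- perPairMaps(sim$series, myo = myo)
tsnr(pairs, mask = myo)
#> [1] 13.22474
#> attr(,"defined")
#> [1] TRUE
```

The map recovers the configured 1.5 ml/g/min up to noise and
partial-volume blur at the annulus edges (this seed's motion draws are
relatively large, costing edge signal); the TSNR of ~13 reflects the
spread of the six per-pair ROI means. On an uncorrupted phantom
(`PhantomSpec(tiJitterFrac = 0, motionTransPx = 0, motionRotDeg = 0,
thermalSigma = 0, physioK = 0)`) the same pipeline returns 1.5 exactly
(to 1e-9 relative) — the phantom's forward model is the algebraic
inverse of the quantifier.

The cohort-level experiment (12 synthetic subjects x 3 protocols,
~5 min):

```r
ex <- runExperiment(nSubjects = 12, seed = 1)
ex$reports$tsnr
#> ComparisonReport for 'tsnr'
#>   one-way ANOVA: F(2, 33) = 28.67, p = 6.075e-08
#>    protocol  n      mean       sd
#>  FAIR-CS3_S 12 12.011100 2.940616
#>  FAIR-PI2_D 12 18.618909 6.972754
#>  FAIR-PI2_S 12  4.243842 2.782812
#>   paired post-hoc t-tests:
#>      group1     group2 mean_diff            p significant
#>  FAIR-CS3_S FAIR-PI2_D -6.607809 1.976094e-02        TRUE
#>  FAIR-CS3_S FAIR-PI2_S  7.767258 1.254930e-07        TRUE
#>  FAIR-PI2_D FAIR-PI2_S 14.375067 4.881268e-05        TRUE
```

Systolic imaging yields ~1.3x more analyzable myocardial pixels than
diastolic (the wall is thicker in systole), but systolic
parallel-imaging FAIR pays a temporal-SNR penalty because its 165 ms
readout overhangs the ~90 ms systolic rest period; compressed sensing
shortens the readout to 110 ms and recovers most of that penalty. Mean
MBF does not differ between protocols (`ex$reports$mean_mbf`).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fairasl.R", package = "FAIRmbf"))')
Rscript $CLI simulate --protocol FAIR-PI2_S --seed 3 --out out/
Rscript $CLI quantify --series out/series.nii.gz --out out/
Rscript $CLI full-run --n-subjects 12 --seed 1 --out out/
Rscript $CLI full-run --no-registration ...   # motion-correction ablation
```

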