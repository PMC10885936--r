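# wbdwiNorm

Automated signal standardisation for whole-body diffusion-weighted MRI
(WBDWI).

WBDWI scans cover a patient as 4–5 separately acquired anatomical
stations whose intensities are not comparable — across stations, scans,
patients or imaging centres. That variability breaks fixed display
windows, longitudinal comparison, and automated bone-lesion delineation.
`wbdwiNorm` standardises the signal using nothing but the diffusion
acquisition itself, with the spinal canal (spinal cord + surrounding
CSF) as an internal reference region:

1. **Diffusion model fitting** — per voxel, ordinary least squares on
   the log-signal of the monoexponential model
   `S(b) = S0·exp(−b·ADC)`, yielding ADC (mm²/s) and S0 maps.
2. **Computed DWI (cDWI)** — synthesis of a high-b-value volume
   `S(b_c) = S0·exp(−b_c·ADC)` at `b_c` = 900 s/mm².
3. **Inter-station harmonisation** — a linear scale per station
   boundary, minimising the mean squared difference between cumulative
   frequency curves of slices on either side of the boundary.
4. **Spinal-canal segmentation** — a 2D U-Net (self-contained
   C++/R implementation: convolutions, batch norm, transposed
   convolutions, Adam, and the log-cosh Dice / Combo / Tversky / Focal
   Tversky losses) on two-channel slices (scaled ADC, scaled log-S0).
5. **Cord/CSF characterisation** — a 2-component Gaussian mixture of
   in-canal ADC values (cord ≈ 1.7, CSF ≈ 3.2 ×10⁻³ mm²/s) with
   volume and cross-section statistics.
6. **Normalisation** — division of the whole volume by the 90th
   percentile of in-canal cDWI signal, making a fixed display window
   (level 1.5, width 3.0) meaningful on every scan.

A parametric multi-station phantom generator (tube-shaped canal with
cord core and CSF ring, known station gains, Rician noise, ground-truth
masks) makes the whole pipeline testable without patient data.

## Worked example

```r
library(wbdwiNorm)

# 3-station phantom, known gains (1, 1.3, 0.8), Rician noise
ph <- generatePhantom(phantomSpec(nStations = 3, slicesPerStation = 12,
                                  stationGains = c(1, 1.3, 0.8), seed = 7))

# train the reduced canal segmenter on independent phantoms (~6 min, 1 CPU)
bench <- segmentationBenchmark(nPhantoms = 15, epochs = 30, seed = 1)
bench$valMetrics
#>      dice precision    recall
#>         1         1         1

res <- runPipeline(ph$study, bench$model, pipelineConfig(seed = 1))
res$normalised
#> NormalisedStudy: 36 slices; station factors 1, 0.7761, 1.23; canal reference 153.3
res$gmm
#> 2-component ADC mixture (units 1e-3 mm^2/s):
#>   cord: weight 0.449, mean 1.581, variance 0.282
#>   CSF : weight 0.551, mean 2.790, variance 0.862
```

The predicted canal mask matches the ground truth (Dice 1 on this
phantom), the station factors invert the simulated gains (1/1.3 ≈ 0.769,
1/0.8 = 1.25, recovered within ~2% despite Rician noise), and after
normalisation the 90th percentile of in-canal signal is exactly 1, so
the volume is displayable with the fixed window. The mixture separates
the cord and CSF components of the *fitted* ADC map; on this noisy
phantom their means sit below the ground-truth draw parameters (1.7 and
3.2) because Rician noise biases the per-voxel ADC fit — fitting the
ground-truth ADC values directly recovers 1.7/3.2, which is what the
mixture-recovery experiment in `scripts/acceptance.R` measures.
`mip(vol, "coronal")` produces the whole-body maximum-intensity
projection used for review.

A command-line front end over the same functions is installed at
`inst/scripts/wbdwi.R` with subcommands `simulate`, `fit-adc`, `train`,
`segment`, `gmm`, `normalise` and `run`.

## Package layout

- `R/` — S4 classes (`DWIStudy`, `ParametricMaps`, `CanalSegmentation`,
  `GMMResult`, `NormalisedStudy`, …), the diffusion model, the network
  engine, mixture modelling, harmonisation/normalisation, phantom
  generator, IO and pipeline orchestration.
- `src/` — C++ convolution/pooling primitives (RcppArmadillo).
- `vignettes/wbdwi-standardisation.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations.
- `tests/testthat/` — unit, property and end-to-end tests.
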