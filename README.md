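# nanoPSD

Detection and morphometric characterization of biogenic nanoparticles in
transmission electron micrographs.

Cyanobacteria such as *Anabaena* sp. and *Calothrix desertica* can
biosynthesize metallic nanoparticles (gold, cerium, other rare earths)
intracellularly. The particles of interest are tiny — roughly 2–12 nm in
equivalent circular diameter — and sit inside a cluttered cellular matrix
whose components often share their gray values, so routine "threshold and
count" workflows misfire. nanoPSD implements the full digital
image-processing chain needed to quantify such particles reproducibly:

1. **Calibration** — nm/px from the micrograph's scale bar
   (`calibrate()`), optional crop / mean-filter smoothing / unsharp-mask
   sharpening (`preprocess()`).
2. **Segmentation** — percentile thresholding on the gray histogram
   (`thresholdMask()`), connected components under 4- or 8-connectivity,
   interior-hole inclusion, exclusion of regions touching the image edge,
   and pixel / nm² area restriction (`extractParticles()`,
   `restrictionSweep()`).
3. **Morphometry** (`measureParticles()`) — per particle:
   - area `A = N_px · (nm/px)²`,
   - equivalent circular diameter `ECD = √(4A/π)`,
   - moment-fitted ellipse with full axes `a ≥ b` (area-preserving),
   - maximum Feret diameter `D_f` (rotating calipers over the hull of the
     pixel corners),
   - reciprocal aspect ratio `RAR = b/a ∈ (0, 1]`,
   - Feret major axis ratio `FMR = D_f/a`,
   - a six-class roundness classification of RAR
     (very angular 0.12–0.17, angular 0.17–0.25, sub-angular 0.25–0.35,
     sub-rounded 0.35–0.49, rounded 0.49–0.70, very rounded 0.70–1.00;
     boundaries upper-inclusive).
4. **Distributions** — global and windowed (e.g. 500 × 500 nm²) particle
   size distributions with N, mean, SE, histogram, cumulative curve and
   box-plot percentiles (`summarizePSD()`, `localPSD()`,
   `shapeBreakdown()`).
5. **Quality control** — matching the same particles across magnifications
   registered in one nm frame and tabulating per-particle ECD deviations
   against the highest-magnification reference (`matchParticles()`,
   `deviationTable()`), plus threshold-sensitivity reports
   (`thresholdSensitivity()`).

Because real micrographs of this kind are rarely redistributable, the
package ships a synthetic micrograph generator (`sceneSpec()`,
`buildScene()`, `renderScene()`) that emulates dark compact particles,
low-contrast amorphous blobs, cell-like textured backgrounds and membrane
bands — with exact analytic ground truth — so every stage of the pipeline is
testable against known answers.

## Worked example

```r
library(nanoPSD)
# a 160 x 160 nm region of a vegetative cell with 16 gold-like nanoparticles
set.seed(7)
particles <- lapply(1:16, function(i)
  diskParticle(cxNm = 25 + 37 * ((i - 1) %% 4) + runif(1, -6, 6),
               cyNm = 25 + 37 * ((i - 1) %/% 4) + runif(1, -6, 6),
               radiusNm = runif(1, 1.5, 5), contrast = -70))
scene <- buildScene(sceneSpec(160, 160, particles, noiseSd = 4, seed = 7))
img <- renderScene(scene, nmPerPx = 0.25, seed = 8)
m <- img$micrograph

cfg <- segmentationConfig(thPercent = suggestThreshold(m), minAreaPx = 50)
ps <- measureParticles(extractParticles(m, cfg))
head(particleTable(ps)[, c("id", "area_nm2", "ecd_nm", "a_nm", "b_nm",
                           "rar", "fmr", "shape_class")], 4)
#>   id area_nm2   ecd_nm      a_nm     b_nm       rar      fmr  shape_class
#> 1  1  78.1875 9.977546 10.019656 9.935613 0.9916122 1.031474 very rounded
#> 2  2  22.8125 5.389413  5.422343 5.356684 0.9878910 1.052378 very rounded
#> 3  3  30.2500 6.206085  6.228444 6.183807 0.9928332 1.046682 very rounded
#> 4  4   9.6875 3.512052  3.533678 3.490558 0.9877977 1.061217 very rounded

summarizePSD(ps, metric = "ecd_nm", binWidth = 1)
#> PSDSummary[ecd_nm]: N = 16, mean = 6.655, SE = 0.5469
#>   7 bins over [3, 10); p10/p25/p75/p90 = 3.892/5.166/8.366/9.922
```

All 16 planted particles are recovered; measured ECDs track the analytic
truth to a few percent (sub-pixel boundary coverage is the remaining error),
the fitted ellipses are round (RAR ≈ 0.99) and every particle classifies as
"very rounded", as planted disks should.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/scripts/nanopsd`:

```sh
nanopsd analyze   --config run.yml --out results/
nanopsd local-psd --config run.yml --out results/
nanopsd qc        --config run.yml --out results/
nanopsd synth     --config run.yml --out fixtures/ --seed 1
```

The YAML configuration schema is documented at the top of `R/cli.R`; every
output CSV carries an md5 hash of the configuration so runs are traceable,
and reruns with the same configuration are byte-identical.

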