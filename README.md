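# emseg

Stable encoder–decoder segmentation of mitochondria in electron microscopy
volumes — the networks *and* the workflow around them.

## What this is for

Semantic segmentation of mitochondria in volume EM (FIB-SEM / ssEM) is a
routine quantification step in neuroscience and cell biology, yet reported
scores depend as much on patch sampling, tiled-inference stitching,
test-time ensembling and morphological post-processing as on the network —
and on luck, because identically configured training runs spread. `emseg`
implements the full workflow for R users:

* **Model zoo** — lightweight 2D/3D U-Nets with residual, attention-gated
  and squeeze-and-excitation variants, declaratively specified
  (`network_spec()`, `preset_spec()`), built on a self-contained CPU engine
  (BLAS-backed im2col convolutions, exact hand-derived backpropagation) so
  training and inference are bit-reproducible for a fixed seed.
* **Sampling** — class-balanced random patch extraction driven by a
  foreground probability map, low-foreground discarding, train/validation
  splitting, seeded geometric and elastic augmentation.
* **Reconstruction** — per-patch / 50%-overlap / full-image inference,
  second-order spline-window blending, dihedral test-time augmentation
  (8 variants in 2D, 16 in 3D).
* **Post-processing** — binarisation, small-blob removal, marker-controlled
  watershed border refinement, median Z-filtering, chained with per-step
  logging.
* **Metrics** — foreground/background/overall IoU, and the ground-truth
  perturbation-tolerance analysis (how much IoU a 1-pixel annotation slip
  costs).
* **Stability harness** — run one configuration n times, report mean ± sd
  and maximum per reconstruction × post-processing cell.
* **Synthetic data** — an EM-like fixture generator (dark ellipsoidal
  organelles with bright rims on noisy background) so everything above is
  testable without downloading any dataset.

The core metric is the Jaccard index: IoU_F = TP/(TP+FP+FN) with
mitochondria as the positive class, IoU_B swaps the classes, and
IoU_O = (IoU_F + IoU_B)/2.

## A worked example

The desk-scale stability study — three seeded training runs of a two-level
2D network on synthetic fixtures, evaluated under four reconstruction /
post-processing cells on a held-out volume:

```r
library(emseg)
prof <- pipeline_profile("desk")
res  <- repeat_runs(prof, n = 3, base_seed = 1)
summ <- summarize_runs(res)
as.data.frame(summ)
```

```
                      cell n      mean          sd       max mean_overall
1                per_patch 3 0.9248547 0.003076085 0.9269795    0.9609403
2               overlap_50 3 0.9518093 0.004561811 0.9568065    0.9746656
3         overlap_50+blend 3 0.9553470 0.004552125 0.9604378    0.9765291
4 overlap_50+blend+zfilter 3 0.9311688 0.005737397 0.9377652    0.9638345
```

`mean`/`sd`/`max` are foreground IoU over the three runs; `mean_overall`
averages foreground and background IoU. The rows read like a stability
table: per-patch scoring understates the reconstructed result, 50%-overlap
tiling recovers it, spline blending adds a little by suppressing tile-border
artefacts, and the small standard deviations say this configuration is
stable across seeds. (Z-filtering slightly trims the small synthetic
organelles at their poles — on real stacks with label discontinuities it is
the step that pays off.) `format_stability_md(summ)` emits the same table as
Markdown; on one CPU the three runs take on the order of ten minutes.

Counting parameters of the published presets:

```r
count_parameters(build_network("attention2d", seed = 1))$millions  # 1.99
count_parameters(build_network("residual3d",  seed = 1))$millions  # 1.50
```

## Command line

A thin CLI wraps the package functions:

```sh
Rscript inst/cli/emseg.R count-params --model unet2d
Rscript inst/cli/emseg.R fixtures --out fx --seed 7
Rscript inst/cli/emseg.R predict --model unet2d --input x.tif --output prob.tif --tta
Rscript inst/cli/emseg.R postprocess --prob prob.tif --raw x.tif --output mask.tif
Rscript inst/cli/emseg.R evaluate --pred mask.tif --truth y.tif
Rscript inst/cli/emseg.R stability --runs 3 --seed 1 --profile desk --out out/
```

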