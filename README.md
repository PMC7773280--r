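# melr — mitochondrial event localisation in 3D time-lapse microscopy

`melr` detects, counts and **localises** mitochondrial fission, fusion and
depolarisation events between pairs of frames of a fluorescence-microscopy
z-stack time-lapse (e.g. TMRE-stained cells imaged every ~10 s with a
0.5 µm z-step). It is aimed at cell biologists quantifying mitochondrial
dynamics — fission/fusion equilibrium, stress responses, depolarisation
onset — who need per-event 3D locations rather than whole-network summary
statistics, and at image-analysis developers who need a deterministic,
scriptable reference implementation with a synthetic ground-truth
generator.

## Method in brief

For a frame pair (F1, F2), each frame is normalised (optional
Richardson–Lucy deconvolution, 1.5× bilinear in-plane upscaling, per-slice
Gaussian blur σ₂D = 1, 0.3 % contrast stretch), binarised by hysteresis
thresholding with automatically selected thresholds (low = edge of the
background valley of the smoothed intensity histogram; high = halfway
between low and the maximum), cleaned of components < 40 voxels, and
segmented into 3D 26-connected structures. Each structure gets a slightly
inflated "blurred support" (3D Gaussian, σ₃D = 0.25, anisotropy-corrected
in z). The overlap matrix

&nbsp;&nbsp;&nbsp;&nbsp;V(x, y) = |support(x in F1) ∩ support(y in F2)|

drives *back-and-forth matching*: following associations F1 → F2 → F1
collects fusion candidate pairs, the mirrored walk collects fission
candidates, and F1 structures with no association depolarise. Candidate
pairs survive three filters — surface-to-surface distance within a movement
budget (1 µm per 10 s, scaled by the actual time separation), no third
structure on the segment between them, and a *common* partner structure
with relative overlap percentage > 50 % for both members. Each surviving
pair becomes one event at the pair's midway point; depolarisations sit at
the vanished structure's centre of mass. Per frame the package also reports
the structure count and combined/average volume, with five-frame
simple-moving-average smoothing for time series.

## Worked example

Plant one fusion, one fission and one depolarisation in a synthetic
acquisition, run detection, and score it against the ground truth:

```r
library(melr)

scene <- make_event_scene(n_fusion = 1, n_fission = 1, n_depol = 1,
                          dim = c(32, 64, 64), radius = 3, gap = 8,
                          noise = "realistic", seed = 2)
sim <- render_scene(scene, seed = 3)
sim$truth
#>   frame_index           kind z_vox y_vox x_vox ids
#> 1           1         fusion     6    17    43 1;2
#> 2           1        fission    10    46    44   3
#> 3           1 depolarisation    18    14    42   4

res <- detect_events(sim$timelapse$frames[[1]], sim$timelapse$frames[[2]])
res
#> <mel_result> frame 1: 1 fusion, 1 fission, 1 depolarisation; 4 structures (mean volume 910.8 vox)

res$events[, c("event_type", "z_um", "y_um", "x_um", "labels_frame1", "labels_frame2")]
#>       event_type     z_um     y_um     x_um labels_frame1 labels_frame2
#> 1 depolarisation 9.006116 1.419572 4.218960             3
#> 2        fission 5.000000 4.533333 4.400000             2           2;3
#> 3         fusion 2.500000 1.733333 4.333333           1;4             1

evaluate_detection(res$events, sim$truth, tol_vox = 3, spacing = scene$spacing)
#>             kind tp fp fn precision recall
#> 1         fusion  1  0  0         1      1
#> 2        fission  1  0  0         1      1
#> 3 depolarisation  1  0  0         1      1
```

Reading the output: the planted fusion between structures 1 and 4 of
Frame 1 (the scene's primitives 1;2) is localised at (2.5, 1.73, 4.33) µm —
the midpoint of the closing gap; the fission is attributed to Frame-1
structure 2 splitting into Frame-2 structures 2 and 3; the vanished blob is
reported at its centre of mass. All three locations fall within 3 scene
voxels of the planted ground truth, so precision = recall = 1 per kind.

For whole time-lapses, `run_pipeline()` (or the `exec/mel` command-line
script: `mel run INPUT --out DIR [--skip K]`, `mel synth SCENE.yaml`,
`mel eval PRED.csv TRUTH.csv`) slides a frame-pair window over the
sequence and writes `events.csv`, `metrics.csv` (with SMA columns), RGB
overlay stacks and optional per-event review patches.

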