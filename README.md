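# CBCTeeth

Hierarchical teeth detection on axial cone beam CT (CBCT) slice stacks,
for dental image-analysis pipelines that need every tooth located and
FDI-numbered on every slice — the starting point for tooth segmentation,
automated charting and treatment planning.

Generic per-tooth object detection struggles on CBCT: neighbouring teeth
look alike, metal restorations streak the image, and missing teeth derail
sequence-based numbering. CBCTeeth instead implements a combined,
anatomy-driven procedure:

1. **Slice classification** into three classes (*no-tooth*, *crown*,
   *overlap*), turned into five monotone z-region labels (lower no-tooth →
   lower crown → overlap → upper crown → upper no-tooth) by an
   **anti-noise switch**: the state advances only when the next region's
   class is held for a confirmed run of `k` slices, so a spurious switch
   needs `k` consecutive classifier errors (probability `p^k`; at 95%
   per-slice accuracy, 0.25% for `k = 2` and 0.0125% for `k = 3`).
2. **Key slices**: the 10th and 10th-from-last slice of each crown region.
3. **Hierarchical detection** on each key slice: the *main area* (tight
   box around all teeth), then five anatomical *blocks* (incisors, left
   and right canines + premolars, left and right molars) via a pluggable
   detector backend (truth-backed oracle, untrained Otsu/arch heuristic,
   or a user-supplied CNN).
4. **Proportion-based division**: each block box `(L0, T0, R0, B0)` is
   split into per-tooth boxes from position ratios
   `λ = (x − x1)/(x2 − x)`, i.e. `x = (x1 + λx·x2)/(1 + λx)`; the shipped
   tooth-45 entry carries the exact published affine form
   `L = 0.83·L0 + 0.17·R0`, `T = 0.72·T0 + 0.28·B0` (and symmetrically for
   `R`, `B`). `calibrateLambdas()` fits all lambda coefficients against
   ground-truth boxes to a target mean IoU (default 0.85).
5. **Propagation**: every slice receives the nearest same-jaw key slice's
   boxes; overlap slices get both jaws' sets.

Evaluation metrics (precision, recall, F1, all-point/11-point mAP, and the
object inclusion ratio `OIR = |A ∩ D| / |A|`), IO for DICOM series, Pascal
VOC XML, JSON and PNG stacks, and a deterministic synthetic dental phantom
generator with complete ground truth are included, so the whole procedure
is testable without clinical data.

## Worked example

A 40-slice synthetic phantom, lambda calibration on four crown slices,
then the full pipeline under realistic error injection (5% classifier
label flips, ±2 px detector box jitter):

```r
library(CBCTeeth)

ph  <- generatePhantom(phantomConfig())      # 40 slices, 256 x 256, seed 1

## calibrate the lambda table against crown-slice ground truth
samples <- truthCalibrationSamples(ph$truth, c(9, 16, 25, 32))
cal <- calibrateLambdas(samples, defaultLambdaTable(enlarge = 0),
                        targetMeanIou = 0.99)

res <- runPipeline(ph$stack,
                   oracleClassifier(ph$truth, errorRate = 0.05, seed = 2),
                   oracleDetector(ph$truth, jitterPx = 2, seed = 3),
                   table = cal$table,
                   config = pipelineConfig(classifierPrep = FALSE,
                                           enlarge = 0.05))
res$labeling
#> LayerLabeling: 40 slices (lower_no_tooth=4, lower_crown=12, overlap=8,
#>   upper_crown=12, upper_no_tooth=4); switches at [5, 17, 25, 37]
res$keySlices
#>   slice   jaw
#>       7 lower
#>      14 lower
#>      27 upper
#>      34 upper
nrow(res$toothBoxes[[10]])
#> [1] 16
head(res$toothBoxes[[10]], 3)
#>   tooth         L        T        R        B
#> 1    42  96.18857 70.94147 109.5275 82.73544
#> 2    41 112.55901 62.53306 125.9001 74.32717
#> 3    31 130.66180 62.53306 144.0023 74.32717
phantomOir(ph$truth, res$toothBoxes)$mean
#> [1] 0.9808657
```

Reading: despite the injected classification and detection noise, the
anti-noise switch recovers the true region boundaries, every crown slice
carries all 16 FDI-labeled tooth boxes, and on average 98% of each tooth's
true pixel area is inside its predicted box (mean OIR 0.98). The
calibration reached mean IoU 1.00 against the phantom's ground truth
(`cal$meanIou`).

A thin command-line wrapper with `simulate`, `run` and `evaluate`
subcommands is installed at `inst/scripts/cbct-teeth.R`.

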