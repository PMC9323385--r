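---
title: "Hierarchical teeth detection on CBCT slice stacks: methods and design"
author: "CBCTeeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical teeth detection on CBCT slice stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CBCTeeth)
```

## The problem

Cone beam CT (CBCT) volumes are processed slice by slice in many dental
workflows: tooth segmentation, implant planning and automatic charting all
start from knowing, on every axial slice, where each tooth is and which FDI
number it carries. Detecting teeth one-by-one with a generic object
detector is fragile — neighbouring teeth look alike, metal restorations
throw bright streaks across the image, and a missing tooth derails
sequence-based numbering. CBCTeeth implements a combined procedure that
leans on anatomy instead:

1. **Slice classification.** Every axial slice is classified into one of
   three classes: *no-tooth*, *crown*, or *overlap* (the z-range where
   upper and lower crowns interdigitate).
2. **Anti-noise switch.** Scanning bottom to top, the class sequence is
   converted into five monotone layer labels (lower no-tooth, lower crown,
   overlap, upper crown, upper no-tooth) by a state machine that only
   advances when the next state's class is held for a confirmed run of
   slices.
3. **Key slices.** From each crown region the 10th and the 10th-from-last
   slice are selected; detection runs only on these four slices.
4. **Hierarchical detection.** On each key slice, first the *main area*
   (the tight box around all teeth) is detected, then the five anatomical
   *blocks* inside it: incisors, right/left canine + premolars, right/left
   molars. Blocks are large, distinctive objects; individual teeth are not.
5. **Proportion-based division.** Each block box is subdivided into
   per-tooth boxes from fixed position ratios (lambda coefficients),
   calibrated once against ground-truth boxes.
6. **Propagation.** Neighbouring slices share the key slices' tooth boxes;
   overlap slices receive both jaws' sets.

The payoff of the hierarchy is robustness: a missing tooth or an artefact
cannot corrupt the numbering, because every tooth's box is derived from its
block's geometry, not from per-tooth appearance.

## The anti-noise switch

With a per-slice classifier accuracy of $1-p$, a premature layer switch
requires $k$ consecutive identical wrong labels; under an independent-error
model that happens with probability $p^k$
(`consecutiveErrorProbability()`). At 95% accuracy, two consecutive errors
occur with probability 0.25% and three with 0.0125%, which motivates the
default confirmation run of `confirmRun = 3` (the changed slice plus two
or more following slices holding the same new class). The run length is
configurable; `confirmRun = 1` degenerates to immediate switching.

Two aspects of the switch are deliberate design choices rather than fixed
by the procedure's published description:

* **Switch index.** We advance the state at the *first* slice of the
  confirming run (not after the run completes), so region boundaries align
  with where the class actually changed.
* **Noise semantics.** Only the *next* state's expected class can trigger
  a switch; any other label — including a long run of a class that is two
  states ahead — is treated as noise. This keeps the layer sequence
  monotone by construction.

For stacks stored top-to-bottom, `scanDirection = "top_to_bottom"` flips
the sequence before labeling and maps all outputs back to input order.

## Key-slice selection and propagation

The 10th / 10th-from-last rule assumes crown regions of at least ten
slices. For shorter regions the offsets are clamped into the region (with
a warning) and duplicate picks collapse, so the procedure degrades to one
key slice per crown region rather than failing.

Propagation sends every slice the box set of the *nearest key slice of its
own jaw* (ties break toward the smaller slice index); overlap slices
receive the union of the nearest lower-jaw and nearest upper-jaw sets.
The published description shows only that neighbouring slices share
boxes; the nearest-key rule is our concrete choice, and it is exact for
anatomies whose in-plane tooth positions drift slowly along z.

## Proportion-based division

A point inside a box is addressed by its position ratio
$\lambda = (x - x_1)/(x_2 - x)$, i.e.

$$x = \frac{x_1 + \lambda_x x_2}{1 + \lambda_x}, \qquad
  y = \frac{y_1 + \lambda_y y_2}{1 + \lambda_y}.$$

Each tooth carries a $(\lambda_x, \lambda_y)$ pair for its box's left-top
corner and one for its right-bottom corner, relative to its block's
detected box `(L0, T0, R0, B0)`. We admit the closed domain
$\lambda \in [0, \infty]$: the limits place the point exactly at $x_1$
and $x_2$, and the edge teeth of a block need them (the first tooth's left
edge is the block's left edge). This is the one place our invariants are
slightly wider than the narrowest reading of a "positive ratio".

The shipped tooth-45 entry stores the published affine form directly:

```{r tooth45}
toothBoxFromBlock(Box(0, 0, 1, 1), tooth45Proportion())
```

Two paths coexist on purpose. The raw lambda evaluation at the published
ratios $(\lambda_x, \lambda_y) = (1/6, 2/9)$ and $(5/6, 4/9)$ gives corners
$\approx (0.143, 0.182, 0.857, 0.308)$, while the published affine
coefficients give $(0.17, 0.28, 0.83, 0.72)$ — the affine set folds in a
small enlargement and vertical re-centering that the ratios alone do not
express. We therefore keep the affine matrix as an exact override on the
tooth-45 entry and never claim the two paths coincide.

### Default table and calibration

The pre-calibration table divides each block uniformly along its
left-right extent (the $k$-th of $n$ teeth spans width fractions
$[(k-1)/n, k/n]$ in image order) and uses the tooth-45 vertical lambdas,
mirrored for the upper jaw. It is an *initialization*:
`calibrateLambdas()` refines every entry against ground-truth tooth boxes
by per-tooth coordinate descent on the four lambda values with a shrinking
step, maximizing mean IoU, stopping at a target mean IoU (default 0.85,
the published calibration criterion) or at step size $10^{-4}$.

Two numerical details matter. First, IoU is flat wherever the generated
and true boxes do not overlap, so the search would stall on a bad
initialization; we therefore rank candidates lexicographically — higher
mean IoU first, smaller mean corner distance as tie-breaker — which guides
the search into contact before IoU takes over. Second, candidates that
would invert a corner ordering (left-top beyond right-bottom) are scored
as worst-possible instead of erroring.

After the proportional corners, boxes are enlarged symmetrically by an
`enlarge` fraction per side (default 0.05) to absorb scan rotation and
malocclusion, then clamped to the image. Calibration is run with
`enlarge = 0` and the margin applied at prediction time, so the margin is
a true safety buffer rather than being fitted away.

Ordering within a block follows the radiological display convention
(patient right on the image's left), so the upper incisors read
12, 11, 21, 22 from image-left to image-right; `chirality = "anatomical"`
mirrors this. The display convention of any given export is metadata the
pipeline cannot infer from pixels, hence a configuration flag.

## Detection backends

Detectors are a contract: `function(image, target, index, roi)` returning
labeled scored boxes. Three backends cover the intended uses:

* `oracleDetector()` replays ground truth with configurable uniform box
  jitter and suppressed labels — the deterministic backend for tests.
* `heuristicDetector()` needs no training: two-level Otsu thresholding
  isolates the bright teeth (the second cut is only applied when the
  foreground is genuinely bimodal, i.e. bone band plus teeth), connected
  components become tooth candidates, a parabola is fitted to their
  centres, and components are grouped into the five blocks by arc-length
  position along the fitted arch (3+3+4+3+3 tooth slots). It is intended
  for phantom-like images with bright teeth on a dark background.
* A trained single-stage CNN detector can be plugged in through the same
  contract; its training is outside this package's scope.

A score threshold of 0.5 (configurable) separates positive detections; at
most one box per block label is kept (highest score), and undetected
blocks are *reported missing* rather than extrapolated from symmetry —
downstream division simply skips them, matching the conservative clinical
behaviour of flagging rather than guessing.

`gridCells()` records the single-stage detector grid geometry (a 416-px
input at 32-px stride gives 13×13 cells); it is a geometry check for
anyone wiring in a trained backend.

## Evaluation metrics

* **Precision / recall / F1** from greedy score-ordered matching
  (IoU ≥ threshold, same label, each truth box consumed at most once).
  All 0/0 cases return 0.
* **AP / mAP**: all-point interpolated area under the precision-recall
  curve per label (11-point interpolation available as an option), mean
  over labels with at least one truth box. The matching protocol for mAP
  is not pinned down by the published description, so both interpolations
  are exposed as configuration.
* **OIR (object inclusion ratio)**: the fraction of an object's true pixel
  area covered by its detected box, $|A \cap D| / |A|$. A pixel belongs to
  the box iff its centre does (`L <= j + 0.5 < R`, 0-based), consistent
  with the half-open area convention `area = (R - L)(B - T)` used
  throughout; teeth flagged missing are skipped in per-image means.

## The synthetic phantom

`generatePhantom()` draws each jaw's dental arch as a parabola in the
axial plane, places the 16 teeth of the jaw at equal arc-length positions
along it, and renders them as bright axis-aligned ellipses (0.9 of the
dynamic range) over a dimmer bone band (0.4) on a dark background (0.1),
with additive Gaussian noise, on an 8-bit 0–255 scale. Along z the stack
has the five-region structure; the overlap region draws both jaws. The
default configuration is a 40-slice, 256×256 stack with region lengths
4/12/8/12/4 — crown regions are the thickest z-regions in practice, and
the key-slice rule presumes at least ten crown slices per jaw. Missing
teeth, metal-artefact streaks radiating from a named tooth, and the noise
level are all configurable; everything is a pure function of the
configuration (seed included).

The phantom's ground truth satisfies the containment chain *mask ⊆ tooth
box ⊆ block box ⊆ main area* on every slice, which is what makes every
pipeline stage testable without clinical data.

What the phantom deliberately does **not** emulate: physically realistic
CT reconstruction (beam hardening, partial-volume effects), root-level
anatomy, tilted or rotated dentitions, adherent tooth edges, and
per-slice variation of tooth cross-sections. Tests passing on the phantom
therefore demonstrate the correctness of the *procedure* — labeling,
geometry, calibration, propagation, metrics — not clinical-grade detector
accuracy, which depends on a trained backend and real data.

## Problem sizes used in the shipped tests

The test suite runs the full pipeline on 40-slice 256×256 phantoms,
calibrates lambda tables from a handful of crown slices (mirroring the
one-slice-per-patient calibration protocol), checks the anti-noise switch
against a thousand random sub-run corruptions, and verifies average
precision against a brute-force PR-curve oracle on all instances with up
to eight predictions. These sizes exercise every code path while keeping
the suite quick to run.

## Known limitations

* Proportion-based division assumes the patient's head was positioned at
  the standard orientation; severe malocclusion or a tilted scan breaks
  the fixed-ratio geometry (an acknowledged failure mode of the method).
* More than about three contiguous missing teeth undermine block
  detection itself; the package reports missing blocks but does not
  attempt symmetry-based recovery.
* The DICOM reader is intentionally narrow: single-frame uncompressed
  little-endian grayscale series, one file per slice. Anything else is
  rejected with an informative error.
* The heuristic detector backend presumes bright teeth on a dark
  background; it is a reference implementation for phantom-scale data,
  not a clinical detector.
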