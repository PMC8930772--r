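---
title: "Quantifying lipid-droplet phenotypes from yeast micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid-droplet phenotypes from yeast micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldscope)
```

## The problem

Seipin-deficient yeast cells show a characteristic lipid-droplet (LD)
phenotype: instead of many small, uniform droplets they carry few droplets,
often clustered, including "supersized" droplets with radii above roughly
400 nm. Scoring this phenotype across strains means (i) finding each cell in
a crowded brightfield field, (ii) counting BODIPY-stained droplets per cell
in the fluorescence channel, (iii) flagging cells that contain a supersized
droplet, and (iv) comparing strains across independent experiments.
`ldscope` implements that measurement chain end to end, together with a
synthetic-scene generator that provides exact ground truth, so every stage
of the chain can be validated quantitatively without any real image data.

## Cell segmentation by spatial embeddings

A convolutional network makes three per-pixel predictions on the
brightfield image: a **seed map** $s_i \in [0,1]$, a **bandwidth**
$\sigma_i > 0$ and a 2-D **offset** $o_i$. Adding the pixel's own
coordinate $x_i$ (normalised by the larger image dimension, so the
embedding space is resolution independent) gives the spatial embedding
$e_i = x_i + o_i$. Training drives the embeddings to be constant within a
cell and distinct between cells, but only indirectly: for every
ground-truth cell $k$ the mean embedding $\bar e_k$ and mean bandwidth
$\bar\sigma_k$ are computed over the cell's pixels and a soft mask

$$\phi_k(i) = \exp\!\left(-\frac{\lVert e_i - \bar e_k\rVert^2}
  {2\bar\sigma_k^2}\right)$$

is grown over the image. The soft masks are matched to the binary
ground-truth cell masks with the Dice loss
$1 - 2\sum\phi t / (\sum\phi + \sum t + \varepsilon)$, which is robust to
the large foreground/background imbalance of crowded fields. The network is
a U-Net variant with a residual block at every scale of both branches and
batch normalisation after every convolution; it is optimised with Adam at a
learning rate of $10^{-4}$ on square crops augmented by random flips and
rotations.

At inference, instances are recovered by iterative seed clustering: the
unassigned pixel with the highest seed score becomes a seed, and every
unassigned pixel whose embedding lies within the seed's Gaussian kernel at
membership above 0.5 joins its instance; this repeats until no pixel with
seed score above 0.5 remains unassigned. The loop always terminates because
a seed's own kernel value is exactly 1. Predicted instances smaller than
300 pixels, and instances touching the image border, are removed; the
convex hulls of the survivors become the cell ROIs used downstream,
mirroring an ImageJ ROI workflow.

Design points the published description leaves open, and the choices made
here:

* **Seed-map loss.** The seed map is regressed (squared error) to the
  gradient-detached soft-mask value on cell pixels and to 0 on background.
  At convergence the seed score therefore predicts how well a pixel would
  act as a cluster seed. The detachment matters: the target moves with the
  embeddings, but only the seed head should chase it.
* **Bandwidth parameterisation.** The raw bandwidth head passes through a
  softplus and a fixed scale of 0.1, keeping $\sigma$ of the order of a
  cell radius in normalised coordinates at initialisation; the "average
  predicted bandwidth" of a cell is the arithmetic mean of $\sigma_i$ over
  its pixels.
* **"Sufficiently close".** Membership of pixel $i$ in the cluster seeded
  at $s$ is $\exp(-\lVert e_i - e_s\rVert^2 / 2\sigma_s^2) > 0.5$ with
  $\sigma_s$ the *seed pixel's own* predicted bandwidth (a running cluster
  average would also be defensible; the seed-pixel form is simpler and is
  what the iterative algorithm needs to guarantee self-assignment).
* **Area filter boundary.** "Falls below a threshold of 300 pixels" is read
  strictly: a 299-pixel instance is removed, a 300-pixel instance kept.
* **Tie-breaking.** Equal maximal seed scores resolve to the smallest
  (row, col), making inference fully deterministic.
* **Normalisation.** Batch statistics are computed per image both in
  training and at prediction time, so inference is deterministic and needs
  no stored running averages (with batch-size-one crops this is the natural
  reading of per-convolution batch normalisation).

The network itself is implemented in the package (im2col convolutions with
hand-derived backpropagation, verified against finite differences in the
test-suite) rather than through an external deep-learning runtime; the
training defaults (`trainConfig()`) are desk scale -- 128-px crops, batch
4, 500 steps -- while the published full-scale setting (1,024-px crops)
remains a configuration choice.

## Droplet counting: a descending threshold sweep with a maximum rule

LD sizes and brightness are heterogeneous, and droplets cluster; no single
intensity threshold counts them well. The counting rule therefore sweeps
lower thresholds from 20,000 down to 2,000 counts in steps of 2,000 (upper
threshold maximal, 16-bit range), counts thresholded particles
(8-connected components, the ImageJ "Analyze Particles" convention;
4-connectivity is a parameter) inside each cell ROI at every threshold, and
takes the **maximum count over the sweep** as the cell's droplet number. At
high thresholds only the brightest droplets appear; at low thresholds dim
droplets appear but clustered ones merge -- the maximum rule trades both
failure modes against each other. The per-threshold mask at a higher
threshold is always a subset of the mask at a lower one (tested as an
invariant), though the *counts* need not be monotone because of merging.

**Supersized scoring** is a separate pass at the 10,000 lower threshold: a
cell is flagged when it contains a particle of area strictly greater than
0.5 µm². With the default calibration of 0.065 µm/px that corresponds to a
radius of about 6.2 px. The parenthetical point-spread-function remark in
the original description is treated as commentary: the area is the plain
thresholded component area, nothing is deconvolved. A particle contributes
to every cell ROI it intersects (counting is performed on the
region-restricted mask), matching per-ROI ImageJ measurement semantics.

## Strain statistics

Each field yields a mean droplets-per-cell and a percentage of cells with
supersized droplets; the (typically three) fields of a strain within one
experiment average into a single data point. Strains are compared with a
one-way ANOVA in which the experiment is a block ("strains linked within
each experiment" -- a randomized complete block layout):
$F = \mathrm{MS}_{\text{strain}} / \mathrm{MS}_{\text{res}}$ on
$(s-1, (s-1)(b-1))$ degrees of freedom. Preselected strain pairs are then
tested with $t = (\bar y_i - \bar y_j)/\sqrt{2\,\mathrm{MS}_{\text{res}}/b}$
on the residual degrees of freedom and adjusted by the **step-down Šidák**
(Holm–Šidák) procedure: sort the $m$ raw p values ascending, set
$p^{\text{adj}}_{(k)} = 1-(1-p_{(k)})^{m-k+1}$, enforce monotonicity by
running maximum, cap at 1. Whether the original Prism workflow used Šidák
or Holm–Bonferroni stepping cannot be determined from the text; Šidák
stepping is the default and Holm–Bonferroni is available via
`method = "holm"`. Pairs must be given explicitly -- an all-pairs default
would silently change $m$ and with it every adjusted p value. All tests are
two-sided. Stars follow the convention \*** p < 0.001, \** p < 0.01,
\* p < 0.05, NS otherwise.

## The synthetic-scene generator

The generator emulates the data this pipeline consumes: projected 2-D
fields of non-overlapping elliptical cells (ground truth drawn as ellipse
masks), a brightfield-like appearance (dark interior, bright rim, Gaussian
read noise -- brightfield pixel appearance has no canonical model; only
learnability matters), and a fluorescence channel in which each cell's
droplets are drawn from a strain archetype: Poisson droplet count,
log-normal radius in µm, uniform peak intensity within a 16-bit count
range, and a clustering probability that places droplets tangent to an
existing one. Droplets are rendered as hard disks softened by a truncated
3×3 Gaussian blur ($\sigma$ = 0.6 px), so droplet signal extends exactly
one pixel beyond each disk; the background (including its read noise) is
capped strictly below 1,900 counts so that background alone can never
register as a particle at the lowest sweep threshold of 2,000. Built-in
archetypes encode the two phenotype poles: `wtArchetype()` (8 droplets per
cell, median radius 150 nm, weak clustering) and `nullArchetype()` (2
droplets per cell, median radius 500 nm -- the supersized regime -- strong
clustering). Their droplet-count means and the supersized boundary mirror
the qualitative published contrast (many small uniform droplets vs. few,
clustered, supersized ones); the numeric values are the generator's own
calibration, chosen once as typical of such images.

Deliberate idealisation, and what it means for the tests: there is no
point-spread-function physics beyond the small blur, no 3-D stacks, no
spectral model of the stain, no debris or dead cells, and cells are perfect
ellipses. Passing the recovery tests therefore shows the *measurement
chain* is correct (segmentation, counting, scoring, statistics), not that
the network would segment any real micrograph; conversely every
quantitative rule (thresholds, area cut, filters, statistics) is exercised
exactly as it would run on real data. Scenes are deterministic given a
seed; a master seed fans out to per-scene and per-stage seeds through a
fixed integer walk (`deriveSeed()`), so any stage can be re-run in
isolation.

Other conventions: pixel coordinates are 1-based (row, col) matrices in R
(exports to ImageJ ROI records use that format's 0-based x/y convention);
label 0 is background; the default calibration 0.065 µm/px corresponds to
a 100× objective on an sCMOS camera -- the pixel size is a required input
because the 0.5 µm² rule is physical, not pixel-based; droplets that
cannot be placed inside their cell within the retry budget are omitted so
the droplet table always describes exactly what was rendered; the
intensity sweep bounds (2,000–20,000 of a 0–65,535 range) imply 16-bit
counts, which the generator adopts throughout.

## Numerical choices and degenerate inputs

* Dice loss uses $\varepsilon = 10^{-6}$; an empty label image gives an
  instance term of exactly 0 and a seed term that drives the seed map to 0.
* Clustering with every seed score at or below 0.5 returns an empty
  instance list; `postprocess()` of an empty list is a valid empty result.
* Convex hulls are rasterised by half-plane tests with a $10^{-9}$
  tolerance; for digitally convex pixel sets (rasterised ellipses) the
  hull region reproduces the pixel set exactly, which the tests assert.
* Training aborts with a diagnostic on non-finite loss rather than
  continuing from a poisoned state.
* `linkedAnova()` refuses incomplete designs and zero residual degrees of
  freedom instead of silently dropping cells.

## Problem sizes used by the test-suite

The suite validates each stage at the smallest size that still exercises
it honestly: 128-px fields of ~8 cells for clustering and recovery tests,
a 500-step / 128-px-crop training run (the desk-scale defaults) for the
end-to-end learning check, 200 Monte-Carlo experiment sets for the type-I
calibration of the full simulate-measure-test chain, and reduced per-field
cell counts for the phenotype-direction check across seeds. The full-scale
settings (1,024-px fields, ~200 cells, three fields per strain and
experiment) remain the configuration defaults of `generateScene()` and are
what `runConfig()` describes.

## Known limitations

* The maximum-rule count compresses the dynamic range (dim droplets raise
  counts, clustered droplets merge); it is a relative, not absolute, LD
  number -- a property inherited from the original procedure.
* Hull ROIs of adjacent cells can overlap slightly; a particle spanning two
  hulls contributes its in-region component to each.
* The trained network is validated on synthetic fields only; applying it to
  real micrographs requires retraining on annotated real data.
* Training is deterministic on one platform but bitwise reproducibility
  across BLAS implementations is not guaranteed; its acceptance is
  threshold-based (IoU), not bitwise.
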