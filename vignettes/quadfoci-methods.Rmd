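---
title: "Quantifying G-quadruplex foci, colocalization, splicing and binding with quadfoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying G-quadruplex foci, colocalization, splicing and binding with quadfoci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadfoci)
```

## The problem

Cells carrying the pathogenic GGGGCC repeat expansion in *C9ORF72*
accumulate RNA G-quadruplex (G-Q) structures that can be visualized with
the structure-specific antibody BG4, and these structures sequester the
splicing factor hnRNP H. quadfoci implements the quantitative pipeline
around that biology: counting BG4 foci in multichannel
immunofluorescence, counting discrete hnRNP H/BG4 colocalization events
by compartment, comparing patient and control cell lines, quantifying
percent exon inclusion (PSI) of hnRNP H target exons from RT-PCR
densitometry, quantifying insoluble hnRNP H from sarkosyl fractionation
westerns, and estimating the hnRNP H/repeat-RNA dissociation constant
from gel shifts. Patient specimens are not distributable, so the package
ships a synthetic generator that plants all of these signals with known
ground truth.

## The foci-count estimator

The imaging quantification works on three normalized intensity planes
(red = BG4, green = hnRNP H, blue = DAPI) with values in $[0,1]$. The
algorithm, per image:

1. Threshold the red plane at an absolute intensity $t$ (default $t =
   0.1$; the comparison is $\ge$, so boundary pixels are kept and results
   are bit-reproducible). Integer images are normalized by the full-scale
   value of their bit depth, never the observed maximum, because a single
   absolute threshold across images presumes one fixed scale.
2. Remove every connected red object that does not overlap blue staining.
   Gating is *object-level*: one overlapping pixel retains the whole
   object, no overlap removes it entirely. This mirrors discarding whole
   stains outside DAPI-positive regions and preserves total-area
   semantics; pixelwise clipping would not.
3. Measure each remaining connected component (8-connectivity by
   default) and sum the areas into `area_total_px` (the total stained
   area).
4. Estimate the single-object area as a trimmed mean: sort the object
   areas, drop $\lfloor 0.1 n \rfloor$ from each tail, and average the
   rest. With fewer than three objects the plain mean is used; the
   "top and bottom 10%" rule has no stated rounding convention, so the
   floor rule is fixed here for reproducibility.
5. Report the *trimmed-mean approximated foci count*

   $$\widehat{N} = \frac{\text{AreaTotal}}{\overline{A}_{\text{trimmed}}}.$$

   $\widehat{N}$ is real-valued, equals the exact object count whenever
   all objects have equal area, and degrades gracefully when dense foci
   merge: merged staining still contributes its full area. No watershed
   splitting or spot deconvolution is attempted -- the estimator is the
   deliberate substitute.

Cells are enumerated as connected DAPI objects of at least
`min_nucleus_area_um2` (default 20 um^2) unless an external `cells.csv`
supplies counts; per-cell metrics are undefined (and flagged) when no
cells are present.

Two points the original description leaves open are exposed as
configuration rather than decided silently: whether the DAPI gate used
the same 0.1 threshold (`blue_threshold`, default 0.1), and whether
per-cell values were computed per image or pooled per line
(`experiment_records()` pools each line's images: total foci over total
cells).

## Colocalization events and compartments

Colocalization is counted as discrete events, not intensity correlation:
events are connected components of the intersection of the thresholded
red and green masks, with a minimum area (`min_coloc_area_um2`, default
0.25 um^2) to suppress single-pixel coincidences, since no
overlap-fraction rule is stated. Each event is classified by its
centroid -- robust to one-pixel boundary crossings -- as *nuclear*
(inside a DAPI object of at least the nucleus minimum area),
*cytoplasmic* (DAPI at or above `cytoplasm_threshold`, default 0.02,
outside nuclei; faint cytoplasmic DAPI indicates nucleic acids), or
*unassigned*.

Two incidence metrics are reported per line because both conventions
appear in this literature: events divided by total cells, and the
fraction of cells containing at least one event. With sparse events
(about 1--8 per 100 cells) they nearly coincide; when the events table
carries no per-cell assignment, the cells-containing metric assumes
distinct cells per event, capped at each image's cell count.

Large foci in tissue sections use a 0.5 um minimum dimension, the
practical lower limit for discernible puncta; "any dimension" is
implemented as the longer bounding-box side, with a Feret-diameter
alternative (`feret = TRUE`).

## Normalization and group comparison

Staining intensity varies between experiments, so each experiment is
normalized separately: every line's per-cell value is divided by the
*average control cell* of that experiment, computed by pooling all
control cells (a cell-count-weighted mean over control lines) rather
than averaging line means -- the phrase refers to cells, not lines.
Normalized control values then average to 1 by construction and all
values are fold changes relative to control. All case replicates are
pooled into one group and compared to all control replicates with an
unpaired t-test; the Student pooled-variance form is the default (the
analysis environments conventional in this field use it), with Welch
available by flag. Fold change is the ratio of group means of the
normalized values.

For RNAse experiments, the percent reduction in foci per cell is
computed per group, and the untreated case:control ratio implied by
treated counts $T$ and reductions $r$ is $[T_{case}/(1-r_{case})] /
[T_{ctrl}/(1-r_{ctrl})]$.

## Splicing quantification

Percent exon inclusion from a band pair is $100 \cdot I/(I+E)$, invariant
to lane loading. Per-patient means are taken over 3--4 replicate lanes;
artifact lanes are dropped via an `exclude` column; exons detectable as
only one isoform are excluded from testing. An optional correction
divides each band by its product's labelled-nucleotide count (signal
scales with labelled-C content) but is off by default since raw
densitometry proportions are the convention.

The severity regression asks whether patients are consistently ordered:
each case patient's mean PSI over the significant gene set defines a
severity axis $x$ (low inclusion = strong disruption), and each gene's
PSI is regressed on $x$ by ordinary least squares. Genes tracking the
overall disruption get positive slopes; oppositely regulated genes
(WDR45, HNRPDL, RPL10, OS9 in the motivating panel) get negative slopes.
On complete data the equal-weight average of slopes is exactly 1, a
useful internal check. Disease duration is related to severity by
Spearman rank correlation (mid-ranks on ties).

## Fractionation and binding

Percent insoluble protein is $100 \cdot \text{insol}/(\text{sol} +
\text{sark-sol} + \text{sark-insol})$, invariant to loading. Co-IP
signals subtract matched beads-alone backgrounds, flooring negatives at
zero (they are noise). Gel-shift binding fits the one-site model $f =
B_{max} P / (K_d + P)$ by nonlinear least squares; the probe (0.3 nM) is
far below $K_d$, so free protein is approximated by total protein.
$B_{max}$ is left free rather than fixed at 1 because gel shifts rarely
saturate completely; no Hill coefficient is fitted (no cooperativity is
modelled). Initialization takes $K_{d,0}$ as the concentration nearest
half the maximal observed fraction bound and $B_{max,0}$ as that
maximum, with a fixed grid of rescaled restarts before a fit is flagged
unconverged; standard errors come from the Jacobian via `vcov`.

## The synthetic world

`generate_image()` renders jittered-grid cells: an elliptical nucleus
(intensity 0.5--0.9), a dim DAPI-positive cytoplasm annulus (2.5 um
wide, intensity 0.03--0.06 -- above the 0.02 cytoplasm threshold, below
the 0.1 nucleus threshold), Poisson-distributed red foci with lognormal
radii placed inside nuclei with a 1.5 px clearance so planted disks can
never touch under 8-connectivity, optional green and colocalized foci,
stray off-cell red foci that the blue gate must remove, and Gaussian
background noise (mean 0.01, sd 0.015) clipped to $[0,1]$ and quantized
to the 16-bit grid so a TIFF write/load round trip is bit-identical.
Focus intensities (0.3--0.9) sit strictly above the 0.1 threshold so
detection failures would reflect the algorithm, not the rendering; the
`dim` preset deliberately straddles the threshold.

Chosen scales, and why: the motivating RNAse experiment implies over a
hundred foci per cell, which cannot be rendered as resolvable disks at a
realistic 0.25 um pixel size. The presets therefore plant scaled-down
densities (5 foci per control cell, mean radius 0.3 um, nuclei 4.2--5.0
um) while planting the reported *ratios* exactly -- and ratios are what
the pipeline recovers. Between-line biological variability is a 5%
lognormal multiplier on the per-line rate in the multi-line presets
(with a single line per group a line multiplier would alter the planted
ratio itself, so the astrocyte and RNAse presets use none); 5% keeps
the pooled fold's sampling error well inside the 10% band the presets
are calibrated to. The `fibroblast` preset
rotates 7 case and 5 control lines through 4 experiments to reproduce
the 16-versus-12 replicate structure with planted foci ratio 1.8 and
area ratio 2.8 (case foci are both more numerous and larger:
radius scale $\sqrt{2.8/1.8}$); `astrocyte` plants 2.0/2.3 over 3
experiments; `rnase` plants an untreated ratio of 2.7 with removable
fractions 0.27/0.76; `mn` plants large (>0.5 um) green foci at 46/36
vs 3/19 per cell. Band tables scale $(\psi, 100-\psi)$ by a random lane
factor with 3% multiplicative noise; fraction tables plant group means
30.0/56.1 with 6-point between-sample and 2-point replicate sds;
binding presets 4R ($K_d$ 75.5 nM, two-fold series to 640 nM) and
4R-7dG (13.5 nM, to 160 nM) add 3% noise on fraction bound.

What a green recovery test establishes, and what it does not: the
synthetic scenes exercise thresholding, gating, labeling, the
trimmed-mean estimator, normalization and the group statistics under
known truth, but they contain no point-spread blur, no chromatic
aberration, no autofluorescence gradients, no z-structure (projections
are assumed done upstream) and no segmentation errors from touching
nuclei. Recovery on these scenes validates the computation, not the
microscopy.

## Numerical choices and edge cases

- Threshold comparisons are $\ge$; coordinates are 0-based (row,
  column); areas are exact pixel counts, with physical areas
  `area_px * pixel_size_um^2`.
- Empty masks yield empty object tables; zero objects yield a foci count
  of exactly 0; `n < 3` areas use the plain mean.
- Identical degenerate groups (zero variance) in a t-test return p = 1;
  separated constant groups return p = 0 rather than erroring.
- Connected-component labeling is two-pass union-find in C++ (no labeling
  primitive exists in the available R stack); labels are renumbered in
  raster order, so results are deterministic.
- TIFF support is a purpose-built codec for the subset used here:
  uncompressed 8/16-bit grayscale pages or one interleaved RGB page,
  both byte orders on read, little-endian multi-page on write, pixel
  size in the resolution tags (unit = cm). Compressed or planar files
  are rejected loudly.
- Generators use a private RNG state (the caller's `.Random.seed` is
  saved and restored) and derive per-image seeds from the master seed,
  so datasets are reproducible image-by-image.

## Known limitations

Merged foci are counted by area ratio rather than split; compartment
classification trusts the DAPI channel and a single cytoplasm threshold;
the cells-containing incidence is approximate without per-cell event
assignment; and the t-test treats line-level replicate values as
exchangeable across experiments after normalization (no mixed-effects
modelling of the experiment batch -- per-experiment normalization *is*
the batch handling here).
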