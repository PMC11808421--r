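---
title: "Pixel-selection criteria for the Pearson colocalisation coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-selection criteria for the Pearson colocalisation coefficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coloccrit)
```

## The quantity and why it is three quantities

Colocalisation analysis asks to what extent two fluorescently labelled
biomolecules occupy the same diffraction-limited volume. The Pearson
correlation coefficient (PCC) of the paired pixel intensities,

$$
\mathrm{PCC} \;=\; \frac{\sum_i (R_i - \bar R)(G_i - \bar G)}
{\sqrt{\sum_i (R_i - \bar R)^2}\,\sqrt{\sum_i (G_i - \bar G)^2}},
$$

ranges from $-1$ (mutual exclusion) through $0$ (no relation) to $+1$
(perfect colocalisation). The definition is incomplete, however, until the
index set $i$ is fixed, and software in circulation uses three different
conventions:

* **PCC~ALL~** — every pixel in the image, background included;
* **PCC~OR~** — pixels strictly above the green threshold *and/or* strictly
  above the red threshold;
* **PCC~AND~** — pixels strictly above *both* thresholds.

The sums and the channel means $\bar R$, $\bar G$ are always taken over the
selected subset only. That makes the three coefficients genuinely different
estimators. PCC~ALL~ is confounded by the foreground-to-background ratio —
object size, object density, even canvas size move it — while PCC~OR~ responds
to both signal co-occurrence and intensity proportionality, and PCC~AND~,
whose pixels co-occur by construction, isolates intensity proportionality and
is therefore the most sensitive detector of weak colocalisation.

`pcc()` computes all three; `select_pixels()` exposes the masks. Thresholds
use strict inequalities (a pixel exactly at a threshold is excluded), and the
ALL criterion ignores the thresholds entirely — treating "zero thresholds" as
definitional shorthand, since a strict inequality at zero would exclude
zero-valued pixels and contradict "all pixels".

## The benchmark image pairs

The behaviour of the three coefficients is characterised on fully synthetic
pairs whose statistics are known in closed form.

**Overlapping squares** (`make_square_pair()`): one filled square of side
$s$ per channel, intensity 0.8, on a zero 1000 × 1000 canvas, positioned so
25% of each square's area is shared. We use a diagonal offset of $s/2$; any
layout with the same areas gives identical coefficients, so the geometry is
presentation-only. The pooled intensity distribution has four mass points —
$(I,I)$ with weight $s^2/4$, $(I,0)$ and $(0,I)$ with $3s^2/4$ each, and
$(0,0)$ on the remaining canvas — so PCC~ALL~ has an analytic value which the
test suite asserts to $10^{-10}$ against the implementation. The family
`object_size_sweep()` reproduces the size dependence: PCC~ALL~ falls from
0.25 (side 2) through 0.25/0.23/0.16 (sides 80/160/320) to $-0.33$ (side
660), while PCC~OR~ stays at $-0.75$ (three-mass-point closed form) and
PCC~AND~ at $1.00$ for every size.

Flat-top squares make the AND selection a constant set in both channels, a
0/0 correlation. The package reports this case as 1.0 with
`degenerate = TRUE` when the two constant intensities are positive (they are
positively proportional vectors); a single selected pixel is treated by the
same convention. If only one channel is constant over the selection, or a
constant equals zero, the value is undefined and a classed error is raised
instead — the flag keeps the convention visible rather than silent.

**Gaussian spots** (`make_spot_pair()`): five isotropic 2D Gaussian spots of
identical width and peak per channel on a dark 1000 × 1000 canvas, exactly
one spot pair at coincident centres. Spot width and positions are free
parameters of this kind of mock image; we fix $\sigma = 15$ px and amplitude
0.8 with hard truncation at $4\sigma$ — compact, well-resolved spots of the
kind a confocal image of discrete puncta would show — and place spots on a
deterministic 4 × 4 grid (spacing 250 px $\gg 6\sigma$) so the default image
is bit-reproducible; a seeded random placement mode exists. Because every
non-coincident spot is separated from all others by more than the truncation
radius, the AND selection under per-channel Otsu thresholds contains only the
coincident spot, where the two channels are identical pixel-by-pixel:
PCC~AND~ is exactly 1. The layout-*dependent* quantities (PCC~ALL~, PCC~OR~,
selected fractions) are asserted only qualitatively — PCC~ALL~ small
(≈ 0.19 under these defaults), PCC~OR~ negative, selected fractions nested
AND < OR < ALL — since they move with $\sigma$ and the spot count.

## Thresholding

`otsu_threshold()` maximises the between-class variance over all candidate
splits of a 256-bin equal-width histogram spanning the data range. The
threshold returned is a bin *edge*; ties at edges fall to the lower bin, and
class means are computed from the actual pixel values in each bin rather than
bin midpoints, so the result is the exact maximiser over edge splits (the
test suite checks it against an exhaustive per-edge search, and against
EBImage's implementation to within one bin width). Constant images raise a
no-contrast error. With range-proportional binning the threshold is
equivariant under positive rescaling and invariant under pixel shuffling.

`costes_thresholds()` implements the iterative PCC-based search: thresholds
start high and are lowered stepwise until the correlation of the pixels *below*
them is null or negative; the surviving above-threshold pixels are the ones a
thresholded PCC should use. The procedure needs two conventions the verbal
description leaves open, and we adopt the classic construction: the green
threshold is slaved to the red one through the least-squares regression line
of green on red over all pixels, and the step is one 256-bin histogram bin of
the red channel. "Below" is taken as at-or-below in both channels — the exact
complement of the strict OR selection, so above/below partitions the image.
Steps whose below-set has fewer than two pixels or zero variance cannot
satisfy the stopping rule and are skipped; if the scan reaches the bottom of
the range (as it must when the channels are globally correlated, e.g. green ≡
red), the thresholds are parked at the grid minimum with `converged = FALSE`
and a warning rather than an error.

## Z-stacks

A z-stack is treated as a single pooled voxel population. `pcc_vs_zrange()`
grows a slice window symmetrically from the stack midpoint (bias to the lower
index for even sizes, clipped at the stack edges, final row always the full
stack) and recomputes the three coefficients per window with thresholds held
fixed, so the curve isolates pixel-selection effects. On a synthetic stack of
20 signal slices flanked by empty ones, PCC~OR~ and PCC~AND~ are invariant to
the window to better than $10^{-12}$ — their selections exclude zero voxels
entirely — while PCC~ALL~ climbs toward a plateau as background voxels
accumulate, matching the four-mass-point closed form with the background
weight scaled by the window size at every row ($10^{-10}$). The practical
reading: with PCC~ALL~, the choice of z-range is a hidden parameter of the
result; with the thresholded criteria it is not.

The test stacks use a 100 × 100 canvas with a 40-px square pair over 60
slices — small enough that the whole curve is recomputed in well under a
second while exercising every window-geometry branch.

## Cytofluorogram and statistics

`cytofluorogram()` partitions the joint intensities at the thresholds into
quadrant 1 (green-only above), 2 (both — the AND selection), 3 (red-only
above) and 4 (neither); quadrants 1 + 2 + 3 are the OR selection, and the
counts are asserted to agree exactly with `select_pixels()`. The regression
line is ordinary least squares of green on red (red on the x-axis) over a
chosen selection; its slope carries the sign of the PCC over the same set.
The optional kernel density estimate is presentation-layer only: Gaussian
kernel, Scott's-rule bandwidth, a 128 × 128 grid padded by three kernel
standard deviations so the density integrates to 1 on its grid (checked to
$10^{-3}$); no quantitative result depends on it.

The comparison layer holds classical tools under explicit conventions:
`two_sample_t()` is the pooled equal-variance Student test (not Welch),
`one_sample_t()` tests a sample of coefficients against a hypothesised mean
(typically 0, the no-correlation value), and `hedges_g()` applies the
small-sample correction $J = 1 - 3/(4N - 9)$ to the pooled-SD standardised
mean difference. Randomisation nulls complement them: `rotation_null()`
rotates the green channel 90° counter-clockwise (histograms, and hence Otsu
thresholds, are unchanged; non-square images are centre-cropped to the
overlapping square; rotating *both* channels is offered as a sanity mode that
must reproduce the original values exactly), and `scramble_null()` permutes
square blocks of the green channel, seeded and bit-reproducible.

## Numerical choices and degenerate inputs

All accumulation is in double precision; values are rounded (to 2 d.p.) only
for display. Failure modes are classed conditions
(`coloccrit_empty_selection`, `coloccrit_degenerate_error`,
`coloccrit_no_contrast`, …) so callers can distinguish an empty AND selection
from a genuinely undefined correlation; batch drivers (`pcc_vs_zrange()`,
the null generators) convert these to `NA` per window or replicate rather
than aborting a whole curve.

## What the synthetic benchmarks do and do not show

The generators emulate geometry and selection effects — overlap area,
foreground-to-background ratio, threshold interplay — under noise-free,
flat-or-Gaussian intensity profiles. They deliberately omit photon (Poisson)
noise, detector offsets, point-spread blur, chromatic misregistration and
realistic morphology. Passing the closed-form and invariance tests therefore
validates the *selection machinery*, not any claim about a particular
specimen; on real data the coefficients additionally inherit the usual
caveats of thresholding (histogram methods always split an image into two
classes, even a pure-background one) and of diffraction-limited
colocalisation itself, which can never prove molecular interaction.
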