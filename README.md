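# coloccrit

Pearson colocalisation coefficients for two-channel fluorescence microscopy,
computed under explicit pixel-selection criteria.

## The problem

The Pearson correlation coefficient (PCC) of paired pixel intensities is the
workhorse of colocalisation analysis, but its value depends on *which pixels
enter the sum* — and software packages silently disagree on that choice.
Three conventions are in circulation:

| coefficient | pixel set |
|---|---|
| PCC_ALL | every pixel in the image |
| PCC_OR  | pixels strictly above the green **and/or** the red threshold |
| PCC_AND | pixels strictly above **both** thresholds |

with means and sums always taken over the selected subset. The same image can
yield a near-zero PCC_ALL, a strongly negative PCC_OR and a PCC_AND of 1.00:
PCC_ALL is confounded by the foreground-to-background ratio, PCC_OR mixes
spatial co-occurrence with intensity proportionality, and PCC_AND isolates
proportionality on co-occurring pixels and so detects weak colocalisation
that the other two miss.

`coloccrit` makes the criterion a first-class argument and supplies the
machinery needed to characterise and compare the three estimators: Otsu and
Costes automatic thresholding, synthetic benchmark generators with closed-form
expected values, z-stack range curves, cytofluorogram quadrant summaries, and
randomisation nulls (channel rotation, block scrambling) with Student t-tests
and Hedges' g. It is aimed at microscopists quantifying colocalisation and at
tool authors who need a reference implementation of the three criteria.

## Worked example

Two 80 × 80 squares of intensity 0.8 on a 1000 × 1000 canvas, 25% of each
square overlapping the other — an image whose three coefficients are known
analytically:

```r
library(coloccrit)

pair <- make_square_pair(side = 80)
pcc(pair, criterion = "all")
#> PCC_ALL = 0.25
#>   thresholds: green=0 red=0; 1000000 pixels (100%)
pcc(pair, c(0.1, 0.1), "or")
#> PCC_OR = -0.75
#>   thresholds: green=0.1 red=0.1; 11200 pixels (1.12%)
pcc(pair, c(0.1, 0.1), "and")
#> PCC_AND = 1.00 (degenerate: zero-variance convention)
#>   thresholds: green=0.1 red=0.1; 1600 pixels (0.16%)
```

One image, three answers: 0.25 says "weak association", −0.75 says "mutual
exclusion", 1.00 says "perfect colocalisation". The OR selection (11 200
pixels) is dominated by the non-overlapping square regions, hence the negative
value; the AND selection (the 1600 shared pixels) is constant in both
channels, so its coefficient is reported under the positive-proportionality
convention with a `degenerate` flag. Sweeping the square size shows PCC_ALL
drifting from 0.25 down to −0.33 while the thresholded criteria do not move:

```r
object_size_sweep(c(2, 80, 160, 320, 660))[, c("side", "pcc_all", "pcc_or", "pcc_and")]
#>   side    pcc_all pcc_or pcc_and
#> 1    2  0.2500188  -0.75       1
#> 2   80  0.2452096  -0.75       1
#> 3  160  0.2302662  -0.75       1
#> 4  320  0.1643584  -0.75       1
#> 5  660 -0.3288382  -0.75       1
```

On a five-spot Gaussian mock image with one coincident spot pair
(`make_spot_pair()`), per-channel Otsu thresholds give PCC_AND = 1.00 from the
0.18% of pixels where the signals co-occur, while PCC_ALL ≈ 0.19 and
PCC_OR ≈ −0.58. For z-stacks, `pcc_vs_zrange()` shows PCC_ALL rising as empty
slices are added while PCC_OR/PCC_AND stay fixed to machine precision.

A command-line front end ships at `inst/cli/coloc-pcc.R`
(subcommands `pcc`, `sweep`, `zrange`, `null`, `synth`; TIFF in, CSV out).
See the vignette `vignettes/pixel-selection-criteria.Rmd` for the model,
conventions and numerical choices.

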