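#' Otsu intensity threshold
#'
#' Splits the intensity histogram at the bin edge that maximises the
#' between-class variance of the two induced classes.  The histogram uses
#' `n_bins` equal-width bins over `range` (the data range by default); values
#' falling exactly on a bin edge are assigned to the lower bin.  Class means
#' and weights are computed from the actual pixel values in each bin, not bin
#' midpoints, so the returned edge is the exact maximiser over all candidate
#' edge splits.  Pixels strictly above the returned threshold are foreground.
#'
#' @param image numeric matrix or array of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @param range length-2 numeric, histogram support; defaults to the data range.
#' @return A single numeric threshold (a histogram bin edge).
#' @examples
#' img <- matrix(c(rep(0, 990), rep(0.8, 34)), 32)
#' otsu_threshold(img)  # strictly between 0 and 0.8
#' @export
otsu_threshold <- function(image, n_bins = 256L, range = NULL) {
  x <- as.numeric(image)
  if (anyNA(x) || any(!is.finite(x))) {
    stop_coloccrit("image contains non-finite values", "coloccrit_input_error")
  }
  if (n_bins < 2L) {
    stop_coloccrit("'n_bins' must be at least 2", "coloccrit_input_error")
  }
  if (is.null(range)) range <- c(min(x), max(x))
  if (range[2] <= range[1] || length(unique(x)) < 2L) {
    stop_coloccrit("image has no intensity contrast: cannot threshold",
                   "coloccrit_no_contrast")
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  # left-open bins (a, b] put edge ties in the lower bin; clamp the minimum
  bin <- findInterval(x, edges, left.open = TRUE, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  bin[bin > n_bins] <- n_bins
  cnt <- as.numeric(tabulate(bin, nbins = n_bins))
  # per-bin sums of the actual pixel values (exact class means at each split)
  s <- numeric(n_bins)
  occupied <- sort(unique(bin))
  s[occupied] <- as.numeric(rowsum(x, factor(bin, levels = occupied))[, 1])
  n <- length(x)
  w0 <- cumsum(cnt)[-n_bins]           # class <= edge k+1
  s0 <- cumsum(s)[-n_bins]
  w1 <- n - w0
  s1 <- sum(x) - s0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- w0[valid] * w1[valid] * (s0[valid] / w0[valid] - s1[valid] / w1[valid])^2
  k <- which.max(bcv)                  # first maximum -> lowest threshold on ties
  edges[k + 1L]
}

#' Costes automatic threshold search
#'
#' Iterative PCC-based threshold determination.  The red threshold starts at
#' the top of the red intensity range and is lowered one histogram bin at a
#' time; the green threshold is slaved to it through the least-squares
#' regression line of green on red over all pixels.  At each step the Pearson
#' correlation of the pixels at-or-below both thresholds (the complement of
#' the strict OR selection) is computed; the first thresholds at which that
#' correlation is null or negative are returned.  Pixels above those
#' thresholds are the ones a subsequent thresholded PCC should use.
#'
#' If the scan reaches the bottom of the red range without meeting the
#' stopping condition (e.g. the two channels are globally correlated at every
#' intensity level), the thresholds are returned at the grid minimum with
#' `converged = FALSE` and a warning.  Steps whose below-threshold set has
#' fewer than two pixels or zero variance in a channel do not satisfy the
#' stopping condition and the scan continues.
#'
#' @param pair a [channel_pair()]; both channels must be nonconstant.
#' @param n_bins histogram resolution of the red-threshold grid (default 256).
#' @return Object of class `costes_thresholds`: list with `thresholds`
#'   (`c(green, red)`), `below_threshold_pcc`, `n_iterations`, `converged`,
#'   and the regression coefficients `slope`, `intercept`.
#' @examples
#' set.seed(1)
#' p <- channel_pair(matrix(runif(4096), 64), matrix(runif(4096), 64))
#' costes_thresholds(p)
#' @export
costes_thresholds <- function(pair, n_bins = 256L) {
  pair <- as_channel_pair(pair)
  g <- as.numeric(pair$green)
  r <- as.numeric(pair$red)
  if (stats::var(g) == 0 || stats::var(r) == 0) {
    stop_coloccrit("both channels must be nonconstant for the Costes search",
                   "coloccrit_no_contrast")
  }
  slope <- stats::cov(r, g) / stats::var(r)
  intercept <- mean(g) - slope * mean(r)
  width <- (max(r) - min(r)) / n_bins
  grid <- max(r) - width * seq_len(n_bins)   # descending; last point = min(r)
  below_pcc <- NA_real_
  for (i in seq_along(grid)) {
    t_red <- grid[i]
    t_green <- intercept + slope * t_red
    below <- r <= t_red & g <= t_green
    below_pcc <- below_set_pcc(r[below], g[below])
    if (!is.na(below_pcc) && below_pcc <= 0) {
      return(new_costes(c(green = t_green, red = t_red), below_pcc, i, TRUE,
                        slope, intercept))
    }
  }
  warning("Costes search reached the bottom of the intensity range without ",
          "a null or negative below-threshold PCC; thresholds set to the grid minimum",
          call. = FALSE)
  t_red <- grid[length(grid)]
  new_costes(c(green = intercept + slope * t_red, red = t_red),
             below_pcc, length(grid), FALSE, slope, intercept)
}

below_set_pcc <- function(r, g) {
  if (length(r) < 2L) return(NA_real_)
  if (stats::var(r) == 0 || stats::var(g) == 0) return(NA_real_)
  stats::cor(r, g)
}

new_costes <- function(thresholds, below_pcc, n_iter, converged, slope, intercept) {
  structure(
    list(
      thresholds = thresholds,
      below_threshold_pcc = below_pcc,
      n_iterations = n_iter,
      converged = converged,
      slope = slope,
      intercept = intercept
    ),
    class = "costes_thresholds"
  )
}

#' @export
print.costes_thresholds <- function(x, ...) {
  cat(sprintf("Costes thresholds: green=%g red=%g (%d steps, %s)\n",
              x$thresholds[1], x$thresholds[2], x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  below-threshold PCC: %s\n",
              if (is.na(x$below_threshold_pcc)) "undefined"
              else sprintf("%.4f", x$below_threshold_pcc)))
  invisible(x)
}

# shared helper: resolve a thresholding policy to a numeric c(green, red)
resolve_thresholds <- function(pair, thresholds) {
  if (is.character(thresholds)) {
    switch(match.arg(thresholds, c("otsu", "costes")),
      otsu = c(green = otsu_threshold(pair$green),
               red = otsu_threshold(pair$red)),
      costes = costes_thresholds(pair)$thresholds
    )
  } else {
    check_thresholds(thresholds)
  }
}
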