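#' Cytofluorogram: joint-intensity representation of a channel pair
#'
#' Collects the paired (red, green) pixel intensities, partitions them into
#' the four threshold quadrants, and fits the least-squares regression line of
#' green on red over the pixel set admitted by `selection_for_fit`.  Quadrants
#' follow the convention that ties the partition to the selection criteria:
#' \describe{
#'   \item{quadrant 1}{above the green threshold only;}
#'   \item{quadrant 2}{above both thresholds (the AND selection);}
#'   \item{quadrant 3}{above the red threshold only;}
#'   \item{quadrant 4}{above neither (background).}
#' }
#' Quadrants 1 + 2 + 3 form the OR selection.  Thresholding uses the same
#' strict inequalities as [select_pixels()].
#'
#' @inheritParams select_pixels
#' @param selection_for_fit criterion choosing the pixels for the regression
#'   line (default `"all"`, the dashed line drawn on published
#'   cytofluorograms).
#' @param density if `TRUE`, also compute a Gaussian kernel density estimate
#'   of the joint distribution (Scott's-rule bandwidth, 128 x 128 grid
#'   extended 3 bandwidths beyond the data range).
#' @return Object of class `cytofluorogram`: list with `red`, `green`
#'   (intensity vectors), `thresholds`, `quadrant_counts` (named, q1..q4),
#'   `regression` (`c(slope, intercept)`), `fit_criterion`, and optionally
#'   `density` (a list `x`, `y`, `z` as from [MASS::kde2d()]).
#' @examples
#' p <- make_square_pair(side = 80)
#' cyto <- cytofluorogram(p, c(0.1, 0.1))
#' cyto$quadrant_counts  # 4800 1600 4800 988800
#' @export
cytofluorogram <- function(pair, thresholds = c(0, 0),
                           selection_for_fit = c("all", "or", "and"),
                           density = FALSE) {
  pair <- as_channel_pair(pair)
  selection_for_fit <- match.arg(selection_for_fit)
  thresholds <- check_thresholds(thresholds)
  g <- as.numeric(pair$green)
  r <- as.numeric(pair$red)
  above_g <- g > thresholds[1]
  above_r <- r > thresholds[2]
  counts <- c(
    q1 = sum(above_g & !above_r),
    q2 = sum(above_g & above_r),
    q3 = sum(!above_g & above_r),
    q4 = sum(!above_g & !above_r)
  )
  fit_mask <- as.logical(criterion_mask(pair, thresholds, selection_for_fit))
  gf <- g[fit_mask]
  rf <- r[fit_mask]
  if (length(rf) < 2L || stats::var(rf) == 0) {
    stop_coloccrit(
      "zero red-channel variance over the fit set: regression undefined",
      "coloccrit_degenerate_error"
    )
  }
  slope <- stats::cov(rf, gf) / stats::var(rf)
  intercept <- mean(gf) - slope * mean(rf)
  out <- list(
    red = r,
    green = g,
    thresholds = thresholds,
    quadrant_counts = counts,
    regression = c(slope = slope, intercept = intercept),
    fit_criterion = selection_for_fit
  )
  if (density) out$density <- joint_density(r, g)
  structure(out, class = "cytofluorogram")
}

# Gaussian KDE, Scott's rule, on a grid padded so the kernel mass is captured
joint_density <- function(r, g, n_grid = 128L) {
  n <- length(r)
  # Scott (1992) for d = 2: h_i = sigma_i * n^(-1/6); kde2d's h is 4 * sd
  sd_r <- max(stats::sd(r), .Machine$double.eps)
  sd_g <- max(stats::sd(g), .Machine$double.eps)
  h <- 4 * c(sd_r, sd_g) * n^(-1 / 6)
  pad <- 3 * h / 4  # 3 kernel standard deviations
  lims <- c(min(r) - pad[1], max(r) + pad[1], min(g) - pad[2], max(g) + pad[2])
  MASS::kde2d(r, g, h = h, n = n_grid, lims = lims)
}

#' @export
print.cytofluorogram <- function(x, ...) {
  cat("cytofluorogram of", length(x$red), "pixels\n")
  cat(sprintf("  thresholds: green=%g red=%g\n", x$thresholds[1], x$thresholds[2]))
  cat("  quadrant counts (1: green-only, 2: both, 3: red-only, 4: neither):\n")
  cat("   ", paste(sprintf("q%d=%d", 1:4, x$quadrant_counts), collapse = "  "), "\n")
  cat(sprintf("  regression (green on red, %s pixels): slope %.4g, intercept %.4g\n",
              toupper(x$fit_criterion), x$regression[1], x$regression[2]))
  invisible(x)
}

#' Plot a cytofluorogram
#'
#' Scatter (or KDE contour, when a density grid is present) of green versus
#' red pixel intensities with the threshold lines and the fitted regression
#' line.
#'
#' @param x a [cytofluorogram()].
#' @param max_points subsample cap for the scatter display.
#' @param ... passed to the underlying plot call.
#' @export
plot.cytofluorogram <- function(x, max_points = 20000L, ...) {
  if (!is.null(x$density)) {
    graphics::image(x$density, xlab = "red intensity", ylab = "green intensity",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::contour(x$density, add = TRUE, col = "white", drawlabels = FALSE)
  } else {
    idx <- if (length(x$red) > max_points) {
      seq(1L, length(x$red), length.out = max_points)
    } else {
      seq_along(x$red)
    }
    graphics::plot(x$red[idx], x$green[idx], pch = ".", col = "grey30",
                   xlab = "red intensity", ylab = "green intensity", ...)
  }
  graphics::abline(v = x$thresholds[2], h = x$thresholds[1], col = "blue")
  graphics::abline(a = x$regression[2], b = x$regression[1],
                   col = "red", lty = 2)
  invisible(x)
}
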