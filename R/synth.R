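#' Synthetic overlapping-square image pair
#'
#' Generates the benchmark pair used to study object-size effects: one filled
#' square per channel on a zero background, positioned so that a fixed
#' fraction of each square's area is shared with the other.  With the default
#' 25% overlap the red square is offset diagonally by half a side, giving a
#' `(side/2)^2` shared region; any layout with the same areas yields identical
#' coefficients, so the geometry is presentation-only.
#'
#' @param side square side in pixels.  The offset `side * (1 - sqrt(overlap_fraction))`
#'   must be a whole number of pixels (always true for even sides at 25%).
#' @param canvas length-2 integer, image height and width (default 1000 x 1000).
#' @param overlap_fraction fraction of each square's area shared with the other
#'   (default 0.25).
#' @param intensity fill value of both squares (default 0.8); background is 0.
#' @return A [channel_pair()].
#' @examples
#' p <- make_square_pair(side = 80)
#' sum(p$green > 0)                 # 6400 foreground pixels per channel
#' sum(p$green > 0 & p$red > 0)     # 1600 shared pixels
#' @export
make_square_pair <- function(side, canvas = c(1000L, 1000L),
                             overlap_fraction = 0.25, intensity = 0.8) {
  if (side < 1 || overlap_fraction <= 0 || overlap_fraction >= 1) {
    stop_coloccrit("need side >= 1 and 0 < overlap_fraction < 1",
                   "coloccrit_spec_error")
  }
  offset <- side * (1 - sqrt(overlap_fraction))
  if (abs(offset - round(offset)) > 1e-9) {
    stop_coloccrit(
      sprintf("offset %.4g px for side %d at overlap %.3g is not integral",
              offset, side, overlap_fraction),
      "coloccrit_spec_error"
    )
  }
  offset <- as.integer(round(offset))
  extent <- side + offset
  if (extent > min(canvas)) {
    stop_coloccrit(
      sprintf("squares of side %d with offset %d do not fit a %d x %d canvas",
              side, offset, canvas[1], canvas[2]),
      "coloccrit_spec_error"
    )
  }
  r0 <- (min(canvas) - extent) %/% 2L  # top-left of the green square (0-based)
  green <- matrix(0, canvas[1], canvas[2])
  red <- matrix(0, canvas[1], canvas[2])
  green[r0 + seq_len(side), r0 + seq_len(side)] <- intensity
  red[r0 + offset + seq_len(side), r0 + offset + seq_len(side)] <- intensity
  channel_pair(green, red)
}

#' Default spot centres: a 4x4 grid allocation
#'
#' Sixteen candidate centres on a regular grid, pairwise separated by far more
#' than the spot extent, ordered from the canvas centre outward (ties broken
#' by row then column).  Coincident pairs claim the most central slots, then
#' the green-only spots, then the red-only spots, so any layout of up to
#' sixteen distinct spots is deterministic.
#' @param canvas length-2 canvas size.
#' @return two-column matrix of (row, col) centres, centre-most first.
#' @keywords internal
spot_grid_centres <- function(canvas = c(1000L, 1000L)) {
  f <- c(0.125, 0.375, 0.625, 0.875)
  grid <- as.matrix(expand.grid(row = round(f * canvas[1]),
                                col = round(f * canvas[2])))
  d2 <- (grid[, 1] - canvas[1] / 2)^2 + (grid[, 2] - canvas[2] / 2)^2
  unname(grid[order(d2, grid[, 1], grid[, 2]), ])
}

#' Synthetic Gaussian-spot image pair
#'
#' Emulates a sparse dual-colour micrograph: each channel holds
#' `n_spots_per_channel` isotropic 2D Gaussian spots of identical width and
#' peak intensity on a zero background, with `n_coincident` spot pairs placed
#' at exactly the same centres in both channels and every other spot well
#' separated (at least `6 * sigma` between any two distinct centres), so that
#' no two spots contribute to the same thresholded region.  Spots are
#' truncated at `4 * sigma`.
#'
#' By default the centres are fixed and deterministic (a 3x3 grid layout, see
#' [spot_grid_centres()]); set `placement = "random"` with a `seed` for a
#' reproducible random layout.
#'
#' @param canvas length-2 canvas size (default 1000 x 1000).
#' @param n_spots_per_channel spots per channel (default 5).
#' @param n_coincident number of cross-channel coincident spot pairs
#'   (default 1).
#' @param sigma Gaussian standard deviation in pixels (default 15).
#' @param amplitude peak intensity (default 0.8).
#' @param placement `"grid"` (deterministic default) or `"random"`.
#' @param seed integer seed for random placement (ignored for `"grid"`).
#' @return A [channel_pair()].
#' @examples
#' p <- make_spot_pair()
#' thr <- c(otsu_threshold(p$green), otsu_threshold(p$red))
#' pcc(p, thr, "and")   # 1: only the coincident pair survives both thresholds
#' @export
make_spot_pair <- function(canvas = c(1000L, 1000L), n_spots_per_channel = 5L,
                           n_coincident = 1L, sigma = 15, amplitude = 0.8,
                           placement = c("grid", "random"), seed = NULL) {
  placement <- match.arg(placement)
  if (n_coincident > n_spots_per_channel) {
    stop_coloccrit("'n_coincident' cannot exceed 'n_spots_per_channel'",
                   "coloccrit_spec_error")
  }
  n_free <- n_spots_per_channel - n_coincident
  if (placement == "grid") {
    grid <- spot_grid_centres(canvas)
    if (n_coincident + 2L * n_free > nrow(grid)) {
      stop_coloccrit(
        sprintf("the grid layout offers %d slots; %d are needed (use placement = \"random\")",
                nrow(grid), n_coincident + 2L * n_free),
        "coloccrit_placement_error"
      )
    }
    if (6 * sigma > 0.25 * min(canvas)) {
      stop_coloccrit(
        sprintf("grid spacing %.0f px cannot keep spots of sigma %g separated by 6*sigma",
                0.25 * min(canvas), sigma),
        "coloccrit_placement_error"
      )
    }
    idx_co <- seq_len(n_coincident)
    idx_g <- n_coincident + seq_len(n_free)
    idx_r <- n_coincident + n_free + seq_len(n_free)
    c_green <- grid[c(idx_co, idx_g), , drop = FALSE]
    c_red <- grid[c(idx_co, idx_r), , drop = FALSE]
  } else {
    placed <- random_spot_centres(canvas, n_coincident + 2L * n_free,
                                  min_sep = 6 * sigma, margin = 4 * sigma,
                                  seed = seed)
    idx_co <- seq_len(n_coincident)
    idx_g <- n_coincident + seq_len(n_free)
    idx_r <- n_coincident + n_free + seq_len(n_free)
    c_green <- placed[c(idx_co, idx_g), , drop = FALSE]
    c_red <- placed[c(idx_co, idx_r), , drop = FALSE]
  }
  channel_pair(
    render_spots(canvas, c_green, sigma, amplitude),
    render_spots(canvas, c_red, sigma, amplitude)
  )
}

random_spot_centres <- function(canvas, n, min_sep, margin, seed = NULL,
                                max_tries = 10000L) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  centres <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(centres) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_coloccrit(
        sprintf("could not place %d spots with separation %g on this canvas",
                n, min_sep),
        "coloccrit_placement_error"
      )
    }
    cand <- c(stats::runif(1, margin, canvas[1] - margin),
              stats::runif(1, margin, canvas[2] - margin))
    if (nrow(centres) == 0L ||
        min(sqrt(rowSums(sweep(centres, 2, cand)^2))) >= min_sep) {
      centres <- rbind(centres, cand)
    }
  }
  unname(centres)
}

render_spots <- function(canvas, centres, sigma, amplitude) {
  img <- matrix(0, canvas[1], canvas[2])
  half <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centres))) {
    cr <- centres[k, 1]; cc <- centres[k, 2]
    rows <- max(1, floor(cr - half)):min(canvas[1], ceiling(cr + half))
    cols <- max(1, floor(cc - half)):min(canvas[2], ceiling(cc + half))
    d2 <- outer((rows - cr)^2, (cols - cc)^2, `+`)
    patch <- amplitude * exp(-d2 / (2 * sigma^2))
    patch[d2 > (4 * sigma)^2] <- 0      # hard truncation at 4 sigma
    img[rows, cols] <- img[rows, cols] + patch
  }
  img
}

#' Object-size sweep over square pairs
#'
#' Recomputes the three coefficients for a series of square sides on a fixed
#' canvas, reproducing the size dependence of PCC_ALL and the size invariance
#' of PCC_OR and PCC_AND.  The `area_ratio` column is
#' `(green area + red area) / canvas area = 2 * side^2 / (H * W)`.
#'
#' @param sides integer vector of square sides.
#' @param canvas,overlap_fraction,intensity passed to [make_square_pair()].
#' @param thresholds thresholds for the OR and AND criteria (default 0.1, as
#'   appropriate for intensity-0.8 objects).
#' @return data.frame with columns `side`, `area_ratio`, `pcc_all`, `pcc_or`,
#'   `pcc_and`, `and_degenerate`.
#' @examples
#' object_size_sweep(c(80, 160, 320))$pcc_all  # 0.25 0.23 0.16 (2 d.p.)
#' @export
object_size_sweep <- function(sides, canvas = c(1000L, 1000L),
                              overlap_fraction = 0.25, intensity = 0.8,
                              thresholds = c(0.1, 0.1)) {
  rows <- lapply(sides, function(s) {
    p <- make_square_pair(s, canvas, overlap_fraction, intensity)
    a <- pcc(p, criterion = "all")
    o <- pcc(p, thresholds, "or")
    d <- pcc(p, thresholds, "and")
    data.frame(
      side = s,
      area_ratio = 2 * s^2 / prod(canvas),
      pcc_all = a$value,
      pcc_or = o$value,
      pcc_and = d$value,
      and_degenerate = d$degenerate
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
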