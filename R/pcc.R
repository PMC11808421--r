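#' Select the pixels entering a PCC calculation
#'
#' Applies one of the three pixel-selection criteria used for thresholded
#' Pearson correlation coefficients:
#' \describe{
#'   \item{`"all"`}{every pixel, regardless of intensity or thresholds;}
#'   \item{`"or"`}{pixels strictly above the green threshold and/or strictly
#'     above the red threshold;}
#'   \item{`"and"`}{pixels strictly above both thresholds.}
#' }
#' Inequalities are strict: a pixel exactly at a threshold is excluded.  The
#' `"all"` criterion ignores the thresholds entirely.
#'
#' @param pair a [channel_pair()] (or `zstack_pair`).
#' @param thresholds numeric of length 2, `c(green, red)` intensity thresholds
#'   (same units as the images); a single value is used for both channels.
#' @param criterion one of `"all"`, `"or"`, `"and"`.
#' @return An object of class `selection_mask`: a list with `mask` (logical
#'   array, shape of the images), `criterion`, `thresholds`, `n_selected` and
#'   `fraction_selected`.
#' @examples
#' p <- make_square_pair(side = 80)
#' select_pixels(p, c(0.1, 0.1), "and")$n_selected  # 1600 shared pixels
#' @export
select_pixels <- function(pair, thresholds = c(0, 0), criterion = c("all", "or", "and")) {
  pair <- as_channel_pair(pair)
  criterion <- match.arg(criterion)
  thresholds <- check_thresholds(thresholds)
  mask <- criterion_mask(pair, thresholds, criterion)
  n_sel <- sum(mask)
  structure(
    list(
      mask = mask,
      criterion = criterion,
      thresholds = thresholds,
      n_selected = n_sel,
      fraction_selected = n_sel / n_pixels(pair)
    ),
    class = "selection_mask"
  )
}

criterion_mask <- function(pair, thresholds, criterion) {
  switch(criterion,
    all = array(TRUE, dim = dim(pair$green)),
    or  = pair$green > thresholds[1] | pair$red > thresholds[2],
    and = pair$green > thresholds[1] & pair$red > thresholds[2]
  )
}

check_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || !length(thresholds) %in% c(1L, 2L) ||
      anyNA(thresholds) || any(thresholds < 0)) {
    stop_coloccrit("'thresholds' must be 1 or 2 nonnegative numbers",
                   "coloccrit_input_error")
  }
  thresholds <- rep_len(as.numeric(thresholds), 2L)
  names(thresholds) <- c("green", "red")
  thresholds
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf(
    "selection mask (criterion %s, thresholds green=%g red=%g)\n",
    toupper(x$criterion), x$thresholds[1], x$thresholds[2]
  ))
  cat(sprintf("  %d pixels selected (%.3g%%)\n", x$n_selected,
              100 * x$fraction_selected))
  invisible(x)
}

#' Pearson's correlation coefficient under a pixel-selection criterion
#'
#' Computes the Pearson correlation of the paired (red, green) pixel
#' intensities over the pixel set admitted by `criterion` at the given
#' `thresholds`.  Channel means and sums are taken over the selected subset
#' only, not over the whole image, so the three criteria genuinely measure
#' different quantities: PCC_ALL is confounded by the foreground-to-background
#' ratio, PCC_OR reflects both signal co-occurrence and intensity
#' proportionality, and PCC_AND isolates intensity proportionality on
#' co-occurring pixels.
#'
#' Degenerate selections: an empty selection or a single selected pixel is an
#' error.  If both channels are constant over the selection with positive
#' intensities (the typical PCC_AND situation on flat-top synthetic objects),
#' the correlation is 0/0; by convention the coefficient is reported as `1.0`
#' with `degenerate = TRUE`, since the two constant intensity vectors are
#' positively proportional.  If only one channel has zero variance the value
#' is undefined and an error of class `coloccrit_degenerate_error` is raised.
#'
#' @inheritParams select_pixels
#' @return Object of class `pcc`: list with `value`, `criterion`, `thresholds`,
#'   `n_selected`, `fraction_selected`, `degenerate`.
#' @examples
#' p <- make_square_pair(side = 80)
#' pcc(p, criterion = "all")                      # 0.25
#' pcc(p, c(0.1, 0.1), "or")                      # -0.75
#' pcc(p, c(0.1, 0.1), "and")                     # 1 (degenerate: flat squares)
#' @seealso [select_pixels()], [otsu_threshold()], [costes_thresholds()]
#' @export
pcc <- function(pair, thresholds = c(0, 0), criterion = c("all", "or", "and")) {
  pair <- as_channel_pair(pair)
  criterion <- match.arg(criterion)
  sel <- select_pixels(pair, thresholds, criterion)
  g <- pair$green[sel$mask]
  r <- pair$red[sel$mask]
  if (length(g) == 0L) {
    stop_coloccrit(
      sprintf("no pixels selected under criterion %s at thresholds (%g, %g)",
              toupper(criterion), sel$thresholds[1], sel$thresholds[2]),
      "coloccrit_empty_selection"
    )
  }
  if (length(g) < 2L) {
    # a lone selected pixel is a zero-variance set; the positive-proportional
    # convention below still applies (flat-top objects whose shared region is
    # a single pixel), otherwise the correlation is undefined
    if (g[1] > 0 && r[1] > 0) {
      vg <- vr <- 0
    } else {
      stop_coloccrit("fewer than 2 pixels selected: correlation undefined",
                     "coloccrit_degenerate_error")
    }
  } else {
    vg <- stats::var(g)
    vr <- stats::var(r)
  }
  degenerate <- FALSE
  if (vg == 0 && vr == 0) {
    if (g[1] > 0 && r[1] > 0) {
      value <- 1.0
      degenerate <- TRUE
    } else {
      stop_coloccrit(
        "selection is constant at zero intensity in a channel: correlation undefined",
        "coloccrit_degenerate_error"
      )
    }
  } else if (vg == 0 || vr == 0) {
    stop_coloccrit(
      "one channel has zero variance over the selection: correlation undefined",
      "coloccrit_degenerate_error"
    )
  } else {
    value <- stats::cor(r, g)
  }
  structure(
    list(
      value = value,
      criterion = criterion,
      thresholds = sel$thresholds,
      n_selected = sel$n_selected,
      fraction_selected = sel$fraction_selected,
      degenerate = degenerate
    ),
    class = "pcc"
  )
}

#' @export
print.pcc <- function(x, digits = 2, ...) {
  cat(sprintf("PCC_%s = %.*f%s\n", toupper(x$criterion), digits, x$value,
              if (x$degenerate) " (degenerate: zero-variance convention)" else ""))
  cat(sprintf("  thresholds: green=%g red=%g; %d pixels (%.3g%%)\n",
              x$thresholds[1], x$thresholds[2], x$n_selected,
              100 * x$fraction_selected))
  invisible(x)
}

#' @export
coef.pcc <- function(object, ...) {
  stats::setNames(object$value, paste0("pcc_", object$criterion))
}

#' @export
summary.pcc <- function(object, ...) {
  out <- data.frame(
    criterion = object$criterion,
    value = object$value,
    degenerate = object$degenerate,
    threshold_green = object$thresholds[1],
    threshold_red = object$thresholds[2],
    n_selected = object$n_selected,
    fraction_selected = object$fraction_selected,
    row.names = NULL
  )
  class(out) <- c("summary.pcc", "data.frame")
  out
}

#' Normalise a series of PCC values by a reference entry
#'
#' Divides each coefficient by the value at `reference`, so the reference
#' position maps to 1.  Used to display object-size sweeps relative to the
#' largest PCC_ALL in the range under consideration.
#'
#' @param values numeric vector of coefficients.
#' @param reference index (1-based) of the reference value; must be nonzero.
#' @return numeric vector of dimensionless ratios.
#' @examples
#' normalize_pcc(c(0.25, 0.16))  # 1.00 0.64
#' @export
normalize_pcc <- function(values, reference = 1L) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop_coloccrit("'values' must be a nonempty numeric vector",
                   "coloccrit_input_error")
  }
  if (reference < 1L || reference > length(values)) {
    stop_coloccrit("'reference' is out of range", "coloccrit_input_error")
  }
  ref <- values[reference]
  if (!is.finite(ref) || ref == 0) {
    stop_coloccrit("reference value is zero or non-finite: cannot normalise",
                   "coloccrit_degenerate_error")
  }
  values / ref
}
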