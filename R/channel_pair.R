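#' Construct a two-channel image pair
#'
#' Bundles the "green" and "red" intensity grids of a dual-colour fluorescence
#' acquisition into a validated container.  Both channels must be numeric,
#' finite, nonnegative and of identical shape.  A 2D matrix per channel gives a
#' single-plane pair; a 3D array (slices in the first dimension) gives a
#' z-stack pair, which all downstream coefficient calculations treat as one
#' pooled voxel population.
#'
#' @param green,red numeric matrices (height x width) or 3D arrays
#'   (slices x height x width) of nonnegative intensities, same shape.
#' @return An object of class `channel_pair` (and additionally `zstack_pair`
#'   for 3D input): a list with elements `green` and `red`.
#' @examples
#' p <- channel_pair(matrix(runif(64), 8), matrix(runif(64), 8))
#' dim(p$green)
#' @export
channel_pair <- function(green, red) {
  green <- validate_channel(green, "green")
  red <- validate_channel(red, "red")
  if (!identical(dim(green), dim(red))) {
    stop_coloccrit(
      sprintf(
        "channel shapes differ: green is %s, red is %s",
        paste(dim(green), collapse = "x"), paste(dim(red), collapse = "x")
      ),
      "coloccrit_shape_error"
    )
  }
  cls <- if (length(dim(green)) == 3L) c("zstack_pair", "channel_pair") else "channel_pair"
  structure(list(green = green, red = red), class = cls)
}

#' Construct a z-stack channel pair
#'
#' Convenience wrapper around [channel_pair()] for volumetric data; the first
#' array dimension indexes the z-slices.
#'
#' @inheritParams channel_pair
#' @return An object of class `zstack_pair`.
#' @export
zstack_pair <- function(green, red) {
  if (length(dim(green)) != 3L || length(dim(red)) != 3L) {
    stop_coloccrit("zstack_pair() expects 3D arrays (slices x height x width)",
                   "coloccrit_shape_error")
  }
  channel_pair(green, red)
}

validate_channel <- function(x, name) {
  if (is.null(dim(x))) {
    stop_coloccrit(sprintf("'%s' must be a matrix or 3D array", name),
                   "coloccrit_input_error")
  }
  if (!is.numeric(x)) {
    stop_coloccrit(sprintf("'%s' must be numeric", name), "coloccrit_input_error")
  }
  x <- x * 1.0  # force double storage
  if (anyNA(x) || any(!is.finite(x))) {
    stop_coloccrit(sprintf("'%s' contains non-finite intensities", name),
                   "coloccrit_input_error")
  }
  if (any(x < 0)) {
    stop_coloccrit(sprintf("'%s' contains negative intensities", name),
                   "coloccrit_input_error")
  }
  x
}

as_channel_pair <- function(x, red = NULL) {
  if (inherits(x, "channel_pair")) return(x)
  if (is.null(red)) {
    stop_coloccrit("supply a channel_pair, or green and red grids",
                   "coloccrit_input_error")
  }
  channel_pair(x, red)
}

n_pixels <- function(pair) length(pair$green)

#' @export
print.channel_pair <- function(x, ...) {
  d <- dim(x$green)
  kind <- if (inherits(x, "zstack_pair")) {
    sprintf("z-stack pair: %d slices of %d x %d", d[1], d[2], d[3])
  } else {
    sprintf("channel pair: %d x %d", d[1], d[2])
  }
  cat(kind, "\n", sep = "")
  cat(sprintf("  green: range [%g, %g]\n", min(x$green), max(x$green)))
  cat(sprintf("  red:   range [%g, %g]\n", min(x$red), max(x$red)))
  invisible(x)
}

# classed conditions so callers can distinguish failure modes
stop_coloccrit <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coloccrit_error")))
}
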