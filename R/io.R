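#' Read a two-channel image pair (or z-stack pair) from TIFF
#'
#' Accepts either two single-channel files (one per channel; multi-page files
#' are read as z-stacks, one slice per page) or a single file whose pages
#' interleave the channels (page 1 = green, page 2 = red, then repeating for
#' stacks).  8- and 16-bit integer samples are returned in native units by
#' default; 32-bit samples are read as floating point.  Pearson coefficients
#' are invariant under the integer-vs-normalised choice, but fixed thresholds
#' are not, so the scale in use is worth keeping explicit.
#'
#' @param path_green path to the green-channel TIFF, or to a single
#'   two-channel (interleaved-page) TIFF when `path_red` is `NULL`.
#' @param path_red path to the red-channel TIFF, or `NULL`.
#' @param normalize if `TRUE`, integer samples are scaled to `[0, 1]` by their
#'   bit depth; floating-point samples are returned as stored either way.
#' @return A [channel_pair()] (single plane) or [zstack_pair()] (multi-slice).
#' @export
read_channel_pair <- function(path_green, path_red = NULL, normalize = FALSE) {
  if (is.null(path_red)) {
    pages <- read_tiff_pages(path_green, normalize)
    if (length(pages) %% 2L != 0L) {
      stop_coloccrit(
        sprintf("'%s' has %d pages; an interleaved two-channel file needs an even count",
                path_green, length(pages)),
        "coloccrit_io_error"
      )
    }
    green <- pages[seq(1L, length(pages), by = 2L)]
    red <- pages[seq(2L, length(pages), by = 2L)]
  } else {
    green <- read_tiff_pages(path_green, normalize)
    red <- read_tiff_pages(path_red, normalize)
    if (length(green) != length(red)) {
      stop_coloccrit(
        sprintf("page counts differ: '%s' has %d, '%s' has %d",
                path_green, length(green), path_red, length(red)),
        "coloccrit_io_error"
      )
    }
  }
  if (!all(vapply(c(green, red), function(p) identical(dim(p), dim(green[[1]])),
                  logical(1)))) {
    stop_coloccrit(
      sprintf("inconsistent page shapes between '%s' and '%s'",
              path_green, if (is.null(path_red)) path_green else path_red),
      "coloccrit_io_error"
    )
  }
  if (length(green) == 1L) {
    channel_pair(green[[1]], red[[1]])
  } else {
    zstack_pair(stack_slices(green), stack_slices(red))
  }
}

read_tiff_pages <- function(path, normalize) {
  if (!file.exists(path)) {
    stop_coloccrit(sprintf("file not found: '%s'", path), "coloccrit_io_error")
  }
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  bits <- if (is.data.frame(info)) info$bits.per.sample else info[["bits.per.sample"]]
  is_float <- any(bits >= 32)
  # floats must be read as stored; integers as.is for native units
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float && !normalize)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L && dim(p)[3] == 1L) p <- p[, , 1]
    storage.mode(p) <- "double"
    p
  })
}

stack_slices <- function(pages) {
  d <- dim(pages[[1]])
  out <- array(0, dim = c(length(pages), d[1], d[2]))
  for (s in seq_along(pages)) out[s, , ] <- pages[[s]]
  out
}

#' Write a channel pair to TIFF
#'
#' Writes grayscale pages with the channels interleaved (green page first; for
#' z-stacks, green/red alternating slice by slice), the layout
#' [read_channel_pair()] expects for single-file input.  Intensities must lie
#' in `[0, 1]`; 32-bit output is stored as floating point, 8/16-bit as scaled
#' integers.
#'
#' @param pair a [channel_pair()] or [zstack_pair()].
#' @param path output file path.
#' @param bits bits per sample: 8, 16 or 32 (default 32, float).
#' @return `path`, invisibly.
#' @export
write_channel_pair <- function(pair, path, bits = 32L) {
  pair <- as_channel_pair(pair)
  if (max(pair$green, pair$red) > 1) {
    stop_coloccrit("intensities must be in [0, 1] for TIFF export",
                   "coloccrit_io_error")
  }
  if (inherits(pair, "zstack_pair")) {
    n <- dim(pair$green)[1]
    pages <- vector("list", 2L * n)
    for (s in seq_len(n)) {
      pages[[2L * s - 1L]] <- pair$green[s, , ]
      pages[[2L * s]] <- pair$red[s, , ]
    }
  } else {
    pages <- list(pair$green, pair$red)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Run a full PCC analysis from a configuration
#'
#' High-level driver behind the command-line interface: resolves the input
#' (TIFF files or a synthetic generator spec), resolves the thresholding mode,
#' computes the requested coefficients and writes a schema-stable CSV
#' (columns: `criterion`, `value`, `degenerate`, `threshold_green`,
#' `threshold_red`, `n_selected`, `fraction_selected`, `threshold_mode`).
#'
#' @param config a list with entries:
#'   \describe{
#'     \item{`input`}{character of 1-2 TIFF paths, or `NULL`;}
#'     \item{`synthetic`}{a list `list(kind = "square"|"spot", ...)` of
#'       arguments for [make_square_pair()] / [make_spot_pair()], or `NULL`
#'       (exactly one of `input` / `synthetic` must be given);}
#'     \item{`criteria`}{criteria to compute (default all three);}
#'     \item{`threshold_mode`}{`"otsu"`, `"costes"` or `"fixed"`;}
#'     \item{`thresholds`}{numeric `c(green, red)`, required for `"fixed"`;}
#'     \item{`normalize`}{passed to [read_channel_pair()];}
#'     \item{`output`}{CSV path, or `NULL` to skip writing.}
#'   }
#' @return The results data.frame, invisibly.
#' @export
run_pcc_command <- function(config) {
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth) {
    stop_coloccrit("config needs exactly one of 'input' or 'synthetic'",
                   "coloccrit_input_error")
  }
  pair <- if (has_input) {
    paths <- config$input
    read_channel_pair(paths[1], if (length(paths) > 1) paths[2] else NULL,
                      normalize = isTRUE(config$normalize))
  } else {
    spec <- config$synthetic
    kind <- match.arg(spec$kind, c("square", "spot"))
    args <- spec[setdiff(names(spec), "kind")]
    if (kind == "square") do.call(make_square_pair, args)
    else do.call(make_spot_pair, args)
  }
  criteria <- config$criteria %||% c("all", "or", "and")
  mode <- match.arg(config$threshold_mode %||% "otsu",
                    c("otsu", "costes", "fixed"))
  thr <- if (mode == "fixed") {
    if (is.null(config$thresholds)) {
      stop_coloccrit("threshold_mode 'fixed' requires 'thresholds'",
                     "coloccrit_input_error")
    }
    check_thresholds(config$thresholds)
  } else {
    resolve_thresholds(pair, mode)
  }
  rows <- lapply(criteria, function(cr) {
    res <- pcc(pair, thr, cr)
    out <- summary(res)
    out$threshold_mode <- mode
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  if (!is.null(config$output)) {
    utils::write.csv(out, config$output, row.names = FALSE)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
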