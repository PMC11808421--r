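#' PCC as a function of the z-range included around the stack centre
#'
#' For a growing family of slice windows centred on the stack midpoint, pools
#' all voxels in each window and computes the three coefficients at fixed
#' thresholds.  This exposes the dependence of PCC_ALL on the
#' foreground-to-background ratio: adding nearly-empty slices dilutes the
#' background class and drags PCC_ALL upward, while PCC_OR and PCC_AND, whose
#' selections exclude background voxels, are unchanged.
#'
#' Windows grow symmetrically by `step` slices per side per row, starting from
#' `min_slices`, and are clipped to the stack at the edges; the final row is
#' always the full stack.  For even window sizes the centre is biased toward
#' the lower slice index.  Thresholds are held fixed across windows (supply
#' them, or compute them once on the full stack), so differences along the
#' curve reflect pixel-selection effects only.  Windows in which the OR or AND
#' selection is empty or degenerate get `NA` for that column.
#'
#' @param stack a [zstack_pair()].
#' @param thresholds numeric `c(green, red)` thresholds, or `"otsu"` to
#'   compute per-channel Otsu thresholds on the full stack.
#' @param min_slices smallest window (default 20).
#' @param step slices added per side per row (default 1).
#' @return Object of class `zrange_curve` (a data.frame) with columns
#'   `n_slices`, `first`, `last`, `pcc_all`, `pcc_or`, `pcc_and`.
#' @export
pcc_vs_zrange <- function(stack, thresholds = "otsu", min_slices = 20L, step = 1L) {
  if (!inherits(stack, "zstack_pair")) {
    stop_coloccrit("'stack' must be a zstack_pair", "coloccrit_input_error")
  }
  n_total <- dim(stack$green)[1]
  if (min_slices > n_total) {
    stop_coloccrit("'min_slices' exceeds the number of slices",
                   "coloccrit_input_error")
  }
  thresholds <- resolve_thresholds(stack, thresholds)
  centre <- (n_total + 1L) %/% 2L  # lower-middle slice for even totals
  windows <- list()
  k <- 0L
  repeat {
    n <- min_slices + 2L * k * step
    first <- max(1L, centre - (n - 1L) %/% 2L - ((n - 1L) %% 2L))
    last <- min(n_total, first + n - 1L)
    first <- max(1L, min(first, last - n + 1L))
    win <- c(first, last)
    if (length(windows) == 0L || !identical(windows[[length(windows)]], win)) {
      windows[[length(windows) + 1L]] <- win
    }
    if (win[1] == 1L && win[2] == n_total) break
    k <- k + 1L
  }
  rows <- lapply(windows, function(w) {
    sub <- zstack_pair(
      stack$green[w[1]:w[2], , , drop = FALSE],
      stack$red[w[1]:w[2], , , drop = FALSE]
    )
    vals <- vapply(c("all", "or", "and"), function(cr) {
      tryCatch(pcc(sub, thresholds, cr)$value,
               coloccrit_empty_selection = function(e) NA_real_,
               coloccrit_degenerate_error = function(e) NA_real_)
    }, numeric(1))
    data.frame(n_slices = w[2] - w[1] + 1L, first = w[1], last = w[2],
               pcc_all = vals[["all"]], pcc_or = vals[["or"]],
               pcc_and = vals[["and"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  class(out) <- c("zrange_curve", "data.frame")
  out
}

#' @export
plot.zrange_curve <- function(x, ...) {
  graphics::matplot(x$n_slices, cbind(x$pcc_all, x$pcc_or, x$pcc_and),
                    type = "b", pch = c(1, 2, 3), lty = 1,
                    col = c("black", "forestgreen", "firebrick"),
                    xlab = "number of z-slices", ylab = "PCC", ...)
  graphics::legend("bottomright",
                   legend = c(expression(PCC[ALL]), expression(PCC[OR]),
                              expression(PCC[AND])),
                   pch = c(1, 2, 3),
                   col = c("black", "forestgreen", "firebrick"), bty = "n")
  invisible(x)
}
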