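#' Hedges' g effect size
#'
#' Bias-corrected standardised mean difference between two samples:
#' `g = (mean(a) - mean(b)) / s_pooled * J`, where `s_pooled` is the pooled
#' standard deviation on `n1 + n2 - 2` degrees of freedom and
#' `J = 1 - 3 / (4 * (n1 + n2) - 9)` is the small-sample correction, which
#' shrinks Cohen's d toward zero.
#'
#' @param sample_a,sample_b numeric vectors, each with at least 2 values.
#' @return Object of class `effect_size`: list with `g`, `n1`, `n2`,
#'   `pooled_sd`, `correction`.
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4))$g  # -0.8
#' @export
hedges_g <- function(sample_a, sample_b) {
  check_sample(sample_a, "sample_a")
  check_sample(sample_b, "sample_b")
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  pooled_var <- ((n1 - 1) * stats::var(sample_a) +
                 (n2 - 1) * stats::var(sample_b)) / (n1 + n2 - 2)
  if (pooled_var == 0) {
    stop_coloccrit("zero pooled variance: effect size undefined",
                   "coloccrit_degenerate_error")
  }
  correction <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- (mean(sample_a) - mean(sample_b)) / sqrt(pooled_var) * correction
  structure(
    list(g = g, n1 = n1, n2 = n2, pooled_sd = sqrt(pooled_var),
         correction = correction),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Hedges' g = %.4g  (n1 = %d, n2 = %d, pooled sd = %.4g, J = %.4g)\n",
              x$g, x$n1, x$n2, x$pooled_sd, x$correction))
  invisible(x)
}

check_sample <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x)) {
    stop_coloccrit(sprintf("'%s' must hold at least 2 non-missing values", name),
                   "coloccrit_input_error")
  }
}

#' One-sample Student's t-test
#'
#' Two-sided test of the sample mean against a hypothesised value, typically
#' zero (the coefficient expected in the absence of any correlation between
#' the channels).
#'
#' @param values numeric vector, at least 2 values with positive variance.
#' @param hypothesised_mean the mean under the null (default 0).
#' @return Object of class `pcc_test`: list with `statistic`, `df`, `p_value`,
#'   `test_kind`, `hypothesised_mean`.
#' @examples
#' one_sample_t(c(0.1, 0.2, 0.3))$statistic  # 3.4641
#' @export
one_sample_t <- function(values, hypothesised_mean = 0) {
  check_sample(values, "values")
  if (stats::var(values) == 0) {
    stop_coloccrit("zero variance: t-test undefined", "coloccrit_degenerate_error")
  }
  ht <- stats::t.test(values, mu = hypothesised_mean)
  new_pcc_test(ht, "one-sample", hypothesised_mean)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical equal-variance two-sided Student's t-test on
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @inheritParams hedges_g
#' @return Object of class `pcc_test`; see [one_sample_t()].
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))$statistic  # -1.2247
#' @export
two_sample_t <- function(sample_a, sample_b) {
  check_sample(sample_a, "sample_a")
  check_sample(sample_b, "sample_b")
  pooled_var <- ((length(sample_a) - 1) * stats::var(sample_a) +
                 (length(sample_b) - 1) * stats::var(sample_b)) /
                (length(sample_a) + length(sample_b) - 2)
  if (pooled_var == 0) {
    stop_coloccrit("zero pooled variance: t-test undefined",
                   "coloccrit_degenerate_error")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  new_pcc_test(ht, "two-sample", NA_real_)
}

new_pcc_test <- function(ht, kind, hypothesised_mean) {
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      test_kind = kind,
      hypothesised_mean = hypothesised_mean
    ),
    class = "pcc_test"
  )
}

#' @export
print.pcc_test <- function(x, ...) {
  cat(sprintf("%s Student's t-test: t = %.4g, df = %g, p = %.3g\n",
              x$test_kind, x$statistic, x$df, x$p_value))
  if (x$test_kind == "one-sample") {
    cat(sprintf("  hypothesised mean: %g\n", x$hypothesised_mean))
  }
  invisible(x)
}

#' Rotate a matrix (or each slice of a volume) by 90 degrees
#'
#' Counter-clockwise quarter rotation; a pure relabelling of pixel positions,
#' so per-channel histograms (and hence Otsu thresholds) are unchanged.
#'
#' @param x matrix or 3D array (slices first).
#' @return rotated matrix/array.
#' @export
rotate90 <- function(x) {
  if (length(dim(x)) == 3L) {
    out <- array(0, dim = c(dim(x)[1], dim(x)[3], dim(x)[2]))
    for (s in seq_len(dim(x)[1])) out[s, , ] <- rotate90(x[s, , ])
    return(out)
  }
  t(x)[ncol(x):1, , drop = FALSE]
}

centre_crop <- function(x, target) {
  d <- dim(x)
  if (length(d) == 3L) {
    r0 <- (d[2] - target[1]) %/% 2L
    c0 <- (d[3] - target[2]) %/% 2L
    return(x[, r0 + seq_len(target[1]), c0 + seq_len(target[2]), drop = FALSE])
  }
  r0 <- (d[1] - target[1]) %/% 2L
  c0 <- (d[2] - target[2]) %/% 2L
  x[r0 + seq_len(target[1]), c0 + seq_len(target[2]), drop = FALSE]
}

#' Rotation randomisation null
#'
#' Empirical no-colocalisation reference: for each image pair, one channel
#' (the green channel by default) is rotated 90 degrees counter-clockwise,
#' destroying any genuine spatial correspondence while preserving its
#' intensity histogram, and the PCC under `criterion` is recomputed.  For
#' non-square images both channels are centre-cropped to the overlapping
#' square after rotation.  With `rotate = "both"` the two channels are rotated
#' identically — a pure relabelling that must reproduce the original
#' coefficients exactly (sanity-check mode).
#'
#' @param pairs a [channel_pair()] or a list of them.
#' @param criterion selection criterion for the recomputed coefficients.
#' @param thresholds `"otsu"` (recomputed per channel on the transformed pair,
#'   the default), `"costes"`, or a fixed numeric `c(green, red)`.
#' @param rotate `"green"` (default) or `"both"`.
#' @return Object of class `pcc_null`: list with `values` (one PCC per pair,
#'   `NA` where the selection was empty or degenerate), `transform`,
#'   `criterion`.
#' @export
rotation_null <- function(pairs, criterion = c("all", "or", "and"),
                          thresholds = "otsu", rotate = c("green", "both")) {
  criterion <- match.arg(criterion)
  rotate <- match.arg(rotate)
  if (inherits(pairs, "channel_pair")) pairs <- list(pairs)
  values <- vapply(pairs, function(p) {
    p <- as_channel_pair(p)
    g <- rotate90(p$green)
    r <- if (rotate == "both") rotate90(p$red) else p$red
    if (!identical(dim(g), dim(r))) {
      # rotation swapped height and width: crop both to the central square
      plane <- utils::tail(dim(r), 2)
      m <- min(plane)
      g <- centre_crop(g, c(m, m))
      r <- centre_crop(r, c(m, m))
    }
    tp <- channel_pair(g, r)
    tryCatch({
      thr <- resolve_thresholds(tp, thresholds)
      pcc(tp, thr, criterion)$value
    },
    coloccrit_empty_selection = function(e) NA_real_,
    coloccrit_degenerate_error = function(e) NA_real_)
  }, numeric(1))
  new_pcc_null(values, paste0("rotate90_", rotate), criterion)
}

#' Block-scramble randomisation null
#'
#' One channel (green) is partitioned into `block_size` x `block_size` tiles
#' which are randomly permuted in each replicate; the PCC under `criterion` is
#' recomputed every time.  With `block_size = 1` this is a full pixel
#' permutation.  Deterministic under a fixed `seed`.
#'
#' @param pair a [channel_pair()] (2D).
#' @param n_replicates number of scrambled replicates.
#' @param block_size tile side in pixels; must divide both image dimensions.
#' @param criterion selection criterion.
#' @param thresholds thresholding policy as in [rotation_null()]; the default
#'   `"otsu"` is computed once on the original pair (scrambling preserves the
#'   histogram exactly).
#' @param seed integer seed.
#' @return Object of class `pcc_null` with one value per replicate.
#' @export
scramble_null <- function(pair, n_replicates = 100L, block_size = 1L,
                          criterion = c("all", "or", "and"),
                          thresholds = "otsu", seed = NULL) {
  pair <- as_channel_pair(pair)
  criterion <- match.arg(criterion)
  if (n_replicates < 1L) {
    stop_coloccrit("'n_replicates' must be at least 1", "coloccrit_input_error")
  }
  d <- dim(pair$green)
  if (length(d) != 2L) {
    stop_coloccrit("scramble_null() expects a 2D pair", "coloccrit_input_error")
  }
  if (any(d %% block_size != 0)) {
    stop_coloccrit(
      sprintf("block_size %d does not divide the %d x %d image", block_size,
              d[1], d[2]),
      "coloccrit_input_error"
    )
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  thr <- resolve_thresholds(pair, thresholds)
  nbr <- d[1] %/% block_size
  nbc <- d[2] %/% block_size
  # block view: dim (block_size, nbr, block_size, nbc)
  gb <- array(pair$green, dim = c(block_size, nbr, block_size, nbc))
  values <- vapply(seq_len(n_replicates), function(i) {
    perm <- sample.int(nbr * nbc)
    flat <- matrix(aperm(gb, c(1, 3, 2, 4)), block_size * block_size, nbr * nbc)
    scrambled_blocks <- array(flat[, perm], dim = c(block_size, block_size, nbr, nbc))
    g <- array(aperm(scrambled_blocks, c(1, 3, 2, 4)), dim = d)
    tryCatch(pcc(channel_pair(g, pair$red), thr, criterion)$value,
             coloccrit_empty_selection = function(e) NA_real_,
             coloccrit_degenerate_error = function(e) NA_real_)
  }, numeric(1))
  new_pcc_null(values, sprintf("scramble_block%d", block_size), criterion)
}

new_pcc_null <- function(values, transform, criterion) {
  structure(
    list(values = values, transform = transform, criterion = criterion),
    class = "pcc_null"
  )
}

#' @export
print.pcc_null <- function(x, ...) {
  ok <- x$values[!is.na(x$values)]
  cat(sprintf("null distribution (%s, criterion %s): %d values (%d missing)\n",
              x$transform, toupper(x$criterion), length(x$values),
              sum(is.na(x$values))))
  if (length(ok)) {
    cat(sprintf("  mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
                mean(ok), stats::sd(ok), min(ok), max(ok)))
  }
  invisible(x)
}

#' @export
summary.pcc_null <- function(object, ...) {
  ok <- object$values[!is.na(object$values)]
  c(n = length(object$values), missing = sum(is.na(object$values)),
    mean = mean(ok), sd = stats::sd(ok),
    q025 = unname(stats::quantile(ok, 0.025)),
    q975 = unname(stats::quantile(ok, 0.975)))
}
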