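# Independent oracles used across the suite: deliberately naive (explicit
# loops, first-principles formulas), never calling the code paths they check.

# plain double-loop Pearson over two equal-length vectors
naive_pearson <- function(r, g) {
  n <- length(r)
  mr <- 0; mg <- 0
  for (i in seq_len(n)) { mr <- mr + r[i] / n; mg <- mg + g[i] / n }
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (r[i] - mr) * (g[i] - mg)
    sxx <- sxx + (r[i] - mr)^2
    syy <- syy + (g[i] - mg)^2
  }
  sxy / sqrt(sxx * syy)
}

# predicate-based selection by explicit per-pixel loop
naive_selected_values <- function(green, red, tg, tr, criterion) {
  gs <- c(); rs <- c()
  for (i in seq_along(green)) {
    keep <- switch(criterion,
      all = TRUE,
      or  = green[i] > tg || red[i] > tr,
      and = green[i] > tg && red[i] > tr
    )
    if (keep) { gs <- c(gs, green[i]); rs <- c(rs, red[i]) }
  }
  list(green = gs, red = rs)
}

# Pearson correlation of a discrete distribution given support points and masses
mass_point_pcc <- function(r_vals, g_vals, weights) {
  w <- weights / sum(weights)
  mr <- sum(w * r_vals); mg <- sum(w * g_vals)
  cov <- sum(w * (r_vals - mr) * (g_vals - mg))
  vr <- sum(w * (r_vals - mr)^2)
  vg <- sum(w * (g_vals - mg)^2)
  cov / sqrt(vr * vg)
}

# closed-form PCC_ALL for the overlapping-square pair: four mass points
# (I,I) s^2/4, (I,0) 3 s^2/4, (0,I) 3 s^2/4, (0,0) remainder of the canvas
square_pcc_all_closed_form <- function(side, canvas = c(1000, 1000), intensity = 0.8) {
  s2 <- side^2
  mass_point_pcc(
    r_vals = c(intensity, intensity, 0, 0),
    g_vals = c(intensity, 0, intensity, 0),
    weights = c(s2 / 4, 3 * s2 / 4, 3 * s2 / 4, prod(canvas) - 7 * s2 / 4)
  )
}

# three-mass-point closed form for the OR selection of the same pair
square_pcc_or_closed_form <- function(intensity = 0.8) {
  mass_point_pcc(
    r_vals = c(intensity, intensity, 0),
    g_vals = c(intensity, 0, intensity),
    weights = c(1, 3, 3)   # proportions 1600 : 4800 : 4800
  )
}

# exhaustive Otsu: try every candidate bin edge, score classes on raw values
brute_otsu <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  best <- -Inf; best_edge <- NA_real_
  for (k in 2:n_bins) {
    lo <- x[x <= edges[k]]
    hi <- x[x > edges[k]]
    if (length(lo) == 0 || length(hi) == 0) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (is.na(best_edge) || bcv > best) { best <- bcv; best_edge <- edges[k] }
  }
  best_edge
}

# two-sided Student p-value by numeric integration of the t density
t_pvalue_numeric <- function(tstat, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  upper <- stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
  2 * upper
}

# random nonnegative test image
rand_image <- function(n = 16, max_int = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:max_int, n * n, replace = TRUE), n, n)
}

# synthetic z-stack: n_signal central slices holding a square pair, flanked by
# n_flank all-zero slices on each side
square_zstack <- function(side = 80, n_signal = 20, n_flank = 20,
                          canvas = c(100L, 100L), intensity = 0.8) {
  p <- make_square_pair(side, canvas = canvas, intensity = intensity)
  n_total <- n_signal + 2 * n_flank
  g <- array(0, dim = c(n_total, canvas[1], canvas[2]))
  r <- array(0, dim = c(n_total, canvas[1], canvas[2]))
  idx <- n_flank + seq_len(n_signal)
  for (s in idx) { g[s, , ] <- p$green; r[s, , ] <- p$red }
  zstack_pair(g, r)
}
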