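test_that("hedges_g reproduces the hand-derived example and its symmetries", {
  res <- hedges_g(c(1, 2, 3), c(2, 3, 4))
  # mean diff -1, pooled sd 1, J = 1 - 3/15 = 0.8
  expect_equal(res$g, -0.8, tolerance = 1e-12)
  expect_equal(res$pooled_sd, 1.0, tolerance = 1e-12)
  expect_equal(res$correction, 0.8)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3))$g, 0)
  expect_equal(hedges_g(c(2, 3, 4), c(1, 2, 3))$g, 0.8, tolerance = 1e-12)
})

test_that("hedges_g magnitude is below Cohen's d for random samples", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), mean = 1)
    res <- hedges_g(a, b)
    d <- (mean(a) - mean(b)) / res$pooled_sd
    expect_lt(abs(res$g), abs(d) + 1e-15)
    expect_equal(res$g, d * res$correction, tolerance = 1e-12)
  }
})

test_that("hedges_g rejects degenerate input", {
  expect_error(hedges_g(c(1, 1), c(1, 1)), class = "coloccrit_degenerate_error")
  expect_error(hedges_g(1, c(1, 2)), class = "coloccrit_input_error")
})

test_that("one-sample t-test reproduces the direct formula", {
  res <- one_sample_t(c(0.1, 0.2, 0.3), 0)
  expect_equal(res$statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  # mean equal to the hypothesised mean
  res0 <- one_sample_t(c(-1, 0, 1), 0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # location invariance
  shift <- one_sample_t(c(0.1, 0.2, 0.3) + 5, 5)
  expect_equal(shift$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(shift$p_value, res$p_value, tolerance = 1e-12)
})

test_that("two-sample t-test reproduces the direct pooled formula", {
  res <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  swapped <- two_sample_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("t-test p-values agree with numeric integration of the t density", {
  set.seed(15)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    res <- one_sample_t(x, 0)
    expect_equal(res$p_value, t_pvalue_numeric(res$statistic, res$df),
                 tolerance = 1e-8)
  }
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1))
    b <- rnorm(sample(3:12, 1), mean = 0.5)
    res <- two_sample_t(a, b)
    expect_equal(res$p_value, t_pvalue_numeric(res$statistic, res$df),
                 tolerance = 1e-8)
  }
})

test_that("rotating both channels identically reproduces the original PCC", {
  set.seed(16)
  pairs <- lapply(1:5, function(i) channel_pair(rand_image(16), rand_image(16)))
  originals <- vapply(pairs, function(p) pcc(p, criterion = "all")$value, numeric(1))
  nd <- rotation_null(pairs, "all", thresholds = c(0, 0), rotate = "both")
  expect_equal(nd$values, originals, tolerance = 1e-14)
})

test_that("rotation destroys an off-centre coincident spot", {
  p <- make_spot_pair(canvas = c(400L, 400L), n_spots_per_channel = 2L,
                      placement = "random", seed = 77)
  thr <- c(otsu_threshold(p$green), otsu_threshold(p$red))
  original <- pcc(p, thr, "and")$value
  expect_equal(original, 1.0, tolerance = 1e-12)
  nd <- rotation_null(p, "and")
  expect_true(is.na(nd$values[1]) || nd$values[1] < 1.0)
})

test_that("rotation null on independent noise is centred at zero", {
  set.seed(18)
  pairs <- lapply(1:100, function(i) {
    channel_pair(matrix(runif(1024), 32), matrix(runif(1024), 32))
  })
  nd <- rotation_null(pairs, "all", thresholds = c(0, 0))
  vals <- nd$values
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("whole-image block scrambling is a no-op", {
  set.seed(19)
  p <- channel_pair(matrix(runif(256), 16), matrix(runif(256), 16))
  nd <- scramble_null(p, n_replicates = 5, block_size = 16, criterion = "all",
                      thresholds = c(0, 0), seed = 1)
  expect_equal(nd$values, rep(pcc(p, criterion = "all")$value, 5),
               tolerance = 1e-14)
})

test_that("pixel scrambling breaks a perfect correlation", {
  set.seed(20)
  g <- matrix(runif(1024), 32)
  p <- channel_pair(g, g)
  nd <- scramble_null(p, n_replicates = 200, block_size = 1, criterion = "all",
                      thresholds = c(0, 0), seed = 5)
  expect_lt(abs(mean(nd$values)), 0.1)
  expect_gt(pcc(p, criterion = "all")$value, quantile(nd$values, 0.99))
})

test_that("scramble null is deterministic under a fixed seed", {
  p <- channel_pair(rand_image(16, seed = 40), rand_image(16, seed = 41))
  a <- scramble_null(p, n_replicates = 20, block_size = 4, criterion = "all",
                     thresholds = c(0, 0), seed = 99)
  b <- scramble_null(p, n_replicates = 20, block_size = 4, criterion = "all",
                     thresholds = c(0, 0), seed = 99)
  expect_identical(a$values, b$values)
})

test_that("scramble null validates its inputs", {
  p <- channel_pair(rand_image(16, seed = 42), rand_image(16, seed = 43))
  expect_error(scramble_null(p, n_replicates = 0), class = "coloccrit_input_error")
  expect_error(scramble_null(p, block_size = 5), class = "coloccrit_input_error")
})
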