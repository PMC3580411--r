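test_that("boundaries follow the one-sided tail geometry at alpha = 0.01", {
  fit <- mixture_fit(means = c(-0.6, 0.4), variances = 0.25)
  calls <- classify_samples(c(0, 0.8, -1), fit, alpha = 0.01)
  z <- qnorm(0.99)
  expect_equal(calls$gain_boundary[1], -0.6 + z * 0.5, tolerance = 1e-10)
  expect_equal(calls$loss_boundary[1], 0.4 - z * 0.5, tolerance = 1e-10)
  # z_{0.99} ~ 2.326 puts the boundaries near +0.563 / -0.763
  expect_equal(round(calls$gain_boundary[1], 2), 0.56)
  expect_equal(round(calls$loss_boundary[1], 2), -0.76)
  expect_equal(as.character(calls$call), c("no_change", "gain", "loss"))
  # one-sided tail probabilities under each component
  expect_equal(calls$p_vs_lower_component,
               pnorm(c(0, 0.8, -1), -0.6, 0.5, lower.tail = FALSE))
  expect_equal(calls$p_vs_upper_component, pnorm(c(0, 0.8, -1), 0.4, 0.5))
})

test_that("calls are monotone loss -> no_change -> gain along delta-T", {
  fit <- mixture_fit(means = c(-0.6, 0.4), variances = 0.25)
  grid <- seq(-3, 3, by = 0.01)
  calls <- classify_samples(grid, fit)
  expect_true(all(diff(as.integer(calls$call)) >= 0))
})

test_that("well-separated components fall back to posterior assignment", {
  fit <- mixture_fit(means = c(-3, 3), variances = 0.01)
  expect_warning(calls <- classify_samples(c(-3.5, -0.1, 0.1, 3.5), fit),
                 "maximum posterior")
  expect_equal(as.character(calls$call), c("loss", "loss", "gain", "gain"))
  # monotone even under the degenerate rule
  expect_warning(dense <- classify_samples(seq(-4, 4, by = 0.05), fit))
  expect_true(all(diff(as.integer(dense$call)) >= 0))
})

test_that("permuting inputs permutes calls identically", {
  fit <- mixture_fit(means = c(-0.5, 1.0), variances = 0.09)
  set.seed(44)
  x <- rnorm(80, 0.2, 0.8)
  perm <- sample(80)
  a <- suppressWarnings(classify_samples(x, fit, pair_ids = sprintf("s%02d", 1:80)))
  b <- suppressWarnings(classify_samples(x[perm], fit,
                                         pair_ids = sprintf("s%02d", (1:80)[perm])))
  b_sorted <- b[match(a$pair_id, b$pair_id), ]
  expect_equal(as.character(a$call), as.character(b_sorted$call))
  expect_equal(a$delta_t, b_sorted$delta_t)
})

test_that("classification rejects fits with the wrong number of components", {
  expect_error(classify_samples(0.1, mixture_fit(0, 0.1)), "two-component")
  fit3 <- mixture_fit(c(-1, 0, 1), 0.1)
  expect_error(classify_samples(0.1, fit3), "two-component")
  fit <- mixture_fit(c(-0.6, 0.4), 0.25)
  expect_error(classify_samples(0.1, fit, alpha = 0.7), "alpha")
  expect_error(classify_samples(NA_real_, fit), "finite")
})

test_that("two-sided tails widen the no-change band", {
  fit <- mixture_fit(means = c(-0.6, 0.4), variances = 0.25)
  one <- classify_samples(0, fit, alpha = 0.01)
  two <- classify_samples(0, fit, alpha = 0.01, two_sided = TRUE)
  expect_gt(two$gain_boundary, one$gain_boundary)
  expect_lt(two$loss_boundary, one$loss_boundary)
})

test_that("concordance implements the qPCR and FISH validation rules", {
  calls <- data.frame(pair_id = c("a", "b", "c"),
                      call = c("gain", "loss", "no_change"))
  fish <- data.frame(pair_id = c("a", "b", "c"),
                     label = c("abnormal", "normal", "normal"))
  expect_equal(as.numeric(concordance(calls, fish, mode = "fish")), 100)

  qcalls <- data.frame(pair_id = c("a", "b"), call = c("gain", "gain"))
  qpcr <- data.frame(pair_id = c("a", "b"), log_ratio = c(0.4, -0.2))
  expect_equal(as.numeric(concordance(qcalls, qpcr, mode = "qpcr")), 50)

  # 8 of 9 gain/loss samples with sign-matching qPCR ratios
  set.seed(6)
  cl <- sample(c("gain", "loss"), 9, replace = TRUE)
  lr <- ifelse(cl == "gain", 1, -1) * runif(9, 0.1, 1)
  lr[9] <- -lr[9]
  nine <- data.frame(pair_id = sprintf("s%d", 1:9), call = cl)
  ext <- data.frame(pair_id = sprintf("s%d", 1:9), log_ratio = lr)
  expect_equal(as.numeric(concordance(nine, ext, mode = "qpcr")), 100 * 8 / 9)

  # no_change-only input leaves qPCR concordance undefined
  nc <- data.frame(pair_id = "a", call = "no_change")
  expect_warning(res <- concordance(nc, qpcr, mode = "qpcr"), "undefined")
  expect_true(is.na(res))
  expect_error(concordance(calls, data.frame(pair_id = "zz", label = "normal"),
                           mode = "fish"), "no overlapping")
})
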