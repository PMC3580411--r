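test_that("rank-sum test is exact for small untied groups", {
  rt <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 0.1)
  expect_equal(rt$p_value, enum_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  # identical multisets: perfect symmetry
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("an empty group gives a not-applicable result, not an error", {
  rt <- rank_sum_test(numeric(0), c(1, 2, 3))
  expect_false(rt$applicable)
  expect_true(is.na(rt$p_value))
  expect_true(is.na(rt$statistic))
})

test_that("swapping groups maps U to n_x*n_y - U and preserves p", {
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(8) + 0.3
    a <- rank_sum_test(x, y)
    b <- rank_sum_test(y, x)
    expect_equal(b$statistic, length(x) * length(y) - a$statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("exact and normal-approximation branches agree closely without ties", {
  set.seed(22)
  for (n in 7:9) {
    x <- rnorm(n); y <- rnorm(n) + 0.5
    p_exact <- rank_sum_test(x, y, exact = TRUE)$p_value
    p_approx <- rank_sum_test(x, y, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("alternative directions behave as labelled", {
  x <- c(5, 6, 7, 9); y <- c(1, 2, 3, 4)
  expect_lt(rank_sum_test(x, y, alternative = "greater")$p_value,
            rank_sum_test(x, y, alternative = "less")$p_value)
  # paired signed-rank variant available behind the flag
  pr <- rank_sum_test(c(1, 2, 3, 5), c(2, 3, 4, 6), paired = TRUE)
  expect_true(pr$applicable)
  expect_match(pr$method, "signed rank")
})

test_that("burden comparison reports per-status medians and gain-vs-rest p", {
  co <- data.frame(pair_id = sprintf("s%d", 1:5),
                   call = c("gain", "gain", "loss", "no_change", "loss"),
                   sv_count = c(10, 12, 1, 3, 2))
  res <- burden_by_status(co, burden = "sv")
  expect_equal(res$median_gain, 11)
  expect_equal(res$median_other, 2)
  expect_equal(res$p_value, enum_ranksum_p(c(10, 12), c(1, 3, 2)))
  # equal burdens everywhere: no signal
  co$sv_count <- 5
  expect_equal(burden_by_status(co, burden = "sv")$p_value, 1)
})

test_that("strata without gain samples report NA, mirroring empty-group cohorts", {
  co <- data.frame(pair_id = sprintf("s%d", 1:6),
                   call = c("loss", "loss", "no_change", "loss", "gain", "gain"),
                   nonsilent_mutation_count = c(4, 2, 1, 3, 20, 25),
                   disease_group = c(rep("hematopoietic", 4), "solid", "solid"))
  hem <- burden_by_status(co, burden = "mutation", groups = "hematopoietic")
  expect_equal(hem$n_gain, 0)
  expect_true(is.na(hem$p_value))
  sol <- burden_by_status(co, burden = "mutation", groups = "solid")
  expect_equal(sol$n_gain, 2)
})

test_that("status fractions tally calls and sum to 100 within each group", {
  co <- data.frame(call = c(rep("gain", 3), rep("loss", 5), rep("no_change", 2)))
  fr <- status_fractions(co)
  expect_equal(fr$percent[fr$call == "gain"], 30)
  expect_equal(fr$percent[fr$call == "loss"], 50)
  expect_equal(fr$percent[fr$call == "no_change"], 20)
  expect_equal(status_fractions(data.frame(call = "gain"))$percent, c(100, 0, 0))

  set.seed(15)
  big <- data.frame(call = sample(c("gain", "loss", "no_change"), 235,
                                  replace = TRUE, prob = c(0.3, 0.5, 0.2)),
                    disease_group = sample(c("brain", "solid", "hematopoietic"),
                                           235, replace = TRUE))
  fr2 <- status_fractions(big, by = "disease_group")
  for (g in unique(big$disease_group)) {
    expect_equal(sum(fr2$percent[fr2$group == g]), 100)
    # brute-force tally
    expect_equal(fr2$n[fr2$group == g & fr2$call == "gain"],
                 sum(big$call == "gain" & big$disease_group == g))
  }
})

test_that("type-I error of the large-sample branch is near nominal", {
  set.seed(99)
  rej <- 0L
  for (i in 1:500) {
    p <- rank_sum_test(rnorm(50), rnorm(50))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / 500, 0.025)
  expect_lt(rej / 500, 0.075)
})
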