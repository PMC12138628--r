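test_that("sn_larger_is_better matches its closed form", {
  expect_equal(sn_larger_is_better(100), 40)
  expect_equal(sn_larger_is_better(1), 0)
  expect_equal(sn_larger_is_better(86.0), 20 * log10(86))
  # multi-replicate form against direct arithmetic
  y <- c(80, 90, 85)
  expect_equal(sn_larger_is_better(y), -10 * log10(mean(1 / y^2)))
  expect_error(sn_larger_is_better(c(50, 0)), "positive")
  expect_error(sn_larger_is_better(-1), "positive")
})

test_that("sn is strictly increasing in each response", {
  set.seed(42)
  for (i in 1:20) {
    y <- runif(3, 1, 100)
    j <- sample(3, 1)
    y2 <- y; y2[j] <- y2[j] + runif(1, 0.1, 10)
    expect_gt(sn_larger_is_better(y2), sn_larger_is_better(y))
  }
})

test_that("sn_to_response inverts the single-response statistic", {
  for (y in c(0.5, 1, 10, 53.3, 86, 99.99, 100))
    expect_equal(as.numeric(sn_to_response(sn_larger_is_better(y))), y)
  expect_equal(as.numeric(sn_to_response(40)), 100)
  expect_equal(as.numeric(sn_to_response(0)), 1)
  over <- sn_to_response(41)
  expect_equal(as.numeric(over), 100)
  expect_true(attr(over, "capped"))
  expect_false(attr(sn_to_response(39), "capped"))
})

test_that("display formatters truncate vs round as documented", {
  expect_equal(trunc_dec(38.99766), 38.99)   # not 39.00
  expect_equal(round_half_up(38.99766), 39.00)
  expect_equal(round_half_up(37.468), 37.47)
  expect_equal(trunc_dec(-1.8792, 3), -1.879)
  expect_equal(round_half_up(0.005), 0.01)   # half away from zero
})

test_that("sn_table computes per-run S/N from mean conversions", {
  d <- build_l9()
  snt <- sn_table(d, ref_results())
  expect_equal(snt$sn, 20 * log10(published_conversions))
  expect_error(sn_table(d, ref_results()[-3, ]), "missing result")
  # uniform scaling shifts every S/N by the same dB offset
  scaled <- ref_results(); scaled$conversion_mean <- scaled$conversion_mean / 2
  expect_equal(sn_table(d, scaled)$sn, snt$sn - 20 * log10(2))
  all100 <- ref_results(); all100$conversion_mean <- 100
  expect_equal(sn_table(d, all100)$sn, rep(40, 9))
})

test_that("response_table level means balance around the grand mean", {
  d <- build_l9()
  rt <- response_table(d, sn_table(d, ref_results()))
  for (j in 1:4)
    expect_lt(abs(sum(rt$levels[, j] - rt$grand_mean)), 1e-9)
  expect_equal(colMeans(rt$levels), rep(c(MR = 0, Cat = 0, BL = 0, t = 0)
                                        + rt$grand_mean, 1))
  expect_true(all(rt$delta >= 0))
  expect_setequal(rt$rank, 1:4)
})

test_that("response_table rejects unbalanced designs", {
  d <- build_l9(); d$levels[9, 1] <- 1L
  expect_error(response_table(d, sn_table(build_l9(), ref_results())),
               "balance")
})

test_that("constant S/N gives zero deltas and column-order ranks", {
  d <- build_l9()
  const <- ref_results(); const$conversion_mean <- 75
  rt <- response_table(d, sn_table(d, const))
  expect_equal(unname(rt$delta), rep(0, 4))
  expect_equal(unname(rt$rank), 1:4)
  expect_equal(unname(select_optimum(rt)), rep(1L, 4))
})

test_that("select_optimum supports argmax and explicit policies", {
  d <- build_l9()
  rt <- response_table(d, sn_table(d, ref_results()))
  expect_equal(select_optimum(rt), c(MR = 1L, Cat = 2L, BL = 1L, t = 3L))
  expect_equal(unname(select_optimum(rt, "explicit", c(2, 2, 1, 1))),
               c(2L, 2L, 1L, 1L))
  expect_error(select_optimum(rt, "explicit", c(2, 2, 1, 4)), "1..3")
  expect_error(select_optimum(rt, "explicit"), "one level per factor")
})

test_that("predict_sn sums level-mean gains over the grand mean", {
  d <- build_l9()
  rt <- response_table(d, sn_table(d, ref_results()))
  # independent hand sum at levels (2,2,1,3)
  lv <- c(2, 2, 1, 3)
  hand <- rt$grand_mean +
    sum(vapply(1:4, function(j) rt$levels[lv[j], j], numeric(1)) -
        rt$grand_mean)
  p <- predict_sn(rt, lv)
  expect_equal(p, hand)
  expect_equal(p, 39.78819, tolerance = 1e-6)
  # single-factor inclusion collapses to that factor's level mean
  expect_equal(predict_sn(rt, lv, include = "BL"), rt$levels[1, "BL"])
  # a flat table predicts the grand mean
  flat <- rt; flat$levels[] <- flat$grand_mean
  expect_equal(predict_sn(flat, c(1, 1, 1, 1)), flat$grand_mean)
})

test_that("predict_optimum back-transforms and flags the cap", {
  d <- build_l9()
  rt <- response_table(d, sn_table(d, ref_results()))
  opt <- predict_optimum(rt, select_optimum(rt))
  expect_true(opt$capped)           # 40.13 dB would exceed 100 %
  expect_equal(opt$conversion_pct, 100)
  stated <- predict_optimum(rt, c(2, 2, 1, 1))
  expect_false(stated$capped)
  expect_equal(stated$conversion_pct, 10^(stated$sn_db / 20))
})
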