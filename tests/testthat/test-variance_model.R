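test_that("taguchi_anova decomposes the reference variability", {
  d <- build_l9()
  an <- taguchi_anova(d, ref_results())
  tab <- an$table
  ss <- tab$ss[match(c("MR", "Cat", "BL", "t"), tab$term)]
  # independent level-mean oracle
  y <- published_conversions; gm <- mean(y)
  ss_oracle <- vapply(1:4, function(j)
    3 * sum((vapply(1:3, function(l) mean(y[d$levels[, j] == l]),
                    numeric(1)) - gm)^2), numeric(1))
  expect_equal(ss, ss_oracle)
  expect_equal(an$ss_total, sum((y - gm)^2))
  expect_equal(sum(ss), an$ss_total, tolerance = 1e-6)
  # pooling picks the smallest-SS factor (time) and leaves 2 error DF
  expect_identical(an$pooled, "t")
  err <- tab[tab$term == "error", ]
  expect_equal(err$df, 2)
  expect_equal(err$ss, ss[4])
  # contributions over non-pooled factors sum to 100
  expect_equal(sum(tab$contribution, na.rm = TRUE), 100, tolerance = 1e-6)
  # F ratios and p-values
  keep <- tab$term %in% c("MR", "Cat", "BL")
  expect_equal(tab$f[keep], tab$ms[keep] / err$ms)
  expect_true(all(tab$p[keep] > 0 & tab$p[keep] < 1))
  expect_equal(tab$p[keep],
               pf(tab$f[keep], 2, 2, lower.tail = FALSE))
  expect_equal(tab$df[tab$term == "total"], 8)
})

test_that("taguchi_anova handles degenerate and explicit pooling", {
  d <- build_l9()
  const <- ref_results(); const$conversion_mean <- 60
  an <- taguchi_anova(d, const)
  expect_true(an$degenerate)
  expect_equal(sum(an$table$ss), 0)
  # which factor gets pooled is arbitrary under all-tied SS; every
  # non-pooled contribution must be reported as 0
  non_pooled <- !an$table$pooled & !an$table$term %in% c("error", "total")
  expect_equal(an$table$contribution[non_pooled], rep(0, 3))
  an2 <- taguchi_anova(d, ref_results(), pool = c("Cat", "t"))
  expect_equal(an2$table$df[an2$table$term == "error"], 4)
  expect_error(taguchi_anova(d, ref_results(),
                             pool = c("MR", "Cat", "BL", "t")),
               "cannot pool every factor")
  expect_error(taguchi_anova(d, ref_results(), pool = "XX"), "unknown")
  d2 <- d; d2$levels[1, 1] <- 2L
  expect_error(taguchi_anova(d2, ref_results()), "balanced")
})

test_that("fit_linear_model agrees with the normal-equations oracle", {
  X <- phys_settings()
  y <- published_conversions
  fit <- fit_linear_model(map_levels(build_l9()), ref_results())
  expect_equal(unname(fit$coefficients), unname(ols_oracle(X, y)),
               tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-9)
  expect_true(fit$r_squared > 0 && fit$r_squared < 1)
  # balanced-design closed form for each slope
  for (j in names(X)) {
    v <- X[[j]]; vl <- sort(unique(v))
    ybar <- vapply(vl, function(l) mean(y[v == l]), numeric(1))
    slope <- sum(3 * (vl - mean(v)) * (ybar - mean(y))) /
      sum(3 * (vl - mean(v))^2)
    expect_equal(unname(fit$coefficients[j]), slope,
                 info = j, tolerance = 1e-10)
  }
})

test_that("fit_linear_model guards rank and size", {
  X <- map_levels(build_l9())
  const <- ref_results(); const$conversion_mean <- 42
  fitc <- fit_linear_model(X, const)
  expect_equal(unname(fitc$coefficients),
               c(42, 0, 0, 0, 0), tolerance = 1e-9)
  Xdup <- X; Xdup$Cat <- Xdup$MR * 2
  expect_error(fit_linear_model(Xdup, ref_results()), "rank deficient")
  expect_error(fit_linear_model(X[1:3, ], ref_results()[1:3, ]),
               "at least")
})

test_that("noiseless synthetic data is recovered exactly", {
  cfg <- generator_config(beta0 = 90, beta = c(MR = -2, Cat = 0.5,
                                               BL = -0.1, t = 0.02),
                          sigma = 0, rep_sd = 0, seed = 7)
  ex <- generate_experiment(cfg)
  fit <- fit_linear_model(map_levels(build_l9()), ex$results)
  expect_equal(unname(fit$coefficients), c(90, -2, 0.5, -0.1, 0.02),
               tolerance = 1e-8)
  # zero-slope factors get zero SS in the ANOVA
  cfg0 <- generator_config(beta0 = 80, beta = c(MR = -3, Cat = 0, BL = 0,
                                                t = 0),
                           sigma = 0, rep_sd = 0, seed = 7)
  an <- taguchi_anova(build_l9(), generate_experiment(cfg0)$results)
  ss <- an$table$ss[match(c("Cat", "BL", "t"), an$table$term)]
  expect_equal(ss, rep(0, 3), tolerance = 1e-16)
})

test_that("predict_conversion evaluates, clamps and warns", {
  cfg <- generator_config(sigma = 0, rep_sd = 0)   # published coefficients
  fit <- fit_linear_model(map_levels(build_l9()),
                          generate_experiment(cfg)$results)
  p <- predict_conversion(fit, c(MR = 5, Cat = 10, BL = 20, t = 48))
  expect_equal(as.numeric(p), 83.16, tolerance = 1e-6)
  expect_false(attr(p, "clamped"))
  hi <- suppressWarnings(
    predict_conversion(fit, c(MR = 1, Cat = 5, BL = 20, t = 300)))
  expect_true(attr(hi, "clamped"))
  expect_equal(as.numeric(hi), 100)
  expect_warning(predict_conversion(fit, c(MR = 0.5, Cat = 10, BL = 20,
                                           t = 48)), "extrapolating")
  expect_error(predict_conversion(fit, c(MR = 5, Cat = 10, BL = 20)),
               "missing factor")
})

test_that("contour_grid equals pointwise predictions", {
  cfg <- generator_config(sigma = 0, rep_sd = 0)
  fit <- fit_linear_model(map_levels(build_l9()),
                          generate_experiment(cfg)$results)
  cg <- contour_grid(fit, "BL", "Cat", fixed = c(MR = 5, t = 48),
                     resolution = 2)
  expect_equal(dim(cg$grid), c(2, 2))
  for (i in 1:2) for (j in 1:2)
    expect_equal(cg$grid[i, j], as.numeric(predict_conversion(
      fit, c(BL = cg$x_values[i], Cat = cg$y_values[j], MR = 5, t = 48))))
  # monotone decreasing along BL (negative slope)
  cg3 <- contour_grid(fit, "BL", "Cat", fixed = c(MR = 5, t = 48),
                      resolution = 3)
  expect_equal(length(cg3$grid), 9)
  expect_true(all(diff(cg3$grid[, 1]) < 0))
  expect_error(contour_grid(fit, "BL", "BL", fixed = c(MR = 5, t = 48)),
               "differ")
  expect_error(contour_grid(fit, "ZZ", "Cat", fixed = c(MR = 5, t = 48)),
               "unknown factor")
  out <- withr::local_tempfile(fileext = ".tsv")
  df <- write_contour_tsv(cg, out)
  back <- utils::read.delim(out)
  expect_equal(back$predicted_conversion_pct, df$predicted_conversion_pct)
})

test_that("parity_data pairs observed with predicted per run", {
  X <- map_levels(build_l9())
  fit <- fit_linear_model(X, ref_results())
  par <- parity_data(fit, X, ref_results())
  expect_equal(nrow(par), 9)
  expect_equal(par$run, 1:9)
  expect_equal(sum(par$residual), 0, tolerance = 1e-9)
  expect_equal(attr(par, "max_abs_residual"), max(abs(par$residual)))
  # noiseless synthetic data sits on the diagonal
  cfg <- generator_config(sigma = 0, rep_sd = 0)
  ex <- generate_experiment(cfg)
  fit0 <- fit_linear_model(X, ex$results)
  par0 <- parity_data(fit0, X, ex$results)
  expect_lt(attr(par0, "max_abs_residual"), 1e-10)
  expect_error(parity_data(fit, X, published_conversions[1:5]),
               "do not match")
})
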