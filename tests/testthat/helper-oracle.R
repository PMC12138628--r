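# Shared fixtures and independent oracles.

# Run-mean conversions and printed S/N column of the published L9 experiment.
published_conversions <- c(89.1, 86.0, 68.9, 81.0, 73.6, 78.6, 53.3, 82.0,
                           63.6)
published_sn <- c(38.99, 38.69, 36.76, 38.17, 37.33, 37.90, 34.53, 38.27,
                  36.07)
# Published response table (display values), rows L1..L3, and deltas/ranks.
published_level_means <- matrix(
  c(38.15, 37.81, 36.29,
    37.23, 38.10, 36.91,
    38.39, 37.65, 36.21,
    37.47, 37.05, 37.74), nrow = 3,
  dimnames = list(paste0("L", 1:3), c("MR", "Cat", "BL", "t")))
published_delta <- c(MR = 1.86, Cat = 1.19, BL = 2.18, t = 0.69)
published_rank <- c(MR = 2, Cat = 3, BL = 1, t = 4)
# Published additive model: X = 100.7 - 1.878 MR - 0.409 Cat - 0.299 BL
# + 0.04 t.
published_coef <- c(`(Intercept)` = 100.7, MR = -1.878, Cat = -0.409,
                    BL = -0.299, t = 0.04)

ref_results <- function() {
  data.frame(run = 1:9, n = 1L, conversion_mean = published_conversions,
             conversion_sd = c(.1, .1, .1, .6, .3, .6, .2, .5, .6))
}

# Brute-force normal-equations OLS, independent of fit_linear_model().
ols_oracle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  drop(solve(t(X) %*% X, t(X) %*% y))
}

phys_settings <- function() map_levels(build_l9())[, -1]
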