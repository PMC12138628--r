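#' Taguchi ANOVA with factor pooling and percentage contributions
#'
#' Decomposes the between-run variability of a balanced 3-level orthogonal
#' design into per-factor sums of squares,
#' \deqn{SS_j = r \sum_{l=1}^{3} (\bar{y}_{jl} - \bar{y})^2,}
#' with \eqn{r} runs per level (3 for the L9). The design is saturated
#' (error DF = 0), so the weakest factor(s) are pooled into an error term
#' until the error has at least 2 DF; F ratios, upper-tail p-values from
#' \eqn{F(2, DF_{err})}, and contributions (factor SS as % of the non-pooled
#' SS sum) are then reported.
#'
#' @param design An `l9_design` passing [validate_orthogonality()].
#' @param responses Numeric vector of per-run responses (conversion %), one
#'   per run in run order, or a data.frame with `run` and `conversion_mean`.
#' @param pool `"auto"` (pool smallest-SS factors until error DF >= 2,
#'   default) or a character vector of factor names to pool.
#' @return A `taguchi_anova` object: list with `table` (data.frame
#'   `term, df, ss, ms, f, p, contribution, pooled` plus `error` and
#'   `total` rows), `ss_total`, `degenerate`.
#' @export
taguchi_anova <- function(design, responses, pool = "auto") {
  stopifnot(inherits(design, "l9_design"))
  if (!validate_orthogonality(design)$pass)
    stop("design is not a balanced orthogonal array", call. = FALSE)
  y <- resolve_responses(design, responses)
  lv <- design$levels
  k <- ncol(lv); n <- nrow(lv); r <- n / 3
  gm <- mean(y)
  ss <- vapply(seq_len(k), function(j) {
    lm_ <- vapply(1:3, function(l) mean(y[lv[, j] == l]), numeric(1))
    r * sum((lm_ - gm)^2)
  }, numeric(1))
  names(ss) <- colnames(lv)
  ss_total <- sum((y - gm)^2)
  degenerate <- ss_total < .Machine$double.eps * n

  if (identical(pool, "auto")) {
    pooled <- character(0)
    ord <- names(sort(ss))
    while (2L * length(pooled) < 2L) pooled <- c(pooled, ord[length(pooled) + 1L])
  } else {
    pooled <- pool
    if (!all(pooled %in% names(ss)))
      stop("unknown factor(s) in 'pool': ",
           paste(setdiff(pooled, names(ss)), collapse = ", "), call. = FALSE)
  }
  if (length(pooled) >= k)
    stop("cannot pool every factor", call. = FALSE)

  df_fac <- 2L
  df_err <- df_fac * length(pooled)
  ss_err <- sum(ss[pooled])
  ms_err <- if (df_err > 0) ss_err / df_err else NA_real_
  keep <- setdiff(names(ss), pooled)
  ms <- ss / df_fac
  f <- ifelse(names(ss) %in% keep & is.finite(ms_err) & ms_err > 0,
              ms / ms_err, NA_real_)
  p <- ifelse(is.na(f), NA_real_,
              stats::pf(f, df_fac, df_err, lower.tail = FALSE))
  contrib <- rep(NA_real_, k); names(contrib) <- names(ss)
  denom <- sum(ss[keep])
  contrib[keep] <- if (degenerate || denom <= 0) 0 else ss[keep] / denom * 100

  tab <- data.frame(
    term = c(names(ss), "error", "total"),
    df = c(rep(df_fac, k), df_err, n - 1L),
    ss = c(ss, ss_err, ss_total),
    ms = c(ms, ms_err, NA_real_),
    f = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    contribution = c(contrib, NA_real_, NA_real_),
    pooled = c(names(ss) %in% pooled, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, ss_total = ss_total, degenerate = degenerate,
                 pooled = pooled),
            class = "taguchi_anova")
}

#' @export
print.taguchi_anova <- function(x, ...) {
  cat("Taguchi ANOVA (pooled:", paste(x$pooled, collapse = ", "), ")\n")
  tab <- x$table
  tab$term[tab$pooled] <- paste0("(", tab$term[tab$pooled], ")")
  print(tab[, c("term", "df", "ss", "ms", "f", "p", "contribution")],
        digits = 4, row.names = FALSE)
  if (x$degenerate) cat("note: constant responses; SS degenerate\n")
  invisible(x)
}

resolve_responses <- function(design, responses) {
  n <- nrow(design$levels)
  if (is.data.frame(responses)) {
    stopifnot(all(c("run", "conversion_mean") %in% names(responses)))
    y <- responses$conversion_mean[match(seq_len(n), responses$run)]
  } else y <- as.numeric(responses)
  if (length(y) != n || anyNA(y))
    stop("need one response per run", call. = FALSE)
  y
}

#' Fit the additive linear conversion model in physical units
#'
#' Ordinary least squares of conversion on the factor settings in their
#' physical units (e.g. molar ratio 1/5/9, catalyst 5/10/15%, blend
#' 20/50/80%, time 48/72/96 h):
#' \deqn{X = b_0 + b_A\,MR + b_B\,Cat + b_C\,BL + b_D\,t}
#'
#' @param settings data.frame of physical settings, one row per run, as from
#'   [map_levels()] (a `run` column, if present, is dropped).
#' @param responses Per-run conversions (%), vector or data.frame with
#'   `run`/`conversion_mean`.
#' @return A `conversion_lm`: list with `coefficients` (named, intercept
#'   first), `fitted`, `residuals`, `r_squared`, `ranges` (per-factor design
#'   range), `fit` (the underlying [stats::lm] object).
#' @export
fit_linear_model <- function(settings, responses) {
  stopifnot(is.data.frame(settings))
  run_col <- settings[["run"]]
  X <- settings[setdiff(names(settings), "run")]
  if (nrow(X) < ncol(X) + 1L || nrow(X) < 5L)
    stop("need at least max(5, p + 1) runs to fit the model", call. = FALSE)
  if (is.data.frame(responses)) {
    stopifnot(all(c("run", "conversion_mean") %in% names(responses)))
    key <- if (is.null(run_col)) seq_len(nrow(X)) else run_col
    y <- responses$conversion_mean[match(key, responses$run)]
  } else y <- as.numeric(responses)
  if (length(y) != nrow(X) || anyNA(y))
    stop("response length must match the number of runs", call. = FALSE)
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[-seq_len(qr_$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", names(X)), response = ".y")
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  names(cf) <- c("(Intercept)", names(X))
  ranges <- vapply(X, range, numeric(2))
  # R^2 by hand: summary.lm warns on (near-)perfect fits, which are routine
  # for noiseless synthetic data
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(coefficients = cf,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::resid(fit)),
                 r_squared = r2,
                 ranges = ranges, fit = fit),
            class = "conversion_lm")
}

#' @export
print.conversion_lm <- function(x, ...) {
  cf <- x$coefficients
  terms <- paste(sprintf("%+.4g %s", cf[-1], names(cf)[-1]), collapse = " ")
  cat(sprintf("Conversion model: X(%%) = %.4g %s\n", cf[1], terms))
  cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Predict conversion at physical factor settings
#'
#' Evaluates the fitted additive model. Settings outside the fitted design
#' range trigger an extrapolation warning; predictions are clamped to
#' \[0, 100\] with attribute `clamped` set.
#'
#' @param model A `conversion_lm`.
#' @param settings Named numeric vector or data.frame of physical settings
#'   covering every model factor.
#' @param clamp Clamp predictions into \[0, 100\] (default TRUE).
#' @return Predicted conversion(s) in %, attribute `clamped`.
#' @export
predict_conversion <- function(model, settings, clamp = TRUE) {
  stopifnot(inherits(model, "conversion_lm"))
  nms <- names(model$coefficients)[-1]
  if (is.data.frame(settings)) {
    miss <- setdiff(nms, names(settings))
    if (length(miss)) stop("missing factor(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    S <- as.matrix(settings[nms])
  } else {
    miss <- setdiff(nms, names(settings))
    if (length(miss)) stop("missing factor(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    S <- matrix(settings[nms], nrow = 1, dimnames = list(NULL, nms))
  }
  out_of_range <- FALSE
  for (j in nms) {
    rg <- model$ranges[, j]
    if (any(S[, j] < rg[1] | S[, j] > rg[2])) out_of_range <- TRUE
  }
  if (out_of_range)
    warning("settings outside the fitted design range: extrapolating",
            call. = FALSE)
  pred <- drop(cbind(1, S) %*% model$coefficients)
  clamped <- FALSE
  if (clamp) {
    clamped <- any(pred < 0 | pred > 100)
    pred <- pmin(pmax(pred, 0), 100)
  }
  attr(pred, "clamped") <- clamped
  pred
}

#' Prediction grid over two factors (contour data)
#'
#' Rectangular grid of model predictions over the design range of two
#' factors, the other factors held at fixed settings — the data behind the
#' usual two-factor contour surface.
#'
#' @param model A `conversion_lm`.
#' @param x,y Factor names for the grid axes (distinct).
#' @param fixed Named numeric vector of settings for the remaining factors.
#' @param resolution Grid points per axis (>= 2, default 25).
#' @return A `contour_grid`: list with `x`, `y`, `x_values`, `y_values`,
#'   `grid` (matrix, rows = x, cols = y), `fixed`.
#' @export
contour_grid <- function(model, x, y, fixed, resolution = 25) {
  stopifnot(inherits(model, "conversion_lm"), resolution >= 2)
  nms <- names(model$coefficients)[-1]
  if (!x %in% nms || !y %in% nms) stop("unknown factor name", call. = FALSE)
  if (identical(x, y)) stop("x and y must differ", call. = FALSE)
  others <- setdiff(nms, c(x, y))
  miss <- setdiff(others, names(fixed))
  if (length(miss)) stop("fixed settings required for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  xs <- seq(model$ranges[1, x], model$ranges[2, x], length.out = resolution)
  ys <- seq(model$ranges[1, y], model$ranges[2, y], length.out = resolution)
  g <- outer(xs, ys, function(a, b) {
    df <- data.frame(a, b)
    names(df) <- c(x, y)
    for (f in others) df[[f]] <- fixed[[f]]
    as.numeric(suppressWarnings(predict_conversion(model, df)))
  })
  structure(list(x = x, y = y, x_values = xs, y_values = ys, grid = g,
                 fixed = fixed[others]),
            class = "contour_grid")
}

#' Write a contour grid as tab-separated long-format text
#' @param cg A `contour_grid`.
#' @param path Output path.
#' @return Invisibly, the written data.frame
#'   (`x_value, y_value, predicted_conversion_pct`).
#' @export
write_contour_tsv <- function(cg, path) {
  stopifnot(inherits(cg, "contour_grid"))
  df <- expand.grid(x_value = cg$x_values, y_value = cg$y_values,
                    KEEP.OUT.ATTRS = FALSE)
  df$predicted_conversion_pct <- as.vector(cg$grid)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Observed vs predicted pairs (parity data)
#'
#' @param model A `conversion_lm`.
#' @param settings Physical settings per run (as in [fit_linear_model()]).
#' @param responses Observed conversions per run.
#' @return data.frame `run, observed, predicted, residual` in run order,
#'   attribute `max_abs_residual`.
#' @export
parity_data <- function(model, settings, responses) {
  stopifnot(inherits(model, "conversion_lm"), is.data.frame(settings))
  run <- if ("run" %in% names(settings)) settings$run
         else seq_len(nrow(settings))
  y <- if (is.data.frame(responses))
         responses$conversion_mean[match(run, responses$run)]
       else as.numeric(responses)
  if (length(y) != nrow(settings) || anyNA(y))
    stop("responses do not match settings rows", call. = FALSE)
  pred <- as.numeric(suppressWarnings(
    predict_conversion(model, settings, clamp = FALSE)))
  out <- data.frame(run = run, observed = y, predicted = pred,
                    residual = y - pred)
  attr(out, "max_abs_residual") <- max(abs(out$residual))
  out
}
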