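#' Run the full Taguchi analysis pipeline
#'
#' Orchestrates design validation, per-run S/N ratios, the response table,
#' optimum selection (argmax and, optionally, explicit levels), pooled
#' Taguchi ANOVA, the additive linear conversion model, parity data and an
#' optional contour grid, into one self-contained report.
#'
#' @param design An `l9_design`.
#' @param results Per-run results data.frame (see [read_results()]).
#' @param explicit_levels Optional integer vector of 4 levels (1..3) to
#'   evaluate alongside the argmax optimum.
#' @param pool Pooling rule for [taguchi_anova()] (default `"auto"`).
#' @param contour Optional character vector `c(x, y)` of factor names for a
#'   contour grid.
#' @param fixed Named numeric vector of fixed settings for the non-contour
#'   factors (physical units).
#' @param resolution Contour grid resolution (default 25).
#' @return An `analysis_report` list with elements `inputs`, `sn_per_run`,
#'   `response_table`, `optimum` (argmax and explicit blocks), `anova`,
#'   `linear_model`, `parity`, `contour` (or NULL), `provenance`.
#' @export
analyze <- function(design, results, explicit_levels = NULL, pool = "auto",
                    contour = NULL, fixed = NULL, resolution = 25) {
  stopifnot(inherits(design, "l9_design"))
  ortho <- validate_orthogonality(design)
  if (!ortho$pass)
    stop("design failed orthogonality validation", call. = FALSE)
  phys <- map_levels(design)
  snt <- sn_table(design, results)
  rt <- response_table(design, snt)
  opt_argmax <- predict_optimum(rt, select_optimum(rt, "argmax"))
  opt_explicit <- if (!is.null(explicit_levels))
    predict_optimum(rt, select_optimum(rt, "explicit",
                                       levels = explicit_levels))
  an <- taguchi_anova(design, results, pool = pool)
  fit <- fit_linear_model(phys, results)
  par <- parity_data(fit, phys, results)
  model_opt <- NULL
  if (!is.null(opt_explicit)) {
    nm <- colnames(design$levels)
    setting <- vapply(seq_along(nm), function(j)
      design$factors[[j]]$levels[opt_explicit$levels[j]], numeric(1))
    names(setting) <- nm
    model_opt <- as.numeric(predict_conversion(fit, setting))
  }
  cg <- NULL
  if (!is.null(contour)) {
    stopifnot(length(contour) == 2L)
    cg <- contour_grid(fit, contour[1], contour[2], fixed, resolution)
  }
  structure(list(
    inputs = list(design = map_levels(design),
                  levels = design$levels,
                  factors = lapply(design$factors, unclass),
                  results = results),
    sn_per_run = snt,
    response_table = list(level_means = rt$levels,
                          level_means_display = rt$display,
                          delta = rt$delta, rank = rt$rank,
                          grand_mean = rt$grand_mean),
    optimum = list(argmax = opt_argmax, explicit = opt_explicit,
                   explicit_model_prediction = model_opt),
    anova = list(table = an$table, ss_total = an$ss_total,
                 pooled = an$pooled, degenerate = an$degenerate),
    linear_model = list(coefficients = as.list(fit$coefficients),
                        r_squared = fit$r_squared,
                        residuals = fit$residuals),
    parity = par,
    contour = if (!is.null(cg)) list(x = cg$x, y = cg$y,
                                     x_values = cg$x_values,
                                     y_values = cg$y_values,
                                     grid = cg$grid, fixed = cg$fixed),
    provenance = list(
      package = "enzopt",
      version = as.character(utils::packageVersion("enzopt")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      conventions = paste("S/N computed at full precision;",
                          "response-table display: half-up rounding, 2",
                          "decimals; delta/ranking from displayed means"))),
    class = "analysis_report")
}

#' Write an analysis report as JSON
#' @param report An `analysis_report` from [analyze()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, unclass_deep))
  if (is.matrix(x)) return(x)
  unclass(x)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("enzopt analysis report\n")
  cat(sprintf("  runs: %d, grand mean S/N: %.3f dB\n",
              nrow(x$sn_per_run), x$response_table$grand_mean))
  cat("  factor ranking:",
      paste(names(sort(x$response_table$rank)), collapse = " > "), "\n")
  oa <- x$optimum$argmax
  cat(sprintf("  argmax optimum: %s -> %.2f dB (%.1f%%%s)\n",
              paste(names(oa$levels), paste0("L", oa$levels),
                    collapse = ", ", sep = "="),
              oa$sn_db, oa$conversion_pct,
              if (oa$capped) ", capped" else ""))
  cat(sprintf("  model R^2: %.3f\n", x$linear_model$r_squared))
  invisible(x)
}
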