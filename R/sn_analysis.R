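#' Larger-is-better signal-to-noise ratio
#'
#' Taguchi's quality statistic for responses to be maximized:
#' \deqn{S/N = -10 \log_{10}\left(\frac{1}{n}\sum_i 1/y_i^2\right)}
#' For a single response this reduces to \eqn{20 \log_{10}(y)}.
#'
#' @param responses Numeric vector of strictly positive responses
#'   (conversions, %). All replicates of one run.
#' @return S/N ratio in dB (single number).
#' @examples
#' sn_larger_is_better(86.0)   # 38.6900 dB
#' sn_larger_is_better(100)    # 40 dB exactly
#' @export
sn_larger_is_better <- function(responses) {
  y <- as.numeric(responses)
  if (length(y) < 1L || anyNA(y))
    stop("need at least one non-missing response", call. = FALSE)
  if (any(y <= 0))
    stop("S/N (larger-is-better) requires strictly positive responses",
         call. = FALSE)
  -10 * log10(mean(1 / y^2))
}

#' Truncate toward zero at a fixed number of decimals
#' @param x Numeric vector.
#' @param digits Number of decimals (default 2).
#' @return Truncated values.
#' @export
trunc_dec <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p + sign(x) * 1e-9) / p
}

#' Round half away from zero at a fixed number of decimals
#'
#' Ordinary "school" rounding (0.005 -> 0.01), unlike [round()]'s
#' round-half-even.
#' @param x Numeric vector.
#' @param digits Number of decimals (default 2).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-run S/N table
#'
#' Computes the larger-is-better S/N ratio of each run from its mean
#' conversion (n = 1 per run: replicate-level values are folded into the
#' mean first, matching how published Taguchi tables are computed from the
#' reported run means). Full precision is kept; use [trunc_dec()] /
#' [round_half_up()] only for display.
#'
#' @param design An `l9_design`.
#' @param results data.frame with columns `run` and `conversion_mean` (as
#'   produced by [aggregate_runs()] or [read_results()]).
#' @return data.frame `run, conversion_mean, sn` in run order.
#' @export
sn_table <- function(design, results) {
  stopifnot(inherits(design, "l9_design"), is.data.frame(results),
            all(c("run", "conversion_mean") %in% names(results)))
  n_runs <- nrow(design$levels)
  idx <- match(seq_len(n_runs), results$run)
  if (anyNA(idx))
    stop("missing result for run(s): ",
         paste(which(is.na(idx)), collapse = ", "), call. = FALSE)
  y <- results$conversion_mean[idx]
  data.frame(run = seq_len(n_runs), conversion_mean = y,
             sn = vapply(y, sn_larger_is_better, numeric(1)))
}

#' Per-factor S/N response table with delta ranking
#'
#' For each factor, the mean S/N over the runs at each of its three levels;
#' delta is the range of the (2-decimal, half-up rounded) level means, and
#' factors are ranked by descending delta (1 = most influential, ties broken
#' by column order). Level means are kept at full precision in `levels`;
#' `display` holds the rounded values the delta and ranking are computed
#' from, the convention used in published response tables.
#'
#' @param design An `l9_design` passing [validate_orthogonality()].
#' @param sn data.frame from [sn_table()] (columns `run`, `sn`).
#' @return An `sn_response` object: list with `levels` (3 x k full-precision
#'   matrix, rows L1..L3), `display`, `delta`, `delta_full`, `rank`,
#'   `grand_mean`, `factors`.
#' @export
response_table <- function(design, sn) {
  stopifnot(inherits(design, "l9_design"))
  rep_ok <- validate_orthogonality(design)
  if (!rep_ok$pass)
    stop("design is not a balanced orthogonal array; response table ",
         "requires balance", call. = FALSE)
  stopifnot(is.data.frame(sn), all(c("run", "sn") %in% names(sn)))
  s <- sn$sn[match(seq_len(nrow(design$levels)), sn$run)]
  if (anyNA(s)) stop("missing S/N entries", call. = FALSE)
  k <- ncol(design$levels)
  lm_full <- vapply(seq_len(k), function(j)
    vapply(1:3, function(l) mean(s[design$levels[, j] == l]), numeric(1)),
    numeric(3))
  colnames(lm_full) <- colnames(design$levels)
  rownames(lm_full) <- paste0("L", 1:3)
  disp <- round_half_up(lm_full, 2)
  delta <- apply(disp, 2, max) - apply(disp, 2, min)
  delta_full <- apply(lm_full, 2, max) - apply(lm_full, 2, min)
  ord <- order(-delta, seq_len(k))
  rk <- integer(k); rk[ord] <- seq_len(k); names(rk) <- colnames(lm_full)
  structure(list(levels = lm_full, display = disp, delta = delta,
                 delta_full = delta_full, rank = rk, grand_mean = mean(s),
                 factors = design$factors),
            class = "sn_response")
}

#' @export
print.sn_response <- function(x, ...) {
  tab <- rbind(x$display, Delta = x$delta, Ranking = x$rank)
  cat("Response table of mean S/N ratios (dB)\n")
  print(tab)
  cat(sprintf("Grand mean S/N: %.4f dB\n", x$grand_mean))
  invisible(x)
}

#' Choose the optimum level of each factor
#'
#' `policy = "argmax"` picks, per factor, the level with the largest mean
#' S/N (ties resolved toward the lowest level index). `policy = "explicit"`
#' accepts user-supplied levels, e.g. to reproduce a published choice that
#' deviates from the argmax.
#'
#' @param rt An `sn_response` from [response_table()].
#' @param policy `"argmax"` (default) or `"explicit"`.
#' @param levels Integer vector of levels in 1..3, one per factor (required
#'   for `"explicit"`).
#' @return Named integer vector of chosen levels.
#' @export
select_optimum <- function(rt, policy = c("argmax", "explicit"),
                           levels = NULL) {
  stopifnot(inherits(rt, "sn_response"))
  policy <- match.arg(policy)
  k <- ncol(rt$levels)
  if (policy == "argmax") {
    lv <- apply(rt$levels, 2, which.max)  # which.max -> lowest index on ties
  } else {
    if (is.null(levels) || length(levels) != k)
      stop("explicit policy needs one level per factor", call. = FALSE)
    lv <- as.integer(levels)
    if (any(lv < 1L | lv > 3L))
      stop("explicit levels must lie in 1..3", call. = FALSE)
    names(lv) <- colnames(rt$levels)
  }
  lv
}

#' Predicted S/N at a chosen factor-level combination
#'
#' Additive Taguchi prediction:
#' \deqn{\widetilde{S/N} = \bar{S}_N + \sum_j (S/N_j - \bar{S}_N)}
#' summing over the included factors at their chosen levels, where
#' \eqn{\bar{S}_N} is the grand mean S/N.
#'
#' @param rt An `sn_response`.
#' @param levels Named or positional integer vector of chosen levels
#'   (1..3), one per factor.
#' @param include Character vector of factor names to include in the sum
#'   (default: all; restrict to the significant factors if desired).
#' @return Predicted S/N in dB.
#' @export
predict_sn <- function(rt, levels, include = colnames(rt$levels)) {
  stopifnot(inherits(rt, "sn_response"))
  k <- ncol(rt$levels)
  lv <- as.integer(levels)
  if (length(lv) != k || any(lv < 1L | lv > 3L))
    stop("need one level in 1..3 per factor", call. = FALSE)
  include <- match.arg(include, colnames(rt$levels), several.ok = TRUE)
  j <- match(include, colnames(rt$levels))
  rt$grand_mean + sum(rt$levels[cbind(lv[j], j)] - rt$grand_mean)
}

#' Back-transform an S/N ratio to a conversion
#'
#' Inverse of the single-response larger-is-better statistic:
#' \eqn{y = 10^{S/N / 20}}. Values above the cap (100% by default) are
#' capped, with attribute `capped` set.
#'
#' @param sn S/N ratio in dB.
#' @param cap Upper cap for the response (default 100); `Inf` disables.
#' @return Conversion in %, with logical attribute `capped`.
#' @examples
#' sn_to_response(40)  # 100
#' @export
sn_to_response <- function(sn, cap = 100) {
  stopifnot(is.finite(sn))
  y <- 10^(sn / 20)
  capped <- y > cap
  y[capped] <- cap
  attr(y, "capped") <- any(capped)
  y
}

#' Optimum prediction record
#'
#' Combines [predict_sn()] and [sn_to_response()] into the standard
#' "predicted performance at the optimum" record.
#'
#' @inheritParams predict_sn
#' @return List with `levels`, `sn_db`, `conversion_pct`, `capped`.
#' @export
predict_optimum <- function(rt, levels, include = colnames(rt$levels)) {
  sn <- predict_sn(rt, levels, include)
  y <- sn_to_response(sn)
  lv <- as.integer(levels); names(lv) <- colnames(rt$levels)
  list(levels = lv, sn_db = sn, conversion_pct = as.numeric(y),
       capped = isTRUE(attr(y, "capped")))
}
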