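#' Acidity index (acid value) from a titration record
#'
#' The acidity index is the mass of NaOH (mg) needed to neutralize the free
#' fatty acids in one gram of sample:
#' \deqn{AI = MW_{NaOH} \cdot M_{NaOH} \cdot f \cdot V_{NaOH} / m}
#' With the titrant volume in mL the result is in mg NaOH per g sample.
#'
#' @param v_naoh_ml Titrant volume consumed (mL), >= 0.
#' @param m_g Sample mass (g), > 0.
#' @param molarity NaOH solution molarity (mol/L), > 0.
#' @param f Standardization correction factor (dimensionless), > 0
#'   (default 1).
#' @param mw_naoh Molar mass of NaOH (g/mol), > 0 (default 40.00).
#' @return Acidity index in mg NaOH / g sample. Vectorized.
#' @examples
#' acidity_index(v_naoh_ml = 5, m_g = 0.2, molarity = 0.1)  # 100 mg/g
#' @export
acidity_index <- function(v_naoh_ml, m_g, molarity, f = 1, mw_naoh = 40.00) {
  n <- max(length(v_naoh_ml), length(m_g), length(molarity), length(f),
           length(mw_naoh))
  v <- rep_len(as.numeric(v_naoh_ml), n); m <- rep_len(as.numeric(m_g), n)
  mol <- rep_len(as.numeric(molarity), n); ff <- rep_len(as.numeric(f), n)
  mw <- rep_len(as.numeric(mw_naoh), n)
  if (anyNA(c(v, m, mol, ff, mw)))
    stop("titration record contains missing values", call. = FALSE)
  if (any(m <= 0) || any(mol <= 0) || any(ff <= 0) || any(mw <= 0))
    stop("invalid measurement: mass, molarity, f and MW must be positive",
         call. = FALSE)
  if (any(v < 0))
    stop("invalid measurement: titrant volume must be non-negative",
         call. = FALSE)
  mw * mol * ff * v / m
}

#' Fatty-acid conversion from initial and final acidity
#'
#' \deqn{X(\%) = (AI_0 - AI) / AI_0 \times 100}
#' A final acidity above the initial one signals a titration inconsistency:
#' by default it raises an error; with `clamp_negative = TRUE` it is clamped
#' to 0 with a warning.
#'
#' @param ai0 Initial acidity index (mg/g), > 0.
#' @param ai Final acidity index (mg/g), >= 0.
#' @param clamp_negative Clamp negative conversions to zero instead of
#'   erroring (default FALSE).
#' @return Conversion X in percent. Vectorized.
#' @examples
#' conversion(2.0, 0.144)  # 92.8
#' @export
conversion <- function(ai0, ai, clamp_negative = FALSE) {
  n <- max(length(ai0), length(ai))
  ai0 <- rep_len(as.numeric(ai0), n); ai <- rep_len(as.numeric(ai), n)
  if (anyNA(ai0) || anyNA(ai)) stop("missing acidity values", call. = FALSE)
  if (any(ai0 <= 0))
    stop("initial acidity index must be positive", call. = FALSE)
  if (any(ai < 0))
    stop("final acidity index must be non-negative", call. = FALSE)
  x <- (ai0 - ai) / ai0 * 100
  if (any(x < 0)) {
    if (!clamp_negative)
      stop("negative conversion (final acidity exceeds initial): ",
           "titration inconsistency", call. = FALSE)
    warning("negative conversion(s) clamped to 0", call. = FALSE)
    x[x < 0] <- 0
  }
  x
}

#' Aggregate replicate conversions into a run result
#'
#' @param conversions Numeric vector of replicate conversions (%), length
#'   >= 1.
#' @param run Optional run id stored in the result.
#' @return A `run_result`: list with `run`, `replicates`, `n`, `mean`, `sd`
#'   (sample standard deviation, n-1 denominator; 0 for a single replicate).
#' @examples
#' aggregate_replicates(c(89.0, 89.1, 89.2))  # mean 89.1, sd 0.1
#' @export
aggregate_replicates <- function(conversions, run = NA_integer_) {
  conversions <- as.numeric(conversions)
  if (length(conversions) < 1L || anyNA(conversions))
    stop("need at least one non-missing replicate", call. = FALSE)
  s <- if (length(conversions) > 1L) stats::sd(conversions) else 0
  structure(list(run = run, replicates = conversions,
                 n = length(conversions),
                 mean = mean(conversions), sd = s),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Run %s: %.2f %% (sd %.2f, n = %d)\n",
              as.character(x$run), x$mean, x$sd, x$n))
  invisible(x)
}

#' Summarize long-format replicate conversions by run
#'
#' @param df data.frame with columns `run`, `conversion_pct` (and optionally
#'   `replicate`).
#' @return data.frame `run, n, conversion_mean, conversion_sd` ordered by
#'   run.
#' @export
aggregate_runs <- function(df) {
  stopifnot(is.data.frame(df), all(c("run", "conversion_pct") %in% names(df)))
  runs <- sort(unique(df$run))
  out <- do.call(rbind, lapply(runs, function(r) {
    a <- aggregate_replicates(df$conversion_pct[df$run == r], run = r)
    data.frame(run = r, n = a$n, conversion_mean = a$mean,
               conversion_sd = a$sd)
  }))
  rownames(out) <- NULL
  out
}
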