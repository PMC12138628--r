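#' Configuration of the synthetic experiment generator
#'
#' Describes an additive ground truth for run-mean conversion,
#' \eqn{\mu = \beta_0 + \sum_j \beta_j v_j} (plus optional pairwise
#' interactions), with independent Gaussian run-level noise (sd `sigma`)
#' and replicate-level titration noise (sd `rep_sd`). Defaults mirror the
#' published esterification study: the fitted additive coefficients as
#' ground truth, triplicates, and a replicate sd of 0.35% (the middle of
#' the 0.1-0.6% range the study reports).
#'
#' @param beta0 Intercept (% conversion).
#' @param beta Named slopes per factor, % per physical unit.
#' @param interactions Optional named list of pairwise interaction
#'   coefficients, names like `"MR:Cat"` (% per product unit).
#' @param sigma Run-level noise sd (%), >= 0. Default 0: the study reports
#'   no between-run replication.
#' @param rep_sd Replicate-level noise sd (%), >= 0.
#' @param n_rep Replicates per run, >= 1 (default 3).
#' @param seed Integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(beta0 = 100.7,
                             beta = c(MR = -1.878, Cat = -0.409,
                                      BL = -0.299, t = 0.04),
                             interactions = NULL,
                             sigma = 0, rep_sd = 0.35, n_rep = 3,
                             seed = 1L) {
  stopifnot(is.numeric(beta0), length(beta0) == 1L,
            is.numeric(beta), !is.null(names(beta)),
            sigma >= 0, rep_sd >= 0, n_rep >= 1)
  if (!is.null(interactions)) {
    stopifnot(is.list(interactions), !is.null(names(interactions)))
    for (nm in names(interactions)) {
      pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(pr) != 2L || !all(pr %in% names(beta)))
        stop("interaction name must be '<factor>:<factor>': ", nm,
             call. = FALSE)
    }
  }
  structure(list(beta0 = beta0, beta = beta, interactions = interactions,
                 sigma = sigma, rep_sd = rep_sd, n_rep = as.integer(n_rep),
                 seed = as.integer(seed)),
            class = "generator_config")
}

true_run_means <- function(cfg, phys) {
  nms <- names(cfg$beta)
  mu <- cfg$beta0 + as.matrix(phys[nms]) %*% cfg$beta
  if (!is.null(cfg$interactions))
    for (nm in names(cfg$interactions)) {
      pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
      mu <- mu + cfg$interactions[[nm]] * phys[[pr[1]]] * phys[[pr[2]]]
    }
  drop(mu)
}

#' Generate a synthetic Taguchi experiment
#'
#' For each design run the true mean conversion follows the configured
#' additive model; true means are clamped into \[1, 100\] (keeping the
#' larger-is-better S/N defined) with clamp events recorded. Replicates are
#' `true mean + N(0, sigma^2)` (one run-level draw) `+ N(0, rep_sd^2)`
#' (per replicate), clamped the same way. Draw order is fixed — per run:
#' one run-level draw, then `n_rep` replicate draws — so a fixed seed gives
#' identical output.
#'
#' @param cfg A [generator_config()].
#' @param design An `l9_design` (default [build_l9()]).
#' @return List with `replicates` (long data.frame
#'   `run, replicate, conversion_pct`), `results` (per-run summary from
#'   [aggregate_runs()]), `truth` (config plus per-run true means), and
#'   `clamped` (runs whose true mean was clamped).
#' @export
generate_experiment <- function(cfg, design = build_l9()) {
  stopifnot(inherits(cfg, "generator_config"), inherits(design, "l9_design"))
  phys <- map_levels(design)
  mu_raw <- true_run_means(cfg, phys)
  clamped <- which(mu_raw < 1 | mu_raw > 100)
  mu <- pmin(pmax(mu_raw, 1), 100)
  n_runs <- nrow(phys)
  set.seed(cfg$seed)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run_shift <- if (cfg$sigma > 0) stats::rnorm(1, 0, cfg$sigma) else {
      stats::rnorm(1, 0, 1); 0  # keep the draw order fixed across sigma
    }
    reps <- mu[i] + run_shift +
      if (cfg$rep_sd > 0) stats::rnorm(cfg$n_rep, 0, cfg$rep_sd)
      else { stats::rnorm(cfg$n_rep, 0, 1); rep(0, cfg$n_rep) }
    reps <- pmin(pmax(reps, 1), 100)
    rows[[i]] <- data.frame(run = i, replicate = seq_len(cfg$n_rep),
                            conversion_pct = reps)
  }
  replicates <- do.call(rbind, rows)
  truth <- list(beta0 = cfg$beta0, beta = cfg$beta,
                interactions = cfg$interactions, sigma = cfg$sigma,
                rep_sd = cfg$rep_sd, run_means = mu, seed = cfg$seed)
  list(replicates = replicates, results = aggregate_runs(replicates),
       truth = truth, clamped = clamped)
}

#' Generate titration records realizing target conversions
#'
#' Inverts the acidity-index and conversion formulas: for each target
#' conversion an initial/final pair of titration records is emitted whose
#' volumes reproduce the target exactly (before optional volumetric noise),
#' so the titration pipeline can be exercised end-to-end.
#'
#' @param targets Target conversions (%), each in \[0, 100\]; element i is
#'   run i.
#' @param ai0 Initial acidity index (mg NaOH/g), > 0.
#' @param n_rep Replicates per run (default 3).
#' @param v_sd Gaussian sd of volumetric noise on the final titrant volume
#'   (mL), default 0.
#' @param mw_naoh,molarity,f,m_g Titration constants (see
#'   [acidity_index()]).
#' @param seed RNG seed used when `v_sd > 0`.
#' @return data.frame with columns
#'   `run, replicate, mw_naoh, molarity, f, v_naoh_ml, m_g, stage`
#'   (`stage` in `initial`/`final`).
#' @export
generate_titration_series <- function(targets, ai0, n_rep = 3, v_sd = 0,
                                      mw_naoh = 40.00, molarity = 0.1,
                                      f = 1, m_g = 0.2, seed = 1L) {
  targets <- as.numeric(targets)
  if (any(targets < 0 | targets > 100) || anyNA(targets))
    stop("targets must lie in [0, 100]", call. = FALSE)
  stopifnot(ai0 > 0, n_rep >= 1, v_sd >= 0)
  k <- mw_naoh * molarity * f / m_g     # AI per mL of titrant
  v0 <- ai0 / k
  if (v_sd > 0) set.seed(as.integer(seed))
  rows <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    ai_final <- ai0 * (1 - targets[i] / 100)
    vf <- rep(ai_final / k, n_rep)
    if (v_sd > 0) vf <- pmax(vf + stats::rnorm(n_rep, 0, v_sd), 0)
    rows[[i]] <- data.frame(
      run = i, replicate = rep(seq_len(n_rep), 2L),
      mw_naoh = mw_naoh, molarity = molarity, f = f,
      v_naoh_ml = c(rep(v0, n_rep), vf), m_g = m_g,
      stage = rep(c("initial", "final"), each = n_rep))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery study over replicated synthetic experiments
#'
#' Repeatedly generates a synthetic experiment, runs the full analysis
#' (OLS coefficient fit plus S/N response-table argmax), and compares the
#' recovered coefficients and optimum levels against the generator's ground
#' truth. Replicate r uses seed `seed + r`, so extending `n_reps` with the
#' same base seed reproduces the earlier replicates.
#'
#' @param cfg A [generator_config()] (its own seed is ignored).
#' @param n_reps Number of replicated experiments, >= 1.
#' @param seed Base integer seed.
#' @param design An `l9_design` (default [build_l9()]).
#' @return List with `per_rep` (data.frame of recovered coefficients and a
#'   logical `opt_ok` per factor/rep), `coef_summary` (per coefficient:
#'   bias, RMSE), `opt_rate` (per-factor identification rate and `all`, the
#'   rate of fully correct optima).
#' @export
recovery_study <- function(cfg, n_reps, seed = 1L, design = build_l9()) {
  stopifnot(inherits(cfg, "generator_config"), n_reps >= 1)
  phys <- map_levels(design)
  fac_names <- names(cfg$beta)
  # noiseless reference: true optimum levels via the same analysis path
  cfg0 <- cfg; cfg0$sigma <- 0; cfg0$rep_sd <- 0; cfg0$seed <- 1L
  ref <- generate_experiment(cfg0, design)
  rt0 <- response_table(design, sn_table(design, ref$results))
  true_opt <- select_optimum(rt0)
  true_cf <- c(`(Intercept)` = cfg$beta0, cfg$beta)

  per <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- as.integer(seed + r)
    ex <- generate_experiment(cfg_r, design)
    fit <- fit_linear_model(phys, ex$results)
    rt <- response_table(design, sn_table(design, ex$results))
    opt <- select_optimum(rt)
    row <- as.list(fit$coefficients)
    names(row) <- c("b0", fac_names)
    for (fn in fac_names) row[[paste0("opt_ok_", fn)]] <- opt[fn] == true_opt[fn]
    row$opt_all <- all(opt == true_opt)
    per[[r]] <- as.data.frame(row, check.names = FALSE)
  }
  per <- do.call(rbind, per)
  per$rep <- seq_len(n_reps)

  est <- as.matrix(per[, c("b0", fac_names)])
  err <- sweep(est, 2, true_cf)
  coef_summary <- data.frame(
    coefficient = c("b0", fac_names),
    true = unname(true_cf),
    bias = colMeans(err),
    rmse = sqrt(colMeans(err^2)))
  rownames(coef_summary) <- NULL
  opt_rate <- c(vapply(fac_names,
                       function(fn) mean(per[[paste0("opt_ok_", fn)]]),
                       numeric(1)),
                all = mean(per$opt_all))
  list(per_rep = per, coef_summary = coef_summary, opt_rate = opt_rate)
}
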