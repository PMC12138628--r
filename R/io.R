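#' Read per-run conversion results from CSV
#'
#' Accepts either of two schemas: long replicate format
#' (`run,replicate,conversion_pct`) or per-run summaries
#' (`run,conversion_mean[,conversion_sd]`). Conversions must lie in
#' (0, 100] — the larger-is-better S/N is undefined at 0. Duplicate
#' run/replicate pairs and non-numeric cells are rejected with the offending
#' row named.
#'
#' @param path Path to the CSV file.
#' @return data.frame `run, n, conversion_mean, conversion_sd` ordered by
#'   run; for the long schema, the replicate values are kept in attribute
#'   `replicates`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("results file is empty: ", path, call. = FALSE)
  long <- all(c("run", "replicate", "conversion_pct") %in% names(df))
  wide <- all(c("run", "conversion_mean") %in% names(df))
  if (!long && !wide)
    stop("results file must have columns run,replicate,conversion_pct ",
         "or run,conversion_mean[,conversion_sd]", call. = FALSE)
  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s', row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    v
  }
  if (long) {
    df$run <- num_col("run"); df$replicate <- num_col("replicate")
    df$conversion_pct <- num_col("conversion_pct")
    key <- paste(df$run, df$replicate)
    if (anyDuplicated(key))
      stop("duplicate run/replicate pair at row ",
           which(duplicated(key))[1], call. = FALSE)
    check_conv(df$conversion_pct)
    out <- aggregate_runs(df)
    attr(out, "replicates") <- df
    out
  } else {
    df$run <- num_col("run")
    df$conversion_mean <- num_col("conversion_mean")
    if (anyDuplicated(df$run))
      stop("duplicate run at row ", which(duplicated(df$run))[1],
           call. = FALSE)
    check_conv(df$conversion_mean)
    sd_ <- if ("conversion_sd" %in% names(df)) num_col("conversion_sd")
           else rep(NA_real_, nrow(df))
    out <- data.frame(run = df$run, n = 1L, conversion_mean =
                        df$conversion_mean, conversion_sd = sd_)
    out[order(out$run), , drop = FALSE]
  }
}

check_conv <- function(x) {
  bad <- which(x <= 0 | x > 100)
  if (length(bad))
    stop("conversion outside (0, 100] at row ", bad[1], call. = FALSE)
  invisible(x)
}

#' Read a titration file and compute per-run conversions
#'
#' Schema: `run,replicate,mw_naoh,molarity,f,v_naoh_ml,m_g,stage` with
#' `stage` in `initial`/`final`. Each run/replicate needs one record per
#' stage; conversion is computed per replicate via [acidity_index()] and
#' [conversion()].
#'
#' @param path Path to the titration CSV.
#' @param clamp_negative Passed to [conversion()].
#' @return Long data.frame `run, replicate, conversion_pct`.
#' @export
read_titration <- function(path, clamp_negative = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run", "replicate", "mw_naoh", "molarity", "f", "v_naoh_ml",
            "m_g", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("titration file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$stage %in% c("initial", "final")))
    stop("stage must be 'initial' or 'final'", call. = FALSE)
  df$ai <- acidity_index(df$v_naoh_ml, df$m_g, df$molarity, df$f, df$mw_naoh)
  ini <- df[df$stage == "initial", ]
  fin <- df[df$stage == "final", ]
  key <- function(d) paste(d$run, d$replicate)
  if (anyDuplicated(key(ini)) || anyDuplicated(key(fin)))
    stop("duplicate run/replicate/stage record", call. = FALSE)
  idx <- match(key(fin), key(ini))
  if (anyNA(idx))
    stop("final record without matching initial record (run ",
         fin$run[which(is.na(idx))[1]], ")", call. = FALSE)
  data.frame(run = fin$run, replicate = fin$replicate,
             conversion_pct = conversion(ini$ai[idx], fin$ai,
                                         clamp_negative = clamp_negative))
}

#' Convert a titration file into a results file
#' @param infile Titration CSV (see [read_titration()]).
#' @param outfile Output CSV written with schema
#'   `run,replicate,conversion_pct`.
#' @return Invisibly, the written data.frame.
#' @export
titrate_file <- function(infile, outfile) {
  out <- read_titration(infile)
  utils::write.csv(out, outfile, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' The published L9 esterification experiment
#'
#' The reference dataset shipped with the package: the four factor
#' specifications and the nine run-mean conversions (with triplicate
#' standard deviations) of the published neem / Nile-tilapia oil
#' biolubricant optimization experiment, read from the package's
#' `extdata` CSV files.
#'
#' @return List with `factors` (list of [factor_spec]), `design`
#'   (`l9_design`), `results` (data.frame
#'   `run, n, conversion_mean, conversion_sd`).
#' @examples
#' ref <- reference_study()
#' ref$results$conversion_mean
#' @export
reference_study <- function() {
  fpath <- system.file("extdata", "l9_factors.csv", package = "enzopt",
                       mustWork = TRUE)
  rpath <- system.file("extdata", "l9_results.csv", package = "enzopt",
                       mustWork = TRUE)
  factors <- read_factor_specs(fpath)
  list(factors = factors, design = build_l9(factors),
       results = read_results(rpath))
}
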