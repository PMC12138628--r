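#' Define a three-level experimental factor
#'
#' A factor specification binds a short label and a physical unit to exactly
#' three ascending physical levels, the granularity the L9(3^4) orthogonal
#' array supports.
#'
#' @param name Short factor label (e.g. `"MR"` for the alcohol:acid molar
#'   ratio).
#' @param unit Non-empty unit string (e.g. `"mol alcohol per mol acid"`,
#'   `"%"`, `"h"`).
#' @param levels Numeric vector of exactly three strictly increasing physical
#'   values.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("Cat", "%", c(5, 10, 15))
#' @export
factor_spec <- function(name, unit, levels) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("'unit' must be a non-empty string", call. = FALSE)
  levels <- as.numeric(levels)
  if (length(levels) != 3L || anyNA(levels))
    stop("'levels' must be exactly 3 numeric values", call. = FALSE)
  if (any(diff(levels) <= 0))
    stop("'levels' must be strictly increasing", call. = FALSE)
  structure(list(name = name, unit = unit, levels = levels),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: L1=%g L2=%g L3=%g\n",
              x$name, x$unit, x$levels[1], x$levels[2], x$levels[3]))
  invisible(x)
}

#' Factor specifications of the esterification optimization study
#'
#' The four process factors optimized in the neem / Nile-tilapia oil
#' biolubricant study: alcohol:acid molar ratio (MR, the numeric value n of
#' the "1:n" notation), biocatalyst load (Cat, % of oil mass), oil blend
#' (BL, % Nile tilapia oil in the substrate) and reaction time (t, h).
#'
#' @return Named list of four [factor_spec] objects (MR, Cat, BL, t).
#' @examples
#' ester_factors()$BL
#' @export
ester_factors <- function() {
  list(
    MR  = factor_spec("MR",  "mol alcohol per mol acid", c(1, 5, 9)),
    Cat = factor_spec("Cat", "%", c(5, 10, 15)),
    BL  = factor_spec("BL",  "%", c(20, 50, 80)),
    t   = factor_spec("t",   "h", c(48, 72, 96))
  )
}

# Canonical L9(3^4) level-index matrix. Rows = runs in standard order; any
# two columns jointly contain each of the nine ordered level pairs once.
.l9_matrix <- function() {
  m <- matrix(c(
    1, 1, 1, 1,
    1, 2, 2, 2,
    1, 3, 3, 3,
    2, 1, 2, 3,
    2, 2, 3, 1,
    2, 3, 1, 2,
    3, 1, 3, 2,
    3, 2, 1, 3,
    3, 3, 2, 1), ncol = 4L, byrow = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Build the canonical L9(3^4) orthogonal array
#'
#' Returns the standard 9-run, 4-factor, 3-level orthogonal array as level
#' indices (1..3). Mapped through [ester_factors()] it reproduces the run
#' settings of the published esterification design row-for-row.
#'
#' @param factors Optional named list of four [factor_spec] objects used to
#'   label the columns; defaults to [ester_factors()].
#' @return An object of class `l9_design` with elements `levels` (9 x 4
#'   integer matrix of level indices, columns named after the factors) and
#'   `factors`.
#' @examples
#' d <- build_l9()
#' d$levels[1, ]  # run 1 sits at level 1 of every factor
#' @export
build_l9 <- function(factors = ester_factors()) {
  check_factor_list(factors)
  lv <- .l9_matrix()
  colnames(lv) <- vapply(factors, `[[`, "", "name")
  structure(list(levels = lv, factors = factors), class = "l9_design")
}

#' @export
print.l9_design <- function(x, ...) {
  cat("L9(3^4) orthogonal design, 9 runs x", ncol(x$levels), "factors\n")
  print(cbind(run = seq_len(nrow(x$levels)), x$levels))
  invisible(x)
}

check_factor_list <- function(factors, n = 4L) {
  if (!is.list(factors) || length(factors) != n ||
      !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop(sprintf("expected a list of %d factor_spec objects", n),
         call. = FALSE)
  invisible(factors)
}

#' Map a design's level indices to physical factor settings
#'
#' @param design An `l9_design` (see [build_l9()]).
#' @param factors List of [factor_spec]s, one per design column; defaults to
#'   the specs stored in the design.
#' @return A data.frame with a `run` column and one physical-value column per
#'   factor.
#' @seealso [invert_levels()] for the inverse mapping.
#' @examples
#' map_levels(build_l9())[7, ]  # run 7: MR 9, Cat 5, BL 80, t 72
#' @export
map_levels <- function(design, factors = design$factors) {
  stopifnot(inherits(design, "l9_design"))
  if (length(factors) != ncol(design$levels))
    stop("factor count does not match design column count", call. = FALSE)
  check_factor_list(factors, ncol(design$levels))
  phys <- vapply(seq_along(factors),
                 function(j) factors[[j]]$levels[design$levels[, j]],
                 numeric(nrow(design$levels)))
  colnames(phys) <- vapply(factors, `[[`, "", "name")
  data.frame(run = seq_len(nrow(design$levels)), phys,
             check.names = FALSE)
}

#' Recover level indices from physical settings
#'
#' Inverse of [map_levels()]: each physical value must be exactly one of the
#' declared levels of its factor.
#'
#' @param physical A data.frame of physical settings with one column per
#'   factor (a `run` column, if present, is ignored).
#' @param factors List of [factor_spec]s matching the factor columns by name.
#' @return Integer matrix of level indices (1..3).
#' @export
invert_levels <- function(physical, factors) {
  check_factor_list(factors, length(factors))
  nms <- vapply(factors, `[[`, "", "name")
  missing <- setdiff(nms, names(physical))
  if (length(missing))
    stop("physical table lacks factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- vapply(seq_along(factors), function(j) {
    v <- physical[[nms[j]]]
    i <- match(v, factors[[j]]$levels)
    if (anyNA(i))
      stop(sprintf("factor %s: value(s) %s not among declared levels",
                   nms[j], paste(unique(v[is.na(i)]), collapse = ", ")),
           call. = FALSE)
    as.integer(i)
  }, integer(nrow(physical)))
  colnames(idx) <- nms
  idx
}

#' Validate balance and pairwise orthogonality of a design
#'
#' Checks the two defining invariants of a 3-level orthogonal array: each
#' level index appears equally often in every column (balance), and every
#' ordered pair of levels appears exactly once per pair of columns
#' (pairwise balance). Failures are reported, not raised.
#'
#' @param design An `l9_design`, or a bare integer matrix of level indices.
#' @return An object of class `orthogonality_report`: list with `pass`
#'   (logical), `balance_violations` (factor names), `pair_violations`
#'   (character vector of offending column pairs).
#' @export
validate_orthogonality <- function(design) {
  lv <- if (inherits(design, "l9_design")) design$levels else as.matrix(design)
  if (nrow(lv) < 1L) stop("design has no runs", call. = FALSE)
  nms <- colnames(lv)
  if (is.null(nms)) nms <- paste0("F", seq_len(ncol(lv)))
  reps <- nrow(lv) / 3
  bal <- vapply(seq_len(ncol(lv)), function(j) {
    tb <- tabulate(lv[, j], nbins = 3L)
    all(tb == reps)
  }, logical(1))
  pair_bad <- character(0)
  if (ncol(lv) >= 2L) {
    pr <- nrow(lv) / 9
    for (a in seq_len(ncol(lv) - 1L)) for (b in seq((a + 1L), ncol(lv))) {
      cell <- table(factor(lv[, a], 1:3), factor(lv[, b], 1:3))
      if (!all(cell == pr))
        pair_bad <- c(pair_bad, paste(nms[a], nms[b], sep = ":"))
    }
  }
  structure(list(pass = all(bal) && length(pair_bad) == 0L,
                 balance_violations = nms[!bal],
                 pair_violations = pair_bad),
            class = "orthogonality_report")
}

#' @export
print.orthogonality_report <- function(x, ...) {
  cat("Orthogonality:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$balance_violations))
    cat("  unbalanced columns:",
        paste(x$balance_violations, collapse = ", "), "\n")
  if (length(x$pair_violations))
    cat("  unbalanced column pairs:",
        paste(x$pair_violations, collapse = ", "), "\n")
  invisible(x)
}

#' Read factor specifications from a CSV file
#'
#' Expected header: `factor,unit,level1,level2,level3`.
#'
#' @param path Path to the CSV file.
#' @return Named list of [factor_spec] objects in file order.
#' @export
read_factor_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("factor", "unit", "level1", "level2", "level3")
  if (!all(need %in% names(df)))
    stop("factor file must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i)
    factor_spec(df$factor[i], df$unit[i],
                parse_ratio(c(df$level1[i], df$level2[i], df$level3[i]))))
  names(specs) <- df$factor
  specs
}

#' Write the physical design table as CSV
#'
#' Header `run,<factor names>` with physical units per run.
#'
#' @param design An `l9_design`.
#' @param path Output path.
#' @param factors Factor specs (default: stored in design).
#' @return Invisibly, the written data.frame.
#' @export
write_design_csv <- function(design, path, factors = design$factors) {
  df <- map_levels(design, factors)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

# "1:n" molar-ratio notation -> numeric n/1; plain numbers pass through.
parse_ratio <- function(x) {
  x <- as.character(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (grepl(":", x[i], fixed = TRUE)) {
      parts <- as.numeric(strsplit(x[i], ":", fixed = TRUE)[[1]])
      if (length(parts) != 2L || anyNA(parts) || parts[1] <= 0)
        stop("cannot parse ratio value: ", x[i], call. = FALSE)
      out[i] <- parts[2] / parts[1]
    } else {
      v <- suppressWarnings(as.numeric(x[i]))
      if (is.na(v)) stop("non-numeric value: ", x[i], call. = FALSE)
      out[i] <- v
    }
  }
  out
}
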