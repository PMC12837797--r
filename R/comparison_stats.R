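#' Build the percent-error factor grid
#'
#' Aggregates long-format percent-error records into the muscle-wise factor
#' grid: one cell per muscle x specificity x linearity x speed combination
#' (mean over subjects), plus marginal means per factor level per muscle.
#'
#' @param records Data.frame with columns `subject`, `muscle`, `specificity`
#'   (`general`/`specific`), `linearity` (`linear`/`logarithmic`), `speed`
#'   (deg/s) and `percent_error`. An optional `time_of_measurement` column
#'   is carried through in the long export unchanged.
#' @return An object of class `factor_grid`: list with `cells` (data.frame
#'   of cell means), `marginals` (data.frame muscle x factor x level x mean)
#'   and `records`.
#' @export
build_factor_grid <- function(records) {
  need <- c("subject", "muscle", "specificity", "linearity", "speed",
            "percent_error")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$percent_error < 0)) stop("percent errors must be >= 0")
  full <- expand.grid(muscle = unique(records$muscle),
                      specificity = c("general", "specific"),
                      linearity = c("linear", "logarithmic"),
                      speed = unique(records$speed),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$muscle, d$specificity, d$linearity, d$speed)
  have <- unique(key(records))
  miss <- setdiff(key(full), have)
  if (length(miss) > 0)
    stop("missing factor combination(s): ", paste(miss, collapse = "; "))
  cells <- stats::aggregate(percent_error ~ muscle + specificity +
                              linearity + speed, data = records, FUN = mean)
  marg <- list()
  for (fac in c("specificity", "linearity", "speed")) {
    m <- stats::aggregate(records$percent_error,
                          by = list(muscle = records$muscle,
                                    level = as.character(records[[fac]])),
                          FUN = mean)
    marg[[fac]] <- data.frame(muscle = m$muscle, factor = fac,
                              level = m$level, percent_error = m$x,
                              stringsAsFactors = FALSE)
  }
  structure(list(cells = cells, marginals = do.call(rbind, marg),
                 records = records),
            class = "factor_grid")
}

#' @export
print.factor_grid <- function(x, ...) {
  cat("<factor_grid> marginal mean percent error by factor level:\n")
  w <- stats::reshape(x$marginals, direction = "wide",
                      idvar = c("muscle"), timevar = "level",
                      drop = "factor")
  print(w, row.names = FALSE)
  invisible(x)
}

#' Export the factor grid in long format
#'
#' Writes the per-record long table (subject, muscle, specificity,
#' linearity, speed, percent_error, and `time_of_measurement` if present) as
#' CSV, ready for any standard statistical environment (e.g. a repeated
#' measures ANOVA).
#'
#' @param grid A [build_factor_grid()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_factor_grid <- function(grid, path) {
  utils::write.csv(grid$records, path, row.names = FALSE)
  invisible(path)
}

#' Two-tailed paired t-test on per-subject means
#'
#' Pairs two models' per-subject summary values (e.g. mean impulse) and
#' tests the mean difference against zero.
#'
#' @param x,y Numeric vectors of equal length (paired by subject), n >= 2.
#' @return List with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: t statistic undefined")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = unname(ht$estimate))
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant sample: normality check undefined")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Align load curves on the percent-of-task grid
#'
#' Resamples each supplied curve to the common 101-point 0-100% task grid
#' (via [normalize_cycle_curve()]) and returns one table ready for plotting
#' or export. Curves produced by other models can be supplied as plain
#' numeric vectors read from delimited text.
#'
#' @param curves Named list of numeric vectors (load values over one cycle,
#'   any lengths >= 2; values already on the 101-point grid pass through).
#' @return Data.frame with `pct_task` (0-100) and one column per curve.
#' @export
compare_load_curves <- function(curves) {
  if (length(curves) == 0) stop("no curves supplied")
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    stop("curves must be named")
  out <- data.frame(pct_task = seq(0, 100, by = 1))
  for (nm in names(curves)) {
    y <- normalize_cycle_curve(as.numeric(curves[[nm]]))
    if (length(y) != 101) stop("internal error: resampled curve length != 101")
    out[[nm]] <- y
  }
  out
}
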