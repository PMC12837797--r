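#' Fit a muscle force-to-sEMG relationship
#'
#' Fits, by ordinary least squares, either a linear relationship
#' `F = a + b * s` or a logarithmic relationship `F = a + b * ln(s)` between
#' solved muscle force `F` (N, per side) and the concurrent sEMG envelope
#' `s`. Linear relationships typically suit the trunk extensors and
#' logarithmic ones the abdominal flexors, but both forms are fitted and
#' scored so the lower-error form can be chosen per muscle. Predicted force
#' is clamped at zero.
#'
#' @param force Solved muscle force samples, N (>= 0).
#' @param envelope Concurrent envelope samples (>= 0; strictly positive for
#'   the logarithmic form).
#' @param form `"linear"` or `"logarithmic"`.
#' @param muscle Channel label the fit belongs to (optional metadata).
#' @param speed Contraction speed of the source trials, deg/s (optional).
#' @param specificity `"specific"` (one subject's own data) or `"general"`
#'   (pooled over subjects on normalized axes; see
#'   [build_general_relationship()]).
#' @param normalization For general fits: list with `max_force` and
#'   `max_envelope` semantics (per subject, applied at prediction time).
#' @return An object of class `force_emg` with components `coefficients`
#'   (named `a`, `b`), `form`, `specificity`, `muscle`, `speed`, `rss`, `n`,
#'   `sigma`, `se` (standard errors of `a`, `b`), `fitted`, `data`.
#' @seealso [predict.force_emg()], [build_general_relationship()],
#'   [percent_error()], [select_best_relationship()]
#' @examples
#' s <- seq(0.1, 1, length.out = 50)
#' f <- 2 + 3 * s
#' fit <- fit_force_emg(f, s, form = "linear")
#' coef(fit)  # a = 2, b = 3
#' @export
fit_force_emg <- function(force, envelope, form = c("linear", "logarithmic"),
                          muscle = NA_character_, speed = NA_real_,
                          specificity = "specific", normalization = NULL) {
  form <- match.arg(form)
  ok <- is.finite(force) & is.finite(envelope)
  if (form == "logarithmic") ok <- ok & envelope > 0
  force <- force[ok]; envelope <- envelope[ok]
  if (length(force) < 3)
    stop("need at least 3 usable force-envelope samples to fit")
  x <- if (form == "linear") envelope else log(envelope)
  if (stats::var(x) == 0)
    stop("degenerate samples: envelope has zero variance")
  fit <- stats::lm.fit(cbind(a = 1, b = x), force)
  cf <- fit$coefficients
  res <- fit$residuals
  n <- length(force)
  rss <- sum(res^2)
  sigma2 <- rss / max(n - 2, 1)
  xtxi <- chol2inv(chol(crossprod(cbind(1, x))))
  se <- sqrt(pmax(diag(xtxi) * sigma2, 0))
  names(se) <- c("a", "b")
  structure(list(coefficients = cf, form = form, specificity = specificity,
                 muscle = muscle, speed = speed, rss = rss, n = n,
                 sigma = sqrt(sigma2), se = se,
                 fitted = pmax(fit$fitted.values, 0),
                 normalization = normalization,
                 data = data.frame(force = force, envelope = envelope)),
            class = "force_emg")
}

#' @export
coef.force_emg <- function(object, ...) object$coefficients

#' Predict muscle force from an envelope
#'
#' Evaluates the fitted relationship and clamps the result at zero. For the
#' logarithmic form, non-positive envelope values predict zero force. For
#' general (normalized) relationships the new subject's own maxima must be
#' supplied: the envelope is scaled by `max_envelope`, the relationship
#' evaluated on normalized axes, and the result rescaled by `max_force`.
#'
#' @param object A `force_emg` fit.
#' @param envelope Envelope values to predict at.
#' @param max_force,max_envelope Subject maxima; required for general fits.
#' @param ... Unused.
#' @return Numeric vector of predicted forces, N, clamped at zero.
#' @export
predict.force_emg <- function(object, envelope, max_force = NULL,
                              max_envelope = NULL, ...) {
  if (identical(object$specificity, "general")) {
    if (is.null(max_force) || is.null(max_envelope))
      stop("general relationship: supply the subject's max_force and max_envelope")
    if (max_envelope <= 0 || max_force <= 0)
      stop("subject maxima must be > 0")
    envelope <- envelope / max_envelope
  }
  a <- object$coefficients[["a"]]; b <- object$coefficients[["b"]]
  f <- if (object$form == "linear") a + b * envelope else {
    out <- rep(0, length(envelope))
    pos <- envelope > 0
    out[pos] <- a + b * log(envelope[pos])
    out
  }
  f <- pmax(f, 0)
  if (identical(object$specificity, "general")) f <- f * max_force
  f
}

#' @export
residuals.force_emg <- function(object, ...) {
  object$data$force - predict(object, object$data$envelope,
                              max_force = 1, max_envelope = 1)
}

#' @export
print.force_emg <- function(x, ...) {
  eq <- if (x$form == "linear") "F = a + b*s" else "F = a + b*ln(s)"
  cat(sprintf("<force_emg> %s %s fit%s%s: %s, a = %.4g, b = %.4g (n = %d)\n",
              x$specificity, x$form,
              if (is.na(x$muscle)) "" else paste0(" [", x$muscle, "]"),
              if (is.na(x$speed)) "" else sprintf(" @ %g deg/s", x$speed),
              eq, x$coefficients[["a"]], x$coefficients[["b"]], x$n))
  invisible(x)
}

#' @export
summary.force_emg <- function(object, ...) {
  structure(list(fit = object), class = "summary.force_emg")
}

#' @export
print.summary.force_emg <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  se(a) = %.4g, se(b) = %.4g, residual sd = %.4g, RSS = %.6g\n",
              f$se[["a"]], f$se[["b"]], f$sigma, f$rss))
  cat(sprintf("  force range [%.4g, %.4g] N, envelope range [%.4g, %.4g]\n",
              min(f$data$force), max(f$data$force),
              min(f$data$envelope), max(f$data$envelope)))
  invisible(x)
}

#' @export
plot.force_emg <- function(x, ...) {
  ord <- order(x$data$envelope)
  graphics::plot(x$data$envelope, x$data$force,
                 xlab = "sEMG envelope", ylab = "muscle force (N)",
                 main = sprintf("%s %s relationship",
                                ifelse(is.na(x$muscle), "", x$muscle),
                                x$form), ...)
  graphics::lines(x$data$envelope[ord],
                  predict(x, x$data$envelope[ord],
                          max_force = 1, max_envelope = 1),
                  col = "red", lwd = 2)
  invisible(x)
}

#' Build a general (pooled, normalized) relationship
#'
#' Scales each subject's calibration samples to `[0, 1]` by that subject's
#' maximum solved force and maximum envelope, pools them across subjects,
#' and fits one relationship on the normalized axes. Predictions for a new
#' subject rescale by that subject's own maxima. Subjects with a
#' non-positive maximum are excluded with a warning.
#'
#' @param sample_sets Named list (one element per subject) of data.frames
#'   with columns `force` and `envelope` for a single muscle.
#' @param form `"linear"` or `"logarithmic"`.
#' @param muscle,speed Optional metadata.
#' @return A `force_emg` object with `specificity = "general"`.
#' @export
build_general_relationship <- function(sample_sets,
                                       form = c("linear", "logarithmic"),
                                       muscle = NA_character_,
                                       speed = NA_real_) {
  form <- match.arg(form)
  if (length(sample_sets) < 2)
    stop("need samples from at least 2 subjects for a general relationship")
  pooled <- list()
  for (nm in names(sample_sets)) {
    s <- sample_sets[[nm]]
    mf <- max(s$force); me <- max(s$envelope)
    if (!is.finite(mf) || mf <= 0 || !is.finite(me) || me <= 0) {
      warning("excluding subject '", nm, "': non-positive maxima")
      next
    }
    pooled[[nm]] <- data.frame(force = s$force / mf, envelope = s$envelope / me)
  }
  if (length(pooled) == 0) stop("no subject left after exclusions")
  pooled <- do.call(rbind, pooled)
  fit_force_emg(pooled$force, pooled$envelope, form = form, muscle = muscle,
                speed = speed, specificity = "general",
                normalization = list(max_force = "per-subject",
                                     max_envelope = "per-subject"))
}

#' Percent error of a relationship on a sample set
#'
#' Mean absolute prediction error, expressed as a percentage of the maximum
#' observed force in the sample set:
#' `100 * mean(|F_pred - F_obs|) / max(F_obs)`. Normalizing by the maximum
#' (rather than per-sample observed force) avoids division blow-ups where
#' the observed force passes through zero.
#'
#' @param relationship A `force_emg` fit.
#' @param samples Data.frame with `force` and `envelope` columns.
#' @param max_force,max_envelope Subject maxima for general relationships.
#' @return Percent error (scalar >= 0).
#' @export
percent_error <- function(relationship, samples, max_force = NULL,
                          max_envelope = NULL) {
  if (nrow(samples) == 0) stop("empty sample set")
  fmax <- max(samples$force)
  if (fmax <= 0) stop("all observed forces are zero: percent error undefined")
  pred <- if (identical(relationship$specificity, "general"))
    predict(relationship, samples$envelope, max_force = max_force,
            max_envelope = max_envelope)
  else predict(relationship, samples$envelope, max_force = 1, max_envelope = 1)
  100 * mean(abs(pred - samples$force)) / fmax
}

#' Choose the relationship form with the lowest percent error
#'
#' Argmin over the `{linear, logarithmic}` error grid for one muscle,
#' regardless of statistical significance. Ties break toward the simpler
#' linear form.
#'
#' @param errors Named numeric vector or list with elements `linear` and
#'   `logarithmic` (percent errors).
#' @return `"linear"` or `"logarithmic"`.
#' @export
select_best_relationship <- function(errors) {
  errors <- unlist(errors)
  if (!all(c("linear", "logarithmic") %in% names(errors)))
    stop("error grid must contain both 'linear' and 'logarithmic'")
  if (errors[["linear"]] <= errors[["logarithmic"]]) "linear" else "logarithmic"
}
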