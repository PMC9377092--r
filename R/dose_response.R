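# Single-agent dose-response fitting: the median-effect model (the canonical
# curve for combination-index work) and a four-parameter logistic for screen
# IC50 summaries.

#' Normalize raw viability signal to vehicle
#'
#' @param raw_signal raw luminescence reading(s).
#' @param vehicle_mean mean luminescence of vehicle-control wells; must be
#'   positive.
#' @return viability fraction(s) `raw_signal / vehicle_mean`; values above 1
#'   are not clipped.
#' @export
normalize_viability <- function(raw_signal, vehicle_mean) {
  if (!is.numeric(vehicle_mean) || length(vehicle_mean) != 1L ||
      !is.finite(vehicle_mean) || vehicle_mean <= 0)
    stop("'vehicle_mean' must be a single positive number", call. = FALSE)
  raw_signal / vehicle_mean
}

#' Fit the median-effect model to a dose-response series
#'
#' The median-effect equation fa/fu = (D/Dm)^m (fa the fraction affected,
#' fu = 1 - fa) is linear in log-log coordinates: log(fa/fu) = m log D -
#' m log Dm. The fit is ordinary least squares of logit(fa) on log(dose)
#' over informative points. Replicates are pooled, not pre-averaged, to
#' preserve error degrees of freedom.
#'
#' Fractions affected are clipped to `[clip, 1 - clip]` before the logit
#' transform; points at the clip bounds (and zero-dose points) carry no
#' information about the slope and are excluded.
#'
#' @param dose doses in uM (non-negative).
#' @param viability vehicle-normalized viability fractions.
#' @param clip clipping bound for fa, default `1e-4`.
#' @return an object of class `"median_effect"` with elements `Dm`
#'   (median-effect dose, uM), `m` (slope), `r2` (coefficient of
#'   determination of the linearized fit) and `n_points`.
#' @export
#' @examples
#' D <- c(0.1, 0.5, 1, 2, 10)
#' fit <- fit_median_effect(D, 1 - D / (D + 1))
#' coef(fit)  # Dm = 1, m = 1
fit_median_effect <- function(dose, viability, clip = 1e-4) {
  if (length(dose) != length(viability))
    stop("'dose' and 'viability' must have equal length", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(viability)))
    stop("viabilities must be finite", call. = FALSE)
  fa <- 1 - viability
  keep <- dose > 0 & fa > clip & fa < 1 - clip
  if (length(unique(dose[keep])) < 2L)
    stop("need at least 2 distinct informative doses (0 < fa < 1)", call. = FALSE)
  x <- log(dose[keep])
  y <- log(fa[keep] / (1 - fa[keep]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  b0 <- unname(stats::coef(fit)[1L])
  Dm <- exp(-b0 / m)
  # direct R2 rather than summary.lm (which warns on exact fits)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  if (m <= 0)
    warning("non-positive median-effect slope: viability does not decrease with dose")
  structure(list(Dm = Dm, m = m, r2 = r2, n_points = sum(keep), fit = fit),
            class = "median_effect")
}

#' @export
print.median_effect <- function(x, ...) {
  cat(sprintf("Median-effect fit: Dm = %.6g uM, m = %.4g (r2 = %.4f, n = %d)\n",
              x$Dm, x$m, x$r2, x$n_points))
  invisible(x)
}

#' @export
coef.median_effect <- function(object, ...) {
  c(Dm = object$Dm, m = object$m)
}

#' Predicted viability from a median-effect curve
#'
#' @param object a `"median_effect"` fit.
#' @param dose doses in uM at which to predict; zero dose gives viability 1.
#' @param ... unused.
#' @return predicted viability fractions.
#' @export
predict.median_effect <- function(object, dose, ...) {
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  r <- (dose / object$Dm)^object$m
  1 / (1 + r)
}

#' @export
plot.median_effect <- function(x, dose = NULL, viability = NULL, ...) {
  dd <- exp(seq(log(x$Dm) - 4, log(x$Dm) + 4, length.out = 200))
  graphics::plot(dd, predict(x, dd), type = "l", log = "x",
                 xlab = "dose (uM)", ylab = "viability", ylim = c(0, 1), ...)
  if (!is.null(dose) && !is.null(viability))
    graphics::points(dose, viability)
  invisible(x)
}

#' Inhibitory concentration ICx from a median-effect curve
#'
#' Closed form of the median-effect equation: ICx = Dm (x / (100 - x))^(1/m).
#' By convention IC0 is 0 uM (no measurable inhibition, drug absent).
#'
#' @param curve a `"median_effect"` fit (or any list with `Dm` and `m`).
#' @param x_percent percent inhibition, in `[0, 100)`; vectorized.
#' @return dose(s) in uM.
#' @export
#' @examples
#' cv <- list(Dm = 1, m = 1)
#' inhibitory_concentration(cv, 90)  # 9
inhibitory_concentration <- function(curve, x_percent) {
  if (any(!is.finite(x_percent)) || any(x_percent < 0) || any(x_percent >= 100))
    stop("'x_percent' must lie in [0, 100)", call. = FALSE)
  out <- curve$Dm * (x_percent / (100 - x_percent))^(1 / curve$m)
  out[x_percent == 0] <- 0
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares of
#' v = bottom + (top - bottom) / (1 + (D / IC50)^hill), with bounds
#' 0 <= bottom <= top <= 1.5. Provided for parity with conventional screen
#' IC50 reporting; the median-effect fit is the canonical curve for
#' combination-index work.
#'
#' @param dose doses in uM; at least 4 distinct values.
#' @param viability vehicle-normalized viability fractions.
#' @return an object of class `"logistic4"` with elements `top`, `bottom`,
#'   `ic50`, `hill` and the underlying `nls` fit.
#' @export
fit_four_param_logistic <- function(dose, viability) {
  if (length(dose) != length(viability))
    stop("'dose' and 'viability' must have equal length", call. = FALSE)
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct doses", call. = FALSE)
  rising <- suppressWarnings(stats::cor(dose, viability, method = "spearman")) > 0
  if (isTRUE(rising))
    warning("viability increases with dose; the fitted hill slope direction may be unreliable")
  pos <- dose[dose > 0]
  ll4 <- function(par) {
    par["bottom"] + (par["top"] - par["bottom"]) /
      (1 + (dose / exp(par["lic50"]))^par["hill"])
  }
  start <- c(top = min(max(viability), 1.5), bottom = max(min(viability), 0),
             lic50 = stats::median(log(pos)),
             hill = if (isTRUE(rising)) -1 else 1)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = function(par) viability - ll4(par),
      lower = c(top = 0, bottom = 0, lic50 = min(log(pos)) - 10, hill = -20),
      upper = c(top = 1.5, bottom = 1.5, lic50 = max(log(pos)) + 10, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error") || fit$info %in% c(0L, 5L)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    err <- simpleError(paste0("4PL fit did not converge: ", msg))
    err$residuals <- if (inherits(fit, "error"))
      viability - stats::median(viability) else fit$fvec
    stop(err)
  }
  cf <- fit$par
  if (cf[["bottom"]] > cf[["top"]])
    warning("fitted bottom exceeds top; curve is effectively increasing")
  structure(list(top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
                 ic50 = unname(exp(cf[["lic50"]])), hill = unname(cf[["hill"]]),
                 fitted = unname(ll4(cf)), residuals = unname(fit$fvec),
                 fit = fit),
            class = "logistic4")
}

#' @export
print.logistic4 <- function(x, ...) {
  cat(sprintf("4PL fit: top = %.4g, bottom = %.4g, IC50 = %.6g uM, hill = %.4g\n",
              x$top, x$bottom, x$ic50, x$hill))
  invisible(x)
}

#' @export
coef.logistic4 <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, ic50 = object$ic50,
    hill = object$hill)
}

#' Log-spaced default dose ladder
#'
#' Half-decade steps spanning 0.0001 uM to 100 uM, the range conventionally
#' used for serial dose-response assays.
#'
#' @param from,to range endpoints in uM.
#' @param n number of doses.
#' @return numeric vector of doses.
#' @export
dose_ladder <- function(from = 1e-4, to = 100, n = 13L) {
  10^seq(log10(from), log10(to), length.out = n)
}
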