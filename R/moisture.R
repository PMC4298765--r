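# Soil-moisture response of heterotrophic respiration: derived from daily
# soil respiration by removing a constant root component and the Q10
# temperature signal, then fitting a log-normal curve in ln(SWC) and
# normalizing it so the optimum equals one.

#' Construct a soil-moisture response
#'
#' The response is Gaussian in ln(SWC):
#' `f(w) = r_opt * exp(-0.5 * ((ln w - ln w_opt) / s)^2)`,
#' unimodal with its optimum at `w_opt`. After [normalize_response()] the
#' amplitude is one and the curve acts as a multiplier on heterotrophic
#' respiration.
#'
#' @param w_opt SWC at the optimum (m3 m-3).
#' @param s Spread in log-SWC (dimensionless).
#' @param r_opt Amplitude at the optimum (g C m-2 d-1 before
#'   normalization).
#' @param normalized Whether the amplitude has been scaled to one.
#' @param rss Residual sum of squares of the fit, if fitted.
#' @return An object of class `moisture_response`.
#' @export
moisture_response <- function(w_opt, s, r_opt = 1, normalized = FALSE,
                              rss = NA_real_) {
  stopifnot(is.finite(w_opt), w_opt > 0, is.finite(s), s > 0, is.finite(r_opt))
  structure(list(w_opt = w_opt, s = s, r_opt = r_opt,
                 normalized = normalized, rss = rss),
            class = "moisture_response")
}

#' Evaluate a moisture response at given soil water contents
#'
#' @param resp A [moisture_response()].
#' @param swc Soil water content values (m3 m-3), all > 0.
#' @return Numeric vector; in (0, r_opt], equal to `r_opt` at `w_opt`.
#' @export
moisture_factor <- function(resp, swc) {
  if (any(swc <= 0)) stop("swc must be > 0")
  resp$r_opt * exp(-0.5 * ((log(swc) - log(resp$w_opt)) / resp$s)^2)
}

#' @export
print.moisture_response <- function(x, ...) {
  cat(sprintf("moisture_response: w_opt = %.4f m3 m-3, s = %.3f, r_opt = %.3f%s\n",
              x$w_opt, x$s, x$r_opt,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Remove the root component from total soil respiration
#'
#' Root respiration is treated as a constant; the remainder is the
#' heterotrophic component. Negative remainders are clamped at zero (a
#' respiration flux cannot be negative) and counted.
#'
#' @param series Data frame with at least `rs_gc_m2_d`; other columns pass
#'   through.
#' @param root_const Constant root respiration (g C m-2 d-1); the site value
#'   is 1.9 +/- 0.3. Alternatively `"half-mean"` uses `mean(rs)/2`, the
#'   estimator the constant derives from.
#' @return The series with a `het_gc_m2_d` column; attribute `n_clamped`
#'   reports clamped days and a warning is raised when any occur.
#' @export
decompose_soil_respiration <- function(series, root_const = 1.9) {
  if (identical(root_const, "half-mean")) {
    root_const <- mean(series$rs_gc_m2_d) / 2
  }
  stopifnot(is.numeric(root_const), root_const > 0)
  het <- series$rs_gc_m2_d - root_const
  n_clamped <- sum(het < 0)
  if (n_clamped > 0) {
    warning(n_clamped, " day(s) with soil respiration below the root ",
            "constant; heterotrophic component clamped at 0")
    het[het < 0] <- 0
  }
  series$het_gc_m2_d <- het
  attr(series, "root_const") <- root_const
  attr(series, "n_clamped") <- n_clamped
  series
}

#' Remove the temperature signal from heterotrophic respiration
#'
#' Divides by the Q10 factor so the residual carries only the moisture
#' signal: a series that is exactly Q10 in temperature becomes constant.
#'
#' @param series Data frame with `het_gc_m2_d` and `tmean_c`.
#' @param t_ref Q10 reference temperature (deg C).
#' @return The series with a `residual` column.
#' @export
detrend_temperature <- function(series, t_ref = T_REF_DEFAULT) {
  if (any(!is.finite(series$tmean_c))) stop("non-finite temperature in series")
  series$residual <- series$het_gc_m2_d / temperature_factor(series$tmean_c, t_ref)
  series
}

#' Fit the log-normal moisture response
#'
#' Least-squares fit of `r_opt * exp(-0.5 * ((ln w - ln w_opt) / s)^2)` to
#' temperature-detrended heterotrophic respiration against soil water
#' content, via Levenberg-Marquardt.
#'
#' @param series Data frame with `residual` and `swc_m3_m3` (> 0), at least
#'   5 points.
#' @param start Optional named start values (`r_opt`, `w_opt`, `s`).
#' @return An unnormalized [moisture_response()] with the residual sum of
#'   squares in `$rss`.
#' @export
fit_lognormal_response <- function(series, start = NULL) {
  w <- series$swc_m3_m3
  y <- series$residual
  keep <- is.finite(w) & is.finite(y)
  w <- w[keep]; y <- y[keep]
  if (length(w) < 5) stop("need at least 5 points to fit the moisture response")
  if (any(w <= 0)) stop("swc must be > 0")
  if (is.null(start)) {
    start <- list(r_opt = max(y), w_opt = w[which.max(y)], s = 0.5)
    if (start$r_opt <= 0) start$r_opt <- 1
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ r_opt * exp(-0.5 * ((log(w) - log(w_opt)) / s)^2),
      start = start,
      lower = c(r_opt = 1e-8, w_opt = 1e-4, s = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("moisture response fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  moisture_response(w_opt = unname(cf["w_opt"]), s = abs(unname(cf["s"])),
                    r_opt = unname(cf["r_opt"]), normalized = FALSE,
                    rss = sum(stats::resid(fit)^2))
}

#' Normalize a moisture response so its optimum equals one
#'
#' @param resp A fitted [moisture_response()].
#' @return The response with amplitude one and `normalized = TRUE`; shape
#'   parameters are unchanged. Idempotent.
#' @export
normalize_response <- function(resp) {
  if (resp$r_opt <= 0) stop("cannot normalize a response with r_opt <= 0")
  resp$r_opt <- 1
  resp$normalized <- TRUE
  resp
}

#' Thin a daily series to remove autocorrelation
#'
#' Retains every `stride`-th day by calendar distance, starting `stride`
#' days into the series: the first retained day is the first observation at
#' least `stride - 1` days after the series start, and each subsequent
#' retained day is at least `stride` days after the previous one. On a
#' 577-day daily series with a 30-day stride this keeps 19 points. A stride
#' of 1 keeps everything.
#'
#' @param series Data frame with a `date` column (sorted ascending).
#' @param stride_days Minimum calendar spacing in days (>= 1).
#' @return The thinned series.
#' @export
thin_autocorrelated <- function(series, stride_days = 30) {
  stopifnot(stride_days >= 1)
  if (stride_days == 1 || nrow(series) == 0) return(series)
  d <- as.numeric(series$date)
  keep <- logical(length(d))
  target <- d[1] + stride_days - 1
  for (i in seq_along(d)) {
    if (d[i] >= target) {
      keep[i] <- TRUE
      target <- d[i] + stride_days
    }
  }
  series[keep, , drop = FALSE]
}

#' Derive the normalized moisture response from a soil-respiration series
#'
#' Convenience pipeline: subtract the root constant, remove the temperature
#' signal, fit the log-normal curve, normalize.
#'
#' @inheritParams decompose_soil_respiration
#' @inheritParams detrend_temperature
#' @param min_chambers Days with fewer chamber measurements are dropped.
#' @return A normalized [moisture_response()].
#' @export
derive_moisture_response <- function(series, root_const = 1.9,
                                     t_ref = T_REF_DEFAULT, min_chambers = 3) {
  if (!is.null(series$n_chambers)) {
    series <- series[series$n_chambers >= min_chambers, , drop = FALSE]
  }
  series <- decompose_soil_respiration(series, root_const)
  series <- detrend_temperature(series, t_ref)
  normalize_response(fit_lognormal_response(series))
}
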