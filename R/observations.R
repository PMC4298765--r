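# Observation operators mapping model trajectories onto each assimilated
# stream, the eddy-covariance daily aggregation filters, steady-state
# pseudo-observations, and the Gaussian misfit / prior terms.

STREAM_IDS <- c("nee", "leaf_resp", "lai", "litterfall", "stem_resp", "agb",
                "soil_resp_het", "soil_resp_aut", "cwd_resp", "growth_ratio")

stream_window <- function(id) {
  switch(id,
         litterfall = "monthly",
         growth_ratio = "annual",
         "daily")
}

#' Construct an observation stream
#'
#' @param id Stream identifier, one of `nee`, `leaf_resp`, `lai`,
#'   `litterfall`, `stem_resp`, `agb`, `soil_resp_het`, `soil_resp_aut`,
#'   `cwd_resp`, `growth_ratio`.
#' @param data Tibble with `value` and `se` plus time columns: `date` for
#'   daily streams, `year`/`month` for monthly, `year` for annual.
#' @return The tibble with attributes `stream_id` and `window`.
#' @export
obs_stream <- function(id, data) {
  if (!id %in% STREAM_IDS) stop("unknown stream id: ", id)
  if (any(data$se <= 0)) stop("observation SEs must be > 0")
  w <- stream_window(id)
  need <- switch(w, daily = "date", monthly = c("year", "month"), annual = "year")
  miss <- setdiff(c(need, "value", "se"), names(data))
  if (length(miss)) stop("stream ", id, " missing columns: ", paste(miss, collapse = ", "))
  structure(tibble::as_tibble(data), stream_id = id, window = w)
}

#' Aggregate half-hourly eddy-covariance records to daily NEE
#'
#' Applies the standard filters: night-time records with friction velocity
#' below `ustar_min` are removed; flux (`fc`) and storage (`sfc`) values
#' more than `spike_sd` standard deviations from their series means are
#' removed; days with fewer than `min_halfhours` surviving records are
#' dropped. Remaining gaps on retained days are filled with that day's mean
#' daytime or night-time value (a slot counts as daytime between 06:00 and
#' 18:00) before the 48 half-hour values are summed into a daily flux.
#'
#' @param raw Tibble with `timestamp` (POSIXct), `fc`, `sfc` (both
#'   g C m-2 per half hour), `ustar` (m s-1) and logical `is_night`.
#' @param ustar_min Night-time friction velocity threshold (m s-1).
#' @param spike_sd Spike threshold in standard deviations.
#' @param min_halfhours Minimum surviving records per retained day.
#' @return Tibble `date`, `value` (daily NEE, g C m-2 d-1), `n_used`.
#' @export
aggregate_daily_nee <- function(raw, ustar_min = 0.15, spike_sd = 10,
                                min_halfhours = 40) {
  keep <- !(raw$is_night & raw$ustar < ustar_min)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0) {
    return(tibble::tibble(date = as.Date(character()), value = numeric(),
                          n_used = integer()))
  }
  ok_fc <- abs(raw$fc - mean(raw$fc)) <= spike_sd * stats::sd(raw$fc)
  ok_sfc <- abs(raw$sfc - mean(raw$sfc)) <= spike_sd * stats::sd(raw$sfc)
  raw <- raw[ok_fc & ok_sfc, , drop = FALSE]

  day <- as.Date(raw$timestamp, tz = "UTC")
  hr <- as.integer(format(raw$timestamp, "%H", tz = "UTC"))
  mi <- as.integer(format(raw$timestamp, "%M", tz = "UTC"))
  slot <- hr * 2L + mi %/% 30L
  nee <- raw$fc + raw$sfc

  out <- lapply(split(seq_along(day), day), function(ix) {
    if (length(ix) < min_halfhours) return(NULL)
    present <- slot[ix]
    missing <- setdiff(0:47, present)
    vals <- nee[ix]
    is_day_slot <- function(s) s >= 12 & s < 36  # 06:00-18:00
    day_mean <- mean(vals[is_day_slot(present)])
    night_mean <- mean(vals[!is_day_slot(present)])
    if (!is.finite(day_mean)) day_mean <- mean(vals)
    if (!is.finite(night_mean)) night_mean <- mean(vals)
    fill <- ifelse(is_day_slot(missing), day_mean, night_mean)
    tibble::tibble(date = day[ix[1]], value = sum(vals) + sum(fill),
                   n_used = length(ix))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(tibble::tibble(date = as.Date(character()), value = numeric(),
                          n_used = integer()))
  }
  out[order(out$date), ]
}

#' Predict an observation stream from a model trajectory
#'
#' Operators: `nee` reads daily NEE; `leaf_resp`, `stem_resp`, `cwd_resp`
#' read the corresponding respiration fluxes; `soil_resp_het` is litter plus
#' soil respiration and `soil_resp_aut` is fine- plus coarse-root
#' respiration (the two components a soil chamber integrates); `lai`
#' converts foliar carbon with [LEAF_C_PER_AREA]; `litterfall` sums the
#' daily foliage turnover flux over each observation month; `agb` is foliar
#' plus wood carbon; `growth_ratio` is the dry- to wet-season ratio of mean
#' daily wood growth input (allocation minus growth respiration) within each
#' observation year.
#'
#' @param traj A `carbon_trajectory`.
#' @param stream_id Stream identifier.
#' @param obs Observation tibble (see [obs_stream()]).
#' @return Numeric vector of predictions aligned with `obs` rows.
#' @export
predict_stream <- function(traj, stream_id, obs) {
  fx <- traj$fluxes
  at_date <- function(v) {
    idx <- match(as.Date(obs$date), traj$dates)
    if (any(is.na(idx))) stop("observation dates outside the trajectory window")
    v[idx]
  }
  switch(stream_id,
    nee = at_date(fx$nee),
    leaf_resp = at_date(fx$r_f),
    stem_resp = at_date(fx$r_w),
    cwd_resp = at_date(fx$r_cwd),
    soil_resp_het = at_date(fx$r_lit + fx$r_som),
    soil_resp_aut = at_date(fx$r_fr + fx$r_cr),
    lai = at_date(traj$pools$c_f / LEAF_C_PER_AREA),
    agb = at_date(traj$pools$c_f + traj$pools$c_w),
    litterfall = {
      ym <- format(traj$dates, "%Y-%m")
      sums <- tapply(fx$litterfall, ym, sum)
      key <- sprintf("%04d-%02d", obs$year, obs$month)
      if (any(!key %in% names(sums))) stop("observation months outside the trajectory window")
      as.numeric(sums[key])
    },
    growth_ratio = {
      yr <- as.integer(format(traj$dates, "%Y"))
      vapply(obs$year, function(y) {
        sel <- yr == y
        if (!any(sel)) stop("observation year ", y, " outside the trajectory window")
        mean(fx$growth_w[sel & traj$dry]) / mean(fx$growth_w[sel & !traj$dry])
      }, numeric(1))
    },
    stop("unknown stream id: ", stream_id)
  )
}

#' Steady-state pseudo-observations on the seven pools
#'
#' One pseudo-observation per pool: the net change in the stock over the
#' run, observed as zero with an SE equal to `sd_fraction` of the initial
#' stock. Regularizes the inversion toward near-steady pools without having
#' to spin the model up.
#'
#' @param traj A `carbon_trajectory`.
#' @param sd_fraction SE as a fraction of the initial stock (default 2%).
#' @return Tibble `pool`, `observed`, `predicted`, `se`.
#' @export
steady_state_pseudo_obs <- function(traj, sd_fraction = 0.02) {
  start <- traj$init_pools
  if (any(start == 0)) stop("zero initial stock")
  end <- as.numeric(traj$pools[nrow(traj$pools), ])
  tibble::tibble(pool = names(start), observed = 0,
                 predicted = end - as.numeric(start),
                 se = sd_fraction * as.numeric(start))
}

#' Model-data misfit and log-likelihood
#'
#' Sum of squared standardized residuals per stream, `sum(((M - O) / E)^2)`,
#' with observation errors treated as independent Gaussians, plus a
#' log-normal prior term `sum(((ln p - ln p0) / sigma_log)^2)` when a prior
#' specification and parameter vector are supplied. The log-likelihood is
#' `-0.5` times the total.
#'
#' @param predictions Named list of numeric prediction vectors per stream.
#' @param streams Named list of observation tibbles (same names); a
#'   `steady_state` entry may carry the pseudo-observations from
#'   [steady_state_pseudo_obs()].
#' @param priors Optional [prior_spec()].
#' @param params Optional parameter vector (required with `priors`).
#' @return List with `per_stream`, `data_term`, `prior_term`, `total` and
#'   `loglik`.
#' @export
misfit <- function(predictions, streams, priors = NULL, params = NULL) {
  ids <- names(streams)
  per <- vapply(ids, function(id) {
    o <- streams[[id]]
    m <- predictions[[id]]
    if (is.null(m)) stop("no predictions for stream ", id)
    if (length(m) != nrow(o)) stop("prediction/observation mismatch for ", id)
    obs_val <- if ("observed" %in% names(o)) o$observed else o$value
    if (any(o$se <= 0)) stop("zero SE in stream ", id)
    sum(((m - obs_val) / o$se)^2)
  }, numeric(1))
  data_term <- sum(per)
  prior_term <- 0
  if (!is.null(priors)) {
    if (is.null(params)) stop("params required when priors are given")
    p <- as.numeric(params[param_names()])
    prior_term <- sum(((log(p) - log(priors$median)) / priors$sigma_log)^2)
  }
  total <- data_term + prior_term
  list(per_stream = per, data_term = data_term, prior_term = prior_term,
       total = total, loglik = -0.5 * total)
}
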