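# Forward model: a seven-pool daily carbon box model with separate wet- and
# dry-season parameters for the live pools. Gross primary production enters
# via a pluggable canopy submodel; heterotrophic respiration from the three
# dead pools responds to temperature (Q10 = 2) and soil moisture.

#' Leaf carbon per unit leaf area (g C m-2 leaf)
#'
#' Half of the site leaf mass per area of 122.07 g m-2, assuming half of
#' leaf dry mass is carbon. Converts foliar carbon stock to LAI.
#' @export
LEAF_C_PER_AREA <- 122.07 / 2

#' Reference temperature for the Q10 response (deg C)
#'
#' The site mean daily temperature; keeps the temperature factor near one on
#' average so the respired-fraction parameters stay interpretable.
#' @export
T_REF_DEFAULT <- 25.6

#' Classify days as wet or dry season from soil water content
#'
#' A day is dry season when its mean soil water content falls strictly below
#' the threshold. The site convention sets the threshold at the lower
#' quartile of the full SWC record, which is 0.12 m3 m-3 there.
#'
#' @param driver Meteorological driver (see [meteo_driver()]).
#' @param threshold Fixed threshold in m3 m-3, or `"lower-quartile"` to
#'   compute the 25th percentile of the driver's SWC series.
#' @return Logical vector (`TRUE` = dry) of class `season_mask`, with
#'   attributes `threshold` and `provenance`.
#' @export
season_mask <- function(driver, threshold = 0.12) {
  swc <- driver$swc_m3_m3
  if (length(swc) < 1) stop("driver has no days")
  if (any(!is.finite(swc))) {
    stop("non-finite SWC on day(s) ", paste(utils::head(which(!is.finite(swc)), 5), collapse = ", "))
  }
  if (identical(threshold, "lower-quartile")) {
    thr <- unname(stats::quantile(swc, 0.25))
    prov <- "computed-quartile"
  } else {
    thr <- as.numeric(threshold)
    if (!is.finite(thr) || thr <= 0 || thr >= 1) stop("threshold must be in (0, 1)")
    prov <- "fixed"
  }
  structure(swc < thr, threshold = thr, provenance = prov,
            class = c("season_mask", "logical"))
}

#' Q10 temperature multiplier for heterotrophic respiration
#'
#' Doubles per 10 deg C rise: `2^((t_mean - t_ref) / 10)`.
#'
#' @param t_mean Mean daily temperature (deg C).
#' @param t_ref Reference temperature (deg C).
#' @return Dimensionless multiplier, 1 at `t_ref`.
#' @export
temperature_factor <- function(t_mean, t_ref = T_REF_DEFAULT) {
  if (any(!is.finite(t_mean)) || any(!is.finite(t_ref))) {
    stop("non-finite temperature")
  }
  2^((t_mean - t_ref) / 10)
}

#' Configure the GPP submodel
#'
#' Two formulations are available. `"standin"` is a saturating
#' light-response: `GPP = g_max * (1 - exp(-k * LAI)) * I / (I + i_half)`,
#' with `g_max` the canopy capacity (g C m-2 d-1), `k` a canopy light
#' extinction coefficient and `i_half` the half-saturation irradiance
#' (MJ m-2 d-1). It is the default for tests and synthetic experiments so
#' the package is self-contained. `"acm"` is the aggregated canopy model, a
#' big-leaf empirical formulation with ten fitted coefficients plus leaf
#' nitrogen, a maximum soil-leaf water potential difference, total hydraulic
#' resistance and site latitude; its coefficients would normally be
#' recalibrated against a detailed ecophysiological model for a site, which
#' is outside this package's scope.
#'
#' @param form `"standin"` or `"acm"`.
#' @param g_max,k,i_half Stand-in parameters.
#' @param acm_coef Ten ACM coefficients.
#' @param leaf_n Average foliar nitrogen (g N m-2 leaf).
#' @param psi_d Maximum soil-leaf water potential difference (MPa).
#' @param rtot Total plant-soil hydraulic resistance (MPa m2 s mmol-1).
#' @param lat_deg Site latitude (degrees).
#' @return A list of class `gpp_config`.
#' @export
gpp_config <- function(form = c("standin", "acm"),
                       g_max = 16, k = 0.5, i_half = 8,
                       acm_coef = c(11.33, 0.0156935, 4.22273, 208.868,
                                    0.0453194, 0.37836, 7.19298, 0.011136,
                                    2.1001, 0.789798),
                       leaf_n = 2.7, psi_d = -2, rtot = 1, lat_deg = 5.27) {
  form <- match.arg(form)
  cfg <- list(form = form, g_max = g_max, k = k, i_half = i_half,
              acm_coef = acm_coef, leaf_n = leaf_n, psi_d = psi_d,
              rtot = rtot, lat_deg = lat_deg)
  if (form == "acm" && length(acm_coef) != 10) stop("ACM needs 10 coefficients")
  if (any(!is.finite(unlist(cfg[-1])))) stop("GPP parameters must be finite")
  class(cfg) <- "gpp_config"
  cfg
}

# Daylength (hours) from day of year and latitude; used by the ACM form.
day_length_hours <- function(doy, lat_deg) {
  dec <- -23.4 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  mult <- pmin(pmax(tan(lat_deg * pi / 180) * tan(dec), -1), 1)
  24 / pi * acos(-mult)
}

acm_gpp <- function(lai, t_max, t_min, rad, co2, doy, cfg) {
  if (lai <= 0) return(0)
  a <- cfg$acm_coef
  gc <- abs(cfg$psi_d)^a[10] / (a[6] * cfg$rtot + 0.5 * (t_max - t_min))
  pp <- lai * cfg$leaf_n / gc * a[1] * exp(a[8] * t_max)
  qq <- a[3] - a[4]
  ci <- 0.5 * (co2 + qq - pp +
                 sqrt((co2 + qq - pp)^2 - 4 * (co2 * qq - pp * a[3])))
  e0 <- a[7] * lai^2 / (lai^2 + a[9])
  dayl <- day_length_hours(doy, cfg$lat_deg)
  cps <- e0 * rad * gc * (co2 - ci) / (e0 * rad + gc * (co2 - ci))
  max(cps * (a[2] * dayl + a[5]), 0)
}

#' Daily gross primary production
#'
#' @param lai Leaf area index (m2 m-2).
#' @param day_driver One-row driver (needs `rad_mj_m2`; the ACM form also
#'   uses `tmin_c`, `tmax_c`, `co2_ppm` and a `doy` column or attribute).
#' @param cfg A [gpp_config()].
#' @return GPP in g C m-2 d-1; zero when `lai` is zero.
#' @export
gpp <- function(lai, day_driver, cfg = gpp_config()) {
  if (!inherits(cfg, "gpp_config")) stop("cfg must be a gpp_config")
  if (lai < 0) stop("lai must be >= 0")
  rad <- day_driver$rad_mj_m2
  if (cfg$form == "standin") {
    return(cfg$g_max * (1 - exp(-cfg$k * lai)) * rad / (rad + cfg$i_half))
  }
  doy <- if ("doy" %in% names(day_driver)) day_driver$doy else
    as.integer(format(day_driver$date, "%j"))
  acm_gpp(lai, day_driver$tmax_c, day_driver$tmin_c, rad, day_driver$co2_ppm,
          doy, cfg)
}

# Evaluate a moisture response (object or plain function) at given SWC.
eval_moisture <- function(moisture, swc) {
  if (inherits(moisture, "moisture_response")) {
    moisture_factor(moisture, swc)
  } else if (is.function(moisture)) {
    moisture(swc)
  } else {
    stop("moisture must be a moisture_response or a function of SWC")
  }
}

flux_names <- function() {
  c("gpp", "alloc_f", "alloc_w", "alloc_fr", "alloc_cr",
    "r_f", "r_w", "r_fr", "r_cr", "r_lit", "r_cwd", "r_som",
    "r_a", "r_h", "r_eco", "nee", "litterfall", "growth_w")
}

#' Advance the carbon pools by one day (reference implementation)
#'
#' Pure-R single-day update, kept as the readable reference for the
#' compiled trajectory runner. Allocation to each live pool is a fraction of
#' GPP; a fixed fraction of each allocation is respired immediately
#' (autotrophic respiration) and the remainder grows the pool. Turnover
#' routes foliage and fine roots to litter, wood and coarse roots to coarse
#' woody debris; litter and CWD decomposition feed soil organic matter.
#' Heterotrophic respiration from litter, CWD and SOM is a fraction of the
#' pool scaled by the Q10 temperature factor and the soil-moisture response.
#'
#' @param pools Named numeric vector of the seven stocks.
#' @param params A [param_vector()].
#' @param day_driver One-row driver.
#' @param season `"wet"` or `"dry"`.
#' @param moisture Moisture response (object or function of SWC).
#' @param cfg A [gpp_config()].
#' @param t_ref Q10 reference temperature.
#' @return List with updated `pools` and the day's `fluxes` (named vector).
#' @export
step_day <- function(pools, params, day_driver, season = "wet",
                     moisture = function(swc) 1, cfg = gpp_config(),
                     t_ref = T_REF_DEFAULT) {
  sp <- season_params(params, season)
  lai <- pools[["c_f"]] / LEAF_C_PER_AREA
  g <- gpp(lai, day_driver, cfg)

  alloc <- c(f = sp$a_f, w = sp$a_w, fr = sp$a_fr, cr = sp$a_cr) * g
  resp_a <- alloc * c(sp$rf_f, sp$rf_w, sp$rf_fr, sp$rf_cr)
  growth <- alloc - resp_a

  lit_in_f <- sp$t_f * pools[["c_f"]]
  lit_in_fr <- sp$t_fr * pools[["c_fr"]]
  cwd_in_w <- sp$t_w * pools[["c_w"]]
  cwd_in_cr <- sp$t_cr * pools[["c_cr"]]
  dec_lit <- sp$d_lit * pools[["c_lit"]]
  dec_cwd <- sp$d_cwd * pools[["c_cwd"]]

  tmean <- (day_driver$tmin_c + day_driver$tmax_c) / 2
  env <- temperature_factor(tmean, t_ref) * eval_moisture(moisture, day_driver$swc_m3_m3)
  r_lit <- sp$rf_lit * pools[["c_lit"]] * env
  r_cwd <- sp$rf_cwd * pools[["c_cwd"]] * env
  r_som <- sp$rf_som * pools[["c_som"]] * env

  new <- c(
    c_f = pools[["c_f"]] + growth[["f"]] - lit_in_f,
    c_w = pools[["c_w"]] + growth[["w"]] - cwd_in_w,
    c_fr = pools[["c_fr"]] + growth[["fr"]] - lit_in_fr,
    c_cr = pools[["c_cr"]] + growth[["cr"]] - cwd_in_cr,
    c_lit = pools[["c_lit"]] + lit_in_f + lit_in_fr - dec_lit - r_lit,
    c_cwd = pools[["c_cwd"]] + cwd_in_w + cwd_in_cr - dec_cwd - r_cwd,
    c_som = pools[["c_som"]] + dec_lit + dec_cwd - r_som
  )
  if (any(new < 0)) {
    bad <- names(new)[which(new < 0)[1]]
    stop("pool ", bad, " driven below zero (unstable parameter draw)")
  }

  r_a <- sum(resp_a)
  r_h <- r_lit + r_cwd + r_som
  fluxes <- stats::setNames(
    c(g, alloc, resp_a, r_lit, r_cwd, r_som,
      r_a, r_h, r_a + r_h, r_a + r_h - g, lit_in_f, growth[["w"]]),
    flux_names())
  list(pools = new, fluxes = fluxes)
}

#' Run the forward model over a driver window
#'
#' Iterates the daily update over the driver, switching between the wet and
#' dry parameter members according to the season mask. Dispatches to a
#' compiled inner loop when the moisture response is a normalized
#' [moisture_response()] object; otherwise falls back to the R stepper.
#'
#' @param params A [param_vector()].
#' @param driver Meteorological driver.
#' @param mask A [season_mask()] aligned with the driver (`TRUE` = dry).
#' @param moisture Moisture response object or function of SWC.
#' @param cfg A [gpp_config()].
#' @param t_ref Q10 reference temperature.
#' @param on_fail `"error"` to stop when a pool would go negative, `"flag"`
#'   to return `NULL` (used by the sampler, which maps it to log-likelihood
#'   `-Inf`).
#' @return A list of class `carbon_trajectory`: `dates`, `pools` (tibble,
#'   end-of-day stocks), `fluxes` (tibble), `dry` (logical mask),
#'   `init_pools`.
#' @export
run_forward <- function(params, driver, mask, moisture, cfg = gpp_config(),
                        t_ref = T_REF_DEFAULT, on_fail = c("error", "flag")) {
  on_fail <- match.arg(on_fail)
  n <- nrow(driver)
  if (length(mask) != n) stop("driver and season mask are not aligned")
  p0 <- initial_pools(params)

  use_cpp <- inherits(moisture, "moisture_response") && isTRUE(moisture$normalized) &&
    inherits(cfg, "gpp_config")
  if (use_cpp) {
    doy <- as.integer(format(driver$date, "%j"))
    res <- run_forward_cpp(
      unname(as.numeric(params[param_names()])), as.integer(mask),
      driver$tmin_c, driver$tmax_c, driver$rad_mj_m2, driver$co2_ppm,
      driver$swc_m3_m3, doy,
      moisture$w_opt, moisture$s,
      cfg$form == "acm",
      c(cfg$g_max, cfg$k, cfg$i_half),
      cfg$acm_coef, cfg$leaf_n, cfg$psi_d, cfg$rtot, cfg$lat_deg,
      LEAF_C_PER_AREA, t_ref)
    if (!res$ok) {
      if (on_fail == "flag") return(NULL)
      stop("pool ", c("c_f", "c_w", "c_fr", "c_cr", "c_lit", "c_cwd", "c_som")[res$fail_pool],
           " driven below zero on day ", res$fail_day)
    }
    pools <- res$pools
    fluxes <- res$fluxes
  } else {
    pools <- matrix(NA_real_, n, 7)
    fluxes <- matrix(NA_real_, n, length(flux_names()))
    cur <- p0
    for (i in seq_len(n)) {
      st <- tryCatch(
        step_day(cur, params, driver[i, , drop = FALSE],
                 if (mask[i]) "dry" else "wet", moisture, cfg, t_ref),
        error = function(e) e)
      if (inherits(st, "error")) {
        if (on_fail == "flag") return(NULL)
        stop(conditionMessage(st), " on day ", i)
      }
      cur <- st$pools
      pools[i, ] <- cur
      fluxes[i, ] <- st$fluxes
    }
  }
  colnames(pools) <- c("c_f", "c_w", "c_fr", "c_cr", "c_lit", "c_cwd", "c_som")
  colnames(fluxes) <- flux_names()
  structure(list(dates = driver$date,
                 pools = tibble::as_tibble(as.data.frame(pools)),
                 fluxes = tibble::as_tibble(as.data.frame(fluxes)),
                 dry = as.logical(mask),
                 init_pools = p0),
            class = "carbon_trajectory")
}

#' Total carbon stock per day of a trajectory
#'
#' @param traj A `carbon_trajectory`.
#' @return Numeric vector of daily total carbon (g C m-2).
#' @export
total_carbon <- function(traj) {
  rowSums(as.matrix(traj$pools))
}

#' @export
print.carbon_trajectory <- function(x, ...) {
  cat("carbon_trajectory:", length(x$dates), "days,",
      sum(x$dry), "dry\n")
  cat("  mean GPP", round(mean(x$fluxes$gpp), 2),
      "| mean NEE", round(mean(x$fluxes$nee), 2), "g C m-2 d-1\n")
  invisible(x)
}
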