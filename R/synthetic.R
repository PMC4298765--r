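# Synthetic site emulation: daily drivers with a long-dry-season SWC cycle,
# and all nine observation streams sampled from a known truth run, so twin
# experiments and every pipeline stage run with no external data.

#' Default observation counts and SEs per stream
#'
#' Counts and average standard errors of the site configuration (NEE 497
#' days at SE 2.66 g C m-2 d-1, four leaf-respiration campaigns, six LAI
#' surveys, 112 monthly litterfall collections, 11 stem-respiration periods,
#' 4 biomass censuses, 19 thinned soil-respiration days, 13 coarse-dead-wood
#' respiration periods, one growth ratio per year at SE 0.09). The
#' soil-respiration stream is assimilated as separate heterotrophic and
#' autotrophic components; the autotrophic SE is the 0.3 uncertainty on the
#' constant root respiration.
#'
#' @return Tibble `stream`, `n`, `se`.
#' @export
default_stream_design <- function() {
  tibble::tibble(
    stream = c("nee", "leaf_resp", "lai", "litterfall", "stem_resp", "agb",
               "soil_resp_het", "soil_resp_aut", "cwd_resp", "growth_ratio"),
    n = c(497L, 4L, 6L, 112L, 11L, 4L, 19L, 19L, 13L, NA_integer_),
    se = c(2.66, 0.76, 0.44, 0.20, 0.08, 2258.35, 0.52, 0.30, 0.07, 0.09))
}

#' Synthetic experiment configuration
#'
#' @param n_years Simulated years (8 gives the 2922-day site window).
#' @param start_date First simulated day.
#' @param swc_mean,swc_sd Target mean and SD of the soil water content
#'   series (site: 0.17 +/- 0.04 m3 m-3).
#' @param swc_threshold Dry-season threshold (m3 m-3).
#' @param truth Truth parameter vector (default: site posterior medians).
#' @param truth_moisture Truth moisture response before normalization
#'   (default optimum 2.5 g C m-2 d-1 at SWC 0.17, spread 0.4).
#' @param root_const Constant root respiration added to synthetic soil
#'   respiration (g C m-2 d-1).
#' @param stream_design Counts/SEs per stream; see
#'   [default_stream_design()].
#' @param noise_scale Multiplier on all observation noise (0 gives
#'   noise-free observations equal to the operator outputs).
#' @param soil_days Length of the contiguous daily soil-respiration series
#'   used for the moisture-response fit.
#' @param seed RNG seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 8, start_date = "2004-01-01",
                             swc_mean = 0.17, swc_sd = 0.04,
                             swc_threshold = 0.12,
                             truth = default_parameters("posterior"),
                             truth_moisture = moisture_response(0.17, 0.4, 2.5),
                             root_const = 1.9,
                             stream_design = default_stream_design(),
                             noise_scale = 1, soil_days = 577, seed = 1) {
  stopifnot(n_years >= 1, swc_mean > 0, swc_sd >= 0)
  structure(list(n_years = n_years, start_date = as.Date(start_date),
                 swc_mean = swc_mean, swc_sd = swc_sd,
                 swc_threshold = swc_threshold, truth = truth,
                 truth_moisture = truth_moisture, root_const = root_const,
                 stream_design = stream_design, noise_scale = noise_scale,
                 soil_days = soil_days, seed = seed),
            class = "synthetic_config")
}

# Seasonal trough shape shared by SWC, radiation and temperature: a smooth
# plateau over the long dry season (Aug-Nov) plus a short March dip. The
# plateau (rather than a bell) reflects that soil moisture sits near its
# dry-season floor for months, and is what places the lower quartile of the
# rescaled SWC series near the 0.12 m3 m-3 threshold.
dry_season_bump <- function(doy) {
  stats::plogis((doy - 225) / 4) * stats::plogis((330 - doy) / 4) +
    0.3 * stats::plogis((doy - 68) / 4) * stats::plogis((82 - doy) / 4)
}

#' Generate a daily meteorological driver with site-like seasonality
#'
#' Soil water content follows an annual cycle with a pronounced dry-season
#' trough plus AR(1) noise, affinely rescaled to the configured mean and SD
#' so that at defaults the lower quartile sits near the 0.12 m3 m-3
#' dry-season threshold and about a quarter of days are dry. Radiation and
#' temperature are elevated in the dry season; precipitation is suppressed.
#' With `swc_sd = 0` and `noise_scale = 0` all drivers are constant.
#'
#' @param cfg A [synthetic_config()].
#' @return A validated driver tibble.
#' @export
generate_drivers <- function(cfg) {
  set.seed(cfg$seed)
  end <- seq(cfg$start_date, by = paste(cfg$n_years, "years"), length.out = 2)[2] - 1
  dates <- seq(cfg$start_date, end, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  b <- dry_season_bump(doy)
  ns <- cfg$noise_scale

  ar1 <- function(n, phi, sd) {
    if (sd == 0) return(numeric(n))
    e <- stats::rnorm(n, 0, sd)
    stats::filter(e, phi, method = "recursive")
  }

  raw <- -b + ns * as.numeric(ar1(n, 0.9, 0.035))
  z <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw * 0
  swc <- pmin(pmax(cfg$swc_mean + cfg$swc_sd * z, 0.02), 0.6)

  rad <- pmax(13 + 3.5 * b + ns * stats::rnorm(n, 0, 1.3), 1)
  tmax <- 29.5 + 1.6 * b + ns * stats::rnorm(n, 0, 0.7)
  tmin <- pmin(22 + 0.5 * b + ns * stats::rnorm(n, 0, 0.4), tmax - 0.5)
  mu_p <- 11.3 * pmax(1 - 0.85 * b, 0.02)
  precip <- if (ns == 0) mu_p else stats::rexp(n, 1 / mu_p)
  year_idx <- as.integer(format(dates, "%Y")) - as.integer(format(dates[1], "%Y"))
  co2 <- 375 + 1.9 * year_idx + ns * stats::rnorm(n, 0, 0.4)

  meteo_driver(tibble::tibble(date = dates, tmin_c = tmin, tmax_c = tmax,
                              precip_mm = precip, rad_mj_m2 = rad,
                              co2_ppm = co2, swc_m3_m3 = swc))
}

#' Run the truth model over a synthetic driver
#'
#' @param cfg A [synthetic_config()].
#' @param driver Driver from [generate_drivers()] (regenerated if omitted).
#' @param gpp_cfg GPP configuration.
#' @return List `driver`, `mask`, `moisture` (normalized truth response),
#'   `trajectory`.
#' @export
truth_run <- function(cfg, driver = NULL, gpp_cfg = gpp_config()) {
  if (is.null(driver)) driver <- generate_drivers(cfg)
  mask <- season_mask(driver, cfg$swc_threshold)
  moist <- normalize_response(cfg$truth_moisture)
  traj <- run_forward(cfg$truth, driver, mask, moist, gpp_cfg)
  list(driver = driver, mask = mask, moisture = moist, trajectory = traj)
}

#' Generate the nine observation streams from a truth trajectory
#'
#' Each stream is the observation operator applied to the truth run plus
#' independent Gaussian noise at its configured SE (litterfall SEs scale
#' with days in the month since the design SE is a per-day rate). NEE is
#' additionally rendered as half-hourly records with injected low-u*
#' night-time records, extreme spikes and short days, so the daily
#' aggregation filters are all exercised; aggregation recovers exactly the
#' NEE observation days.
#'
#' @param truth Output of [truth_run()].
#' @param cfg The [synthetic_config()].
#' @return List `streams` (named observation tibbles), `halfhourly`
#'   (tibble with attribute `spike_days`), `soil_daily` (daily
#'   soil-respiration series for the moisture-response fit).
#' @export
generate_observations <- function(truth, cfg) {
  set.seed(cfg$seed + 1)
  traj <- truth$trajectory
  dates <- traj$dates
  n <- length(dates)
  ns <- cfg$noise_scale
  des <- cfg$stream_design
  getn <- function(id) des$n[des$stream == id]
  getse <- function(id) des$se[des$stream == id]

  pick_days <- function(count) {
    if (count > n) stop("requested ", count, " observation days but only ",
                        n, " available")
    sort(sample.int(n, count))
  }
  daily_stream <- function(id, count = getn(id), se = getse(id)) {
    ix <- pick_days(count)
    ob <- tibble::tibble(date = dates[ix], value = NA_real_, se = se)
    ob$value <- predict_stream(traj, id, ob) + ns * stats::rnorm(count, 0, se)
    obs_stream(id, ob)
  }

  streams <- list(
    nee = daily_stream("nee"),
    leaf_resp = daily_stream("leaf_resp"),
    lai = daily_stream("lai"),
    stem_resp = daily_stream("stem_resp"),
    agb = daily_stream("agb"),
    cwd_resp = daily_stream("cwd_resp"))

  soil_ix <- pick_days(getn("soil_resp_het"))
  soil_dates <- dates[soil_ix]
  het <- tibble::tibble(date = soil_dates, value = NA_real_,
                        se = getse("soil_resp_het"))
  het$value <- predict_stream(traj, "soil_resp_het", het) +
    ns * stats::rnorm(nrow(het), 0, het$se)
  aut <- tibble::tibble(date = soil_dates, value = NA_real_,
                        se = getse("soil_resp_aut"))
  aut$value <- predict_stream(traj, "soil_resp_aut", aut) +
    ns * stats::rnorm(nrow(aut), 0, aut$se)
  streams$soil_resp_het <- obs_stream("soil_resp_het", het)
  streams$soil_resp_aut <- obs_stream("soil_resp_aut", aut)

  months <- unique(format(dates, "%Y-%m"))
  n_lf <- getn("litterfall")
  mkeys <- if (n_lf <= length(months)) sort(sample(months, n_lf)) else
    sort(sample(months, n_lf, replace = TRUE))
  lf <- tibble::tibble(year = as.integer(substr(mkeys, 1, 4)),
                       month = as.integer(substr(mkeys, 6, 7)))
  ndays <- vapply(mkeys, function(k) sum(format(dates, "%Y-%m") == k), numeric(1))
  lf$se <- getse("litterfall") * ndays
  lf$value <- predict_stream(traj, "litterfall", lf) +
    ns * stats::rnorm(nrow(lf), 0, lf$se)
  streams$litterfall <- obs_stream("litterfall", lf)

  yrs <- sort(unique(as.integer(format(dates, "%Y"))))
  gr <- tibble::tibble(year = yrs, value = NA_real_, se = getse("growth_ratio"))
  gr$value <- predict_stream(traj, "growth_ratio", gr) +
    ns * stats::rnorm(nrow(gr), 0, gr$se)
  streams$growth_ratio <- obs_stream("growth_ratio", gr)

  halfhourly <- render_halfhourly_nee(streams$nee, cfg)
  soil_daily <- synth_soil_daily(truth, cfg)

  list(streams = streams, halfhourly = halfhourly, soil_daily = soil_daily)
}

# Render the daily NEE observations as half-hourly flux records, with
# defects injected to exercise the aggregation filters: low-u* night
# records (whose values equal the night mean, so filtering plus gap-filling
# preserves the daily sum), a few 15-SD spikes, and extra short days that
# fall below the 40-half-hour rule and must disappear on aggregation.
render_halfhourly_nee <- function(nee_stream, cfg) {
  set.seed(cfg$seed + 2)
  slots <- 0:47
  is_day <- slots >= 12 & slots < 36
  wday <- sin(pi * (slots[is_day] - 11.5) / 24)
  wday <- wday / sum(wday)

  one_day <- function(date, value, n_lowu, short = FALSE) {
    night_val <- 0.6 * abs(value) / sum(!is_day)
    day_total <- value - night_val * sum(!is_day)
    fc <- numeric(48)
    fc[is_day] <- day_total * wday
    fc[!is_day] <- night_val
    ustar <- stats::runif(48, 0.2, 0.6)
    if (n_lowu > 0) {
      low <- sample(which(!is_day), n_lowu)
      ustar[low] <- stats::runif(n_lowu, 0.02, 0.12)
    }
    keep <- if (short) sort(sample.int(48, 30)) else slots + 1
    tibble::tibble(
      timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
        (keep - 1) * 1800,
      fc = fc[keep], sfc = 0, ustar = ustar[keep], is_night = !is_day[keep])
  }

  rows <- lapply(seq_len(nrow(nee_stream)), function(i) {
    one_day(nee_stream$date[i], nee_stream$value[i], stats::rbinom(1, 5, 0.4))
  })
  # short defect days on dates without NEE observations
  all_dates <- seq(min(nee_stream$date), max(nee_stream$date), by = "day")
  free <- setdiff(as.character(all_dates), as.character(nee_stream$date))
  short_dates <- as.Date(sample(free, min(10, length(free))))
  rows <- c(rows, lapply(short_dates, function(d) one_day(d, -1, 0, short = TRUE)))
  out <- do.call(rbind, rows)
  out <- out[order(out$timestamp), ]

  # spikes far beyond 10 SDs of the series, on observation days
  spike_days <- sample(seq_len(nrow(nee_stream)), 3)
  big <- max(1000 * stats::sd(out$fc), 200)
  for (d in nee_stream$date[spike_days]) {
    ix <- which(as.Date(out$timestamp, tz = "UTC") == d & !out$is_night)[5]
    out$fc[ix] <- big
  }
  attr(out, "spike_days") <- nee_stream$date[spike_days]
  attr(out, "spike_value") <- big
  out
}

# Daily soil-respiration series consistent with the truth run: modelled
# litter+soil heterotrophic respiration plus the constant root component,
# with chamber noise; a few days drop below the 3-chamber rule.
synth_soil_daily <- function(truth, cfg) {
  set.seed(cfg$seed + 3)
  traj <- truth$trajectory
  driver <- truth$driver
  n <- length(traj$dates)
  len <- min(cfg$soil_days, n)
  start <- min(max(1, n - len + 1), 461)
  ix <- seq(start, start + len - 1)
  het <- traj$fluxes$r_lit[ix] + traj$fluxes$r_som[ix]
  noise_sd <- 0.15
  rs <- het + cfg$root_const + cfg$noise_scale * stats::rnorm(len, 0, noise_sd)
  n_ch <- ifelse(stats::runif(len) < 0.03, 2L, 4L)
  tibble::tibble(date = traj$dates[ix], rs_gc_m2_d = rs, se = noise_sd,
                 swc_m3_m3 = driver$swc_m3_m3[ix],
                 tmean_c = (driver$tmin_c[ix] + driver$tmax_c[ix]) / 2,
                 n_chambers = n_ch)
}

#' Simulate temperature- and moisture-driven soil respiration directly
#'
#' Small simulator for moisture-response recovery checks: soil water
#' contents log-uniform over a site-like range, heterotrophic respiration
#' from a known response times the Q10 factor, plus the root constant and
#' Gaussian noise.
#'
#' @param n Number of days.
#' @param truth True (unnormalized) [moisture_response()].
#' @param noise_sd Gaussian noise SD on total soil respiration.
#' @param root_const Constant root respiration.
#' @param t_ref Q10 reference temperature.
#' @param seed RNG seed.
#' @return Series suitable for [derive_moisture_response()].
#' @export
simulate_moisture_data <- function(n = 200,
                                   truth = moisture_response(0.17, 0.4, 2.5),
                                   noise_sd = 0.1, root_const = 1.9,
                                   t_ref = T_REF_DEFAULT, seed = 1) {
  set.seed(seed)
  swc <- exp(stats::runif(n, log(0.07), log(0.35)))
  tmean <- t_ref + stats::rnorm(n, 0, 1.5)
  het <- moisture_factor(truth, swc) * temperature_factor(tmean, t_ref)
  tibble::tibble(date = as.Date("2005-01-01") + seq_len(n) - 1,
                 rs_gc_m2_d = het + root_const + stats::rnorm(n, 0, noise_sd),
                 se = noise_sd, swc_m3_m3 = swc, tmean_c = tmean,
                 n_chambers = 4L)
}
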