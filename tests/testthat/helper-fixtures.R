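# Shared fixtures: small constant drivers, a fast synthetic configuration,
# and a cached mini twin setup used by several test files.

constant_driver <- function(n = 10, swc = 0.17, rad = 16, tmin = 22,
                            tmax = 29.2, start = "2004-01-01") {
  meteo_driver(tibble::tibble(
    date = seq(as.Date(start), by = "day", length.out = n),
    tmin_c = tmin, tmax_c = tmax, precip_mm = 5, rad_mj_m2 = rad,
    co2_ppm = 380, swc_m3_m3 = swc))
}

# Parameter vector with selected values overridden (before normalization).
params_with <- function(..., base = default_parameters("posterior"),
                        normalize = FALSE) {
  ov <- c(...)
  x <- stats::setNames(as.numeric(base), param_names())
  x[names(ov)] <- ov
  param_vector(x, normalize = normalize)
}

# Parameter vector whose only non-degenerate process is chosen by override:
# all turnover/decomposition/respired fractions shrunk to effectively zero.
null_dynamics_params <- function(...) {
  eps <- 1e-300
  ov <- c(...)
  x <- stats::setNames(as.numeric(default_parameters("posterior")), param_names())
  rates <- grep("^(t_|d_|rf_)", param_names(), value = TRUE)
  x[rates] <- eps
  x[names(ov)] <- ov
  param_vector(x, normalize = FALSE)
}

flat_moisture <- function() normalize_response(moisture_response(0.17, 1e6))

# Small synthetic world shared across tests (2 years, reduced counts).
small_synth_config <- function(seed = 7, noise_scale = 1) {
  des <- default_stream_design()
  des$n <- c(120L, 4L, 6L, 24L, 8L, 4L, 10L, 10L, 8L, NA_integer_)
  synthetic_config(n_years = 2, stream_design = des, seed = seed,
                   soil_days = 400, noise_scale = noise_scale)
}

small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_synth_config()
      tru <- truth_run(cfg)
      obs <- generate_observations(tru, cfg)
      cache <<- list(cfg = cfg, truth = tru, obs = obs)
    }
    cache
  }
})
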