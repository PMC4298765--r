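# Forward-model mechanics: season classification, temperature and GPP
# responses, single-day bookkeeping and multi-day conservation.

test_that("season mask classifies days by strict SWC threshold", {
  d <- constant_driver(4)
  d$swc_m3_m3 <- c(0.11, 0.12, 0.13, 0.119)
  m <- season_mask(d, 0.12)
  expect_equal(as.logical(m), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(m, "threshold"), 0.12)

  # lower-quartile mode against an independent sorted-interpolation oracle
  d2 <- constant_driver(4)
  d2$swc_m3_m3 <- c(0.10, 0.14, 0.18, 0.22)
  sorted <- sort(d2$swc_m3_m3)
  h <- 1 + 0.25 * (4 - 1)  # type-7 percentile by hand
  oracle <- sorted[floor(h)] + (h - floor(h)) * (sorted[ceiling(h)] - sorted[floor(h)])
  m2 <- season_mask(d2, "lower-quartile")
  expect_equal(attr(m2, "threshold"), oracle)
  expect_equal(as.logical(m2), d2$swc_m3_m3 < oracle)

  expect_error(season_mask(d[0, ]), "no days")
  d$swc_m3_m3[2] <- NaN
  expect_error(season_mask(d), "non-finite SWC")
})

test_that("temperature factor doubles per 10 degrees", {
  expect_equal(temperature_factor(25.6, 25.6), 1)
  expect_equal(temperature_factor(35.6, 25.6), 2)
  expect_equal(temperature_factor(15.6, 25.6), 0.5)
  t <- seq(10, 40, by = 0.5)
  expect_true(all(diff(temperature_factor(t, 25.6)) > 0))
  expect_error(temperature_factor(NA_real_), "non-finite")
})

test_that("stand-in GPP matches its closed form and is monotone", {
  cfg <- gpp_config(g_max = 12, k = 0.5, i_half = 8)
  day <- constant_driver(1, rad = 16)
  expect_equal(gpp(5, day, cfg), 12 * (1 - exp(-2.5)) * 16 / 24)
  expect_equal(gpp(0, day, cfg), 0)
  lai <- seq(0, 10, by = 0.5)
  g <- vapply(lai, gpp, numeric(1), day_driver = day, cfg = cfg)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g <= 12))
  day2 <- constant_driver(1, rad = 32)
  expect_gte(gpp(5, day2, cfg), gpp(5, day, cfg))
})

test_that("ACM GPP is nonnegative, zero without canopy, monotone in light", {
  cfg <- gpp_config("acm")
  day <- constant_driver(1, rad = 16)
  expect_equal(gpp(0, day, cfg), 0)
  rads <- c(2, 8, 16, 24, 30)
  g <- vapply(rads, function(r) gpp(5, constant_driver(1, rad = r), cfg),
              numeric(1))
  expect_true(all(g >= 0))
  expect_true(all(diff(g) > 0))
  lais <- c(0.5, 2, 4, 6, 8)
  gl <- vapply(lais, gpp, numeric(1), day_driver = day, cfg = cfg)
  expect_true(all(diff(gl) > 0))
})

test_that("single-day bookkeeping follows allocation/respiration arithmetic", {
  # fix GPP = 10 via a saturating canopy and capacity tuned to the driver
  day <- constant_driver(1, rad = 16)
  cfg <- gpp_config(g_max = 15, k = 20, i_half = 8)  # saturated: 15*16/24 = 10
  p <- params_with(a_f_wet = 0.40, rf_f_wet = 0.78)
  pools <- initial_pools(p)
  st <- step_day(pools, p, day[1, ], "wet", flat_moisture(), cfg,
                 t_ref = (22 + 29.2) / 2)
  expect_equal(st$fluxes[["gpp"]], 10, tolerance = 1e-12)
  expect_equal(st$fluxes[["alloc_f"]], 4.0)
  expect_equal(st$fluxes[["r_f"]], 3.12)
  # foliar growth input = allocation minus growth respiration
  expect_equal(st$fluxes[["alloc_f"]] - st$fluxes[["r_f"]], 0.88)

  # null dynamics: zero GPP and vanishing rates leave pools unchanged
  p0 <- null_dynamics_params()
  st0 <- step_day(initial_pools(p0), p0, day[1, ], "wet", flat_moisture(),
                  gpp_config(g_max = 0))
  expect_equal(st0$pools, initial_pools(p0), tolerance = 1e-12)
  expect_equal(sum(abs(st0$fluxes)), 0, tolerance = 1e-250)

  # litter decomposition routes to SOM and conserves carbon
  pl <- null_dynamics_params(d_lit = 0.001)
  poolsl <- initial_pools(pl)
  poolsl["c_lit"] <- 300
  stl <- step_day(poolsl, pl, day[1, ], "wet", flat_moisture(),
                  gpp_config(g_max = 0))
  expect_equal(stl$pools[["c_lit"]], 300 - 0.3)
  expect_equal(stl$pools[["c_som"]], poolsl[["c_som"]] + 0.3)
  expect_equal(sum(stl$pools), sum(poolsl))
})

test_that("negative pools abort with the pool named", {
  p <- params_with(t_f_wet = 0.9999, rf_f_wet = 0.999999)
  pools <- initial_pools(p)
  pools["c_f"] <- 1e-9
  day <- constant_driver(1)
  # two days of near-total turnover with no growth drive foliage negative
  d2 <- constant_driver(2)
  expect_error(
    run_forward(params_with(t_f_wet = 1.5), d2, season_mask(d2, 0.5) & FALSE,
                flat_moisture()),
    "c_f")
})

test_that("forward run conserves carbon and matches the R stepper", {
  set.seed(11)
  d <- generate_drivers(synthetic_config(n_years = 1, seed = 3))
  m <- season_mask(d, 0.12)
  moist <- normalize_response(moisture_response(0.17, 0.4, 2.5))
  for (rep in 1:5) {
    p <- param_vector(stats::setNames(
      as.numeric(default_parameters()) * exp(rnorm(36, 0, 0.15)),
      param_names()))
    tr <- run_forward(p, d, m, moist)
    drift <- total_carbon(tr) - sum(initial_pools(p))
    err <- max(abs(cumsum(tr$fluxes$gpp - tr$fluxes$r_eco) - drift))
    expect_lt(err, 1e-6)
    # flux identities at every step
    fx <- tr$fluxes
    expect_equal(fx$r_a, fx$r_f + fx$r_w + fx$r_fr + fx$r_cr)
    expect_equal(fx$r_h, fx$r_lit + fx$r_cwd + fx$r_som)
    expect_equal(fx$r_eco, fx$r_a + fx$r_h)
    expect_equal(fx$nee, fx$r_eco - fx$gpp)
    expect_true(all(fx[c("r_f", "r_w", "r_fr", "r_cr",
                         "r_lit", "r_cwd", "r_som")] >= 0))
  }

  # compiled path equals the pure-R reference path
  p <- default_parameters()
  tr_cpp <- run_forward(p, d[1:40, ], m[1:40], moist)
  tr_r <- run_forward(p, d[1:40, ], m[1:40],
                      function(w) moisture_factor(moist, w))
  expect_equal(as.matrix(tr_cpp$pools), as.matrix(tr_r$pools),
               tolerance = 1e-12)
  expect_equal(as.matrix(tr_cpp$fluxes), as.matrix(tr_r$fluxes),
               tolerance = 1e-12)

  # one-day run equals a single step_day call
  tr1 <- run_forward(p, d[1, ], m[1], moist)
  st1 <- step_day(initial_pools(p), p, d[1, ],
                  if (m[1]) "dry" else "wet",
                  function(w) moisture_factor(moist, w))
  expect_equal(as.numeric(tr1$pools[1, ]), unname(st1$pools))
})

test_that("identical seasonal members make the run mask-invariant", {
  d <- constant_driver(60)
  d$swc_m3_m3 <- runif(60, 0.08, 0.3)
  x <- stats::setNames(as.numeric(default_parameters()), param_names())
  for (b in c("a_f", "a_w", "a_fr", "a_cr", "t_f", "t_w", "t_fr", "t_cr",
              "rf_f", "rf_w", "rf_fr", "rf_cr")) {
    x[paste0(b, "_dry")] <- x[paste0(b, "_wet")]
  }
  p <- param_vector(x)
  moist <- normalize_response(moisture_response(0.17, 0.4))
  m1 <- season_mask(d, 0.12)
  m2 <- season_mask(d, 0.25)
  tr1 <- run_forward(p, d, m1, moist)
  tr2 <- run_forward(p, d, m2, moist)
  expect_equal(tr1$pools, tr2$pools, tolerance = 1e-12)
  expect_equal(tr1$fluxes, tr2$fluxes, tolerance = 1e-12)
})

test_that("parameter vector validation and allocation closure", {
  p <- default_parameters()
  for (s in c("wet", "dry")) {
    expect_equal(sum(p[paste0(c("a_f_", "a_w_", "a_fr_", "a_cr_"), s)]), 1)
  }
  expect_error(param_vector(stats::setNames(rep(-1, 36), param_names())),
               "positive")
  expect_error(validate_parameters(params_with(rf_f_wet = 1.2)), "< 1")
  expect_error(validate_parameters(default_parameters(), hard_bounds = TRUE),
               "outside prior range")
  expect_silent(validate_parameters(default_parameters("prior"),
                                    hard_bounds = TRUE))
})
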