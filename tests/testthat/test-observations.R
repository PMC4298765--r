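# Observation operators, eddy-covariance aggregation filters, steady-state
# pseudo-observations and the misfit/likelihood arithmetic.

make_halfhourly <- function(date = as.Date("2005-06-01"), fc = rep(0.01, 48),
                            sfc = rep(0, 48), ustar = rep(0.3, 48),
                            slots = 0:47) {
  tibble::tibble(
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + slots * 1800,
    fc = fc[slots + 1], sfc = sfc[slots + 1], ustar = ustar[slots + 1],
    is_night = slots < 12 | slots >= 36)
}

test_that("uniform half-hour fluxes sum to the daily value", {
  out <- aggregate_daily_nee(make_halfhourly())
  expect_equal(out$value, 0.48)
  expect_equal(out$n_used, 48L)
})

test_that("short days and low-u* night records are filtered", {
  # 39 surviving half hours -> day excluded
  out <- aggregate_daily_nee(make_halfhourly(slots = 0:38))
  expect_equal(nrow(out), 0)
  # exactly 40 -> retained
  out40 <- aggregate_daily_nee(make_halfhourly(slots = 0:39))
  expect_equal(nrow(out40), 1)

  # u* below threshold at night removes the record before counting:
  # 9 low-u* night records leave 39 survivors -> day dropped
  u <- rep(0.3, 48); u[1:9] <- 0.10
  expect_equal(nrow(aggregate_daily_nee(make_halfhourly(ustar = u))), 0)
  # same u* pattern by day (slots 12:20) is not filtered
  u2 <- rep(0.3, 48); u2[13:21] <- 0.10
  expect_equal(nrow(aggregate_daily_nee(make_halfhourly(ustar = u2))), 1)
})

test_that("gap filling uses day/night means and spikes are removed", {
  # drop 4 day slots and 4 night slots; fill with the respective means
  slots <- setdiff(0:47, c(0:3, 20:23))
  fc <- numeric(48); fc[13:36] <- -0.2; fc[c(1:12, 37:48)] <- 0.05
  out <- aggregate_daily_nee(make_halfhourly(fc = fc, slots = slots))
  day_mean <- mean(fc[13:36][-(8:11)])
  night_mean <- mean(fc[c(1:12, 37:48)][-(1:4)])
  expect_equal(out$value, sum(fc[slots + 1]) + 4 * day_mean + 4 * night_mean)

  # a large spike among many clean days is filtered (10 SD rule)
  days <- lapply(1:30, function(i) {
    make_halfhourly(date = as.Date("2005-06-01") + i,
                    fc = rep(0.01, 48) + rnorm(48, 0, 0.001))
  })
  clean <- do.call(rbind, days)
  spiked <- clean
  spiked$fc[100] <- 50
  agg_clean <- aggregate_daily_nee(clean)
  agg_spiked <- aggregate_daily_nee(spiked)
  expect_lt(max(abs(agg_spiked$value)), 1)
  # the spiked day is gap-filled, others identical
  same <- agg_spiked$date != as.Date("2005-06-04")  # row 100 falls on day 3
  expect_equal(agg_spiked$value[same], agg_clean$value[same])

  # permuting within-day record order changes nothing
  set.seed(2)
  perm <- clean[sample(nrow(clean)), ]
  expect_equal(aggregate_daily_nee(perm), agg_clean)
})

test_that("observation operators map trajectories to streams", {
  sy <- small_synth()
  traj <- sy$truth$trajectory

  # LAI conversion
  ob <- tibble::tibble(date = traj$dates[c(10, 100)], value = 0, se = 1)
  expect_equal(predict_stream(traj, "lai", ob),
               traj$pools$c_f[c(10, 100)] / 61.035)

  # component respiration and soil-chamber split
  expect_equal(predict_stream(traj, "leaf_resp", ob), traj$fluxes$r_f[c(10, 100)])
  het <- predict_stream(traj, "soil_resp_het", ob)
  aut <- predict_stream(traj, "soil_resp_aut", ob)
  expect_equal(het + aut,
               (traj$fluxes$r_lit + traj$fluxes$r_som +
                  traj$fluxes$r_fr + traj$fluxes$r_cr)[c(10, 100)])

  # aboveground biomass = foliage + wood
  expect_equal(predict_stream(traj, "agb", ob),
               (traj$pools$c_f + traj$pools$c_w)[c(10, 100)])

  # monthly litterfall operator sums daily foliage turnover
  obm <- tibble::tibble(year = 2004, month = 3, value = 0, se = 1)
  mar <- format(traj$dates, "%Y-%m") == "2004-03"
  expect_equal(predict_stream(traj, "litterfall", obm),
               sum(traj$fluxes$litterfall[mar]))

  # constant trajectory: month sum = days * t_f * c_f
  d <- constant_driver(90, start = "2004-01-01")
  p <- null_dynamics_params(t_f_wet = 1e-5)
  tr <- run_forward(p, d, rep(FALSE, 90), flat_moisture(), gpp_config(g_max = 0))
  obf <- tibble::tibble(year = 2004, month = 2, value = 0, se = 1)
  # c_f decays slowly under pure turnover, hence the loose tolerance
  expect_equal(predict_stream(tr, "litterfall", obf),
               29 * 1e-5 * initial_pools(p)[["c_f"]], tolerance = 1e-3)

  # growth-ratio operator: dry/wet mean wood growth input per year
  oby <- tibble::tibble(year = 2004, value = 0, se = 1)
  yr <- format(traj$dates, "%Y") == "2004"
  gw <- traj$fluxes$growth_w
  expect_equal(predict_stream(traj, "growth_ratio", oby),
               mean(gw[yr & traj$dry]) / mean(gw[yr & !traj$dry]))

  expect_error(predict_stream(traj, "unknown", ob), "unknown stream")
})

test_that("growth ratio from the reference medians is near the observed 0.40", {
  # hand arithmetic: seasonal wood allocation flux times the unrespired
  # fraction gives the wood growth input; their dry/wet ratio matches the
  # assimilated stem-growth seasonality of 0.40 +/- 0.09
  tab <- site_parameter_table()
  fl <- site_flux_table()
  g <- function(nm, col) tab[[col]][tab$name == nm]
  a <- function(col) fl[[col]][fl$quantity == "alloc_w"]
  wet <- a("wet_mean") * (1 - g("rf_w", "pos_wet"))   # 2.36 * 0.39
  dry <- a("dry_mean") * (1 - g("rf_w", "pos_dry"))   # 1.88 * 0.20
  expect_equal(dry / wet, 0.4085, tolerance = 1e-3)
  expect_lt(abs(dry / wet - 0.40), 0.09)
})

test_that("steady-state pseudo-observations scale with initial stocks", {
  sy <- small_synth()
  traj <- sy$truth$trajectory
  ss <- steady_state_pseudo_obs(traj)
  expect_equal(ss$se, 0.02 * as.numeric(traj$init_pools))
  expect_equal(ss$se[ss$pool == "c_som"],
               0.02 * as.numeric(default_parameters()["c_som0"]))
  expect_equal(ss$observed, rep(0, 7))
  expect_equal(ss$predicted,
               as.numeric(traj$pools[nrow(traj$pools), ]) -
                 as.numeric(traj$init_pools))
  # a pool growing by exactly one SE has standardized residual 1
  z <- (ss$predicted - ss$observed) / ss$se
  expect_equal(z[2], ss$predicted[2] / (0.02 * traj$init_pools[["c_w"]]))
})

test_that("misfit arithmetic, additivity and ordering invariance", {
  ob1 <- obs_stream("nee", tibble::tibble(date = as.Date("2004-01-05"),
                                          value = 2, se = 1))
  # (M - O)/E = 2 -> data term 4, log-likelihood -2
  mf <- misfit(list(nee = 4), list(nee = ob1))
  expect_equal(mf$data_term, 4)
  expect_equal(mf$loglik, -2)

  # prior term: one parameter displaced by one log-SD
  p <- default_parameters("prior", normalize = FALSE)
  ps <- prior_spec()
  p2 <- stats::setNames(as.numeric(p), param_names())
  p2["d_lit"] <- p2["d_lit"] * exp(ps$sigma_log[["d_lit"]])
  mf2 <- misfit(list(nee = ob1$value), list(nee = ob1), ps,
                param_vector(p2, normalize = FALSE))
  expect_equal(mf2$prior_term, 1, tolerance = 1e-12)
  expect_equal(mf2$data_term, 0)

  # exact match and prior medians give zero misfit
  mf0 <- misfit(list(nee = ob1$value), list(nee = ob1), ps, p)
  expect_equal(mf0$total, 0)
  expect_equal(mf0$loglik, 0)

  # additive across streams, invariant to row order
  sy <- small_synth()
  streams <- sy$obs$streams
  traj <- sy$truth$trajectory
  preds <- lapply(names(streams), function(id)
    predict_stream(traj, id, streams[[id]]))
  names(preds) <- names(streams)
  mfa <- misfit(preds, streams)
  expect_equal(mfa$data_term, sum(mfa$per_stream))
  shuf <- streams
  set.seed(9)
  ix <- sample(nrow(shuf$nee))
  shuf$nee <- shuf$nee[ix, ]
  preds2 <- preds
  preds2$nee <- preds2$nee[ix]
  expect_equal(misfit(preds2, shuf)$data_term, mfa$data_term)

  ob_bad <- tibble::tibble(date = as.Date("2004-01-05"), value = 2, se = 0)
  expect_error(misfit(list(nee = 2), list(nee = ob_bad)), "SE")
})
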