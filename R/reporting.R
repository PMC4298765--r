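# Seasonal and annual flux accounting over stored ensemble runs, carbon use
# efficiency and derived seasonal metrics, and the site reference flux
# table they can be checked against.

#' Site reference flux and stock summary
#'
#' Published-style summary for the eastern Amazonian site: wet/dry season
#' means and mean annual sums (fluxes, g C m-2 d-1 and g C m-2 yr-1) or
#' means (stocks, g C m-2; CUE dimensionless), with SDs across 1000 stored
#' assimilation runs. Used as fixture input to [derived_metrics()].
#'
#' @return Tibble `quantity`, `kind`, `wet_mean`, `wet_sd`, `dry_mean`,
#'   `dry_sd`, `annual`, `annual_sd`.
#' @export
site_flux_table <- function() {
  r <- function(q, k, wm, ws, dm, ds, a, as.) {
    tibble::tibble(quantity = q, kind = k, wet_mean = wm, wet_sd = ws,
                   dry_mean = dm, dry_sd = ds, annual = a, annual_sd = as.)
  }
  rbind(
    r("alloc_f",  "flux",  4.01, 0.19, 3.42, 0.18, 1413.1, 54.9),
    r("alloc_w",  "flux",  2.36, 0.12, 1.88, 0.07, 818.5,  38.5),
    r("alloc_fr", "flux",  3.04, 0.22, 4.84, 0.22, 1272.6, 61.7),
    r("alloc_cr", "flux",  0.64, 0.14, 0.71, 0.18, 252.5,  43.7),
    r("r_f",      "flux",  3.13, 0.18, 3.27, 0.15, 1158.9, 54.2),
    r("r_w",      "flux",  1.48, 0.03, 1.53, 0.03, 544.2,  8.5),
    r("r_fr",     "flux",  1.42, 0.17, 1.40, 0.15, 501.3,  53.7),
    r("r_cr",     "flux",  0.49, 0.16, 0.64, 0.14, 210.8,  54.9),
    r("r_lit",    "flux",  0.40, 0.09, 0.26, 0.06, 130.8,  30.2),
    r("r_cwd",    "flux",  0.41, 0.02, 0.26, 0.01, 134.5,  6.5),
    r("r_som",    "flux",  2.23, 0.16, 1.43, 0.11, 735.0,  54.6),
    r("nee",      "flux", -0.54, 0.12, -2.11, 0.15, -341.4, 36.3),
    r("gpp",      "flux", 10.09, 0.05, 10.87, 0.05, 3756.7, 19.1),
    r("r_eco",    "flux",  9.55, 0.13, 8.77, 0.15, 3415.3, 38.5),
    r("r_a",      "flux",  6.53, 0.17, 6.83, 0.14, 2415.1, 49.7),
    r("r_h",      "flux",  3.02, 0.12, 1.93, 0.08, 1000.2, 39.1),
    r("cue",      "ratio", 0.35, 0.02, 0.37, 0.01, 0.36,   0.02),
    r("c_f",      "stock", 398,  8,    397,  8,    398,    8),
    r("c_w",      "stock", 22376, 1225, 22362, 1217, 22373, 1223),
    r("c_fr",     "stock", 465,  57,   520,  52,   480,    56),
    r("c_cr",     "stock", 2842, 717,  2841, 714,  2842,   717),
    r("c_lit",    "stock", 524,  63,   530,  63,   525,    64),
    r("c_cwd",    "stock", 2181, 364,  2179, 364,  2181,   364),
    r("c_som",    "stock", 29579, 5668, 29462, 5676, 29550, 5670)
  )
}

#' Forward-run an ensemble of stored parameter draws
#'
#' @param params_matrix Matrix of parameter draws (rows in the
#'   [param_names()] layout).
#' @param driver,mask,moisture,cfg Forward-model inputs as in
#'   [run_forward()].
#' @return List of `carbon_trajectory` objects.
#' @export
ensemble_runs <- function(params_matrix, driver, mask, moisture,
                          cfg = gpp_config()) {
  lapply(seq_len(nrow(params_matrix)), function(i) {
    p <- param_vector(stats::setNames(params_matrix[i, ], param_names()),
                      normalize = FALSE)
    run_forward(p, driver, mask, moisture, cfg)
  })
}

summarize_one_run <- function(traj, n_years) {
  dry <- traj$dry
  fx <- as.matrix(traj$fluxes)
  flux_cols <- c("alloc_f", "alloc_w", "alloc_fr", "alloc_cr",
                 "r_f", "r_w", "r_fr", "r_cr", "r_lit", "r_cwd", "r_som",
                 "nee", "gpp", "r_eco", "r_a", "r_h")
  wet_m <- colMeans(fx[!dry, flux_cols, drop = FALSE])
  dry_m <- colMeans(fx[dry, flux_cols, drop = FALSE])
  ann <- colSums(fx[, flux_cols, drop = FALSE]) / n_years

  pools <- as.matrix(traj$pools)
  st_wet <- colMeans(pools[!dry, , drop = FALSE])
  st_dry <- colMeans(pools[dry, , drop = FALSE])
  st_ann <- colMeans(pools)

  cue <- c(wet = 1 - wet_m[["r_a"]] / wet_m[["gpp"]],
           dry = 1 - dry_m[["r_a"]] / dry_m[["gpp"]],
           annual = 1 - ann[["r_a"]] / ann[["gpp"]])
  list(wet = c(wet_m, cue = cue[["wet"]], st_wet),
       dry = c(dry_m, cue = cue[["dry"]], st_dry),
       annual = c(ann, cue = cue[["annual"]], st_ann))
}

#' Seasonal and annual summary across stored ensemble runs
#'
#' For each run: wet- and dry-season daily means and annual sums of every
#' flux (annual means for stocks; CUE as one minus the autotrophic share of
#' GPP at each aggregation level), then the mean and SD across runs. The
#' annual-sum identity `annual = (wet_mean * n_wet + dry_mean * n_dry) /
#' n_years` holds for every flux row by construction.
#'
#' @param runs A `carbon_trajectory` or list of them (each carries its
#'   season mask).
#' @param n_years Number of simulated years; defaults to days/365.25.
#' @return Tibble in the [site_flux_table()] shape.
#' @export
seasonal_summary <- function(runs, n_years = NULL) {
  if (inherits(runs, "carbon_trajectory")) runs <- list(runs)
  if (length(runs) < 1) stop("need at least one stored run")
  if (is.null(n_years)) n_years <- length(runs[[1]]$dates) / 365.25
  per <- lapply(runs, summarize_one_run, n_years = n_years)
  agg <- function(part) {
    m <- do.call(rbind, lapply(per, `[[`, part))
    s <- if (nrow(m) == 1) rep(0, ncol(m)) else apply(m, 2, stats::sd)
    list(mean = colMeans(m), sd = stats::setNames(s, colnames(m)))
  }
  wet <- agg("wet"); dry <- agg("dry"); ann <- agg("annual")
  qn <- names(wet$mean)
  kind <- ifelse(qn == "cue", "ratio",
                 ifelse(qn %in% c("c_f", "c_w", "c_fr", "c_cr", "c_lit",
                                  "c_cwd", "c_som"), "stock", "flux"))
  tibble::tibble(quantity = qn, kind = kind,
                 wet_mean = unname(wet$mean), wet_sd = unname(wet$sd),
                 dry_mean = unname(dry$mean), dry_sd = unname(dry$sd),
                 annual = unname(ann$mean), annual_sd = unname(ann$sd))
}

#' Derived seasonal metrics from a flux summary
#'
#' Computes carbon use efficiency at each aggregation level, the
#' heterotrophic-to-autotrophic respiration ratio per season, wet-to-dry
#' percent changes, the net sink and its size relative to both GPP and
#' ecosystem respiration (both conventions are reported, labelled by
#' denominator), annual allocation percentages of GPP, and the consistency
#' NEE from recombining the seasonal means.
#'
#' @param fluxtab Summary tibble in the [site_flux_table()] shape.
#' @param n_wet,n_dry Wet and dry season day counts of the study window.
#' @param n_years Number of study years.
#' @return Named list of metrics (percentages on the 0-100 scale).
#' @export
derived_metrics <- function(fluxtab, n_wet = 2189, n_dry = 733, n_years = 8) {
  g <- function(q, col) fluxtab[[col]][fluxtab$quantity == q]
  wet <- function(q) g(q, "wet_mean"); dry <- function(q) g(q, "dry_mean")
  ann <- function(q) g(q, "annual")

  cue_wet <- 1 - wet("r_a") / wet("gpp")
  cue_dry <- 1 - dry("r_a") / dry("gpp")
  cue_annual <- 1 - ann("r_a") / ann("gpp")
  sink <- ann("gpp") - ann("r_eco")

  list(
    cue_wet = cue_wet, cue_dry = cue_dry, cue_annual = cue_annual,
    cue_change_pct = 100 * (cue_dry - cue_wet) / cue_wet,
    rh_ra_wet = wet("r_h") / wet("r_a"),
    rh_ra_dry = dry("r_h") / dry("r_a"),
    rh_reduction_pct = 100 * (wet("r_h") - dry("r_h")) / wet("r_h"),
    ra_increase_pct = 100 * (dry("r_a") - wet("r_a")) / wet("r_a"),
    gpp_increase_pct = 100 * (dry("gpp") - wet("gpp")) / wet("gpp"),
    gpp_increase = dry("gpp") - wet("gpp"),
    reco_decrease = wet("r_eco") - dry("r_eco"),
    ra_dry_share_of_reco_pct = 100 * dry("r_a") / dry("r_eco"),
    nee_dry_over_wet_pct = 100 * dry("nee") / wet("nee"),
    nee_annual = ann("nee"),
    nee_annual_from_seasons = (wet("nee") * n_wet + dry("nee") * n_dry) / n_years,
    sink_annual = sink,
    sink_pct_of_gpp = 100 * sink / ann("gpp"),
    sink_pct_of_reco = 100 * sink / ann("r_eco"),
    alloc_f_pct = 100 * ann("alloc_f") / ann("gpp"),
    alloc_w_pct = 100 * ann("alloc_w") / ann("gpp"),
    alloc_fr_pct = 100 * ann("alloc_fr") / ann("gpp"),
    alloc_cr_pct = 100 * ann("alloc_cr") / ann("gpp")
  )
}

#' Wet-to-dry changes of the seasonal parameters
#'
#' Percent change of each seasonal parameter's posterior median from wet to
#' dry season, reported under both conventions: relative to the wet-season
#' value, and relative to the larger of the two values.
#'
#' @param tab A parameter table in the [site_parameter_table()] shape.
#' @return Tibble `name`, `wet`, `dry`, `change_pct_of_wet`,
#'   `change_pct_of_larger`.
#' @export
seasonal_parameter_changes <- function(tab = site_parameter_table()) {
  s <- tab[tab$seasonal, ]
  tibble::tibble(
    name = s$name, wet = s$pos_wet, dry = s$pos_dry,
    change_pct_of_wet = 100 * (s$pos_wet - s$pos_dry) / s$pos_wet,
    change_pct_of_larger = 100 * abs(s$pos_wet - s$pos_dry) /
      pmax(s$pos_wet, s$pos_dry))
}

#' Posterior-median table in the site reporting layout
#'
#' @param ensemble A `posterior_ensemble`.
#' @return Tibble `name`, `median`, `lower`, `upper` with seasonal
#'   parameters on separate wet/dry rows.
#' @export
report_parameters <- function(ensemble) {
  posterior_summary(ensemble$draws)
}
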