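# Parameter vector layout and the site reference table.
#
# The model optimizes 36 quantities: 7 initial pool stocks, then
# wet/dry-season members of the allocation fractions, turnover rates and
# autotrophic respired fractions for the four live pools, the litter and
# coarse-woody-debris decomposition rates, and the heterotrophic respired
# fractions of the three dead pools.

#' Canonical ordering of the 36 optimized parameters
#'
#' Names are `<quantity>_<season>` for seasonal parameters; initial stocks
#' carry a `0` suffix. This ordering is shared by the R and compiled code
#' paths and by all matrices of posterior draws.
#'
#' @return Character vector of length 36.
#' @export
param_names <- function() {
  c("c_f0", "c_w0", "c_fr0", "c_cr0", "c_lit0", "c_cwd0", "c_som0",
    "a_f_wet", "a_f_dry", "a_w_wet", "a_w_dry",
    "a_fr_wet", "a_fr_dry", "a_cr_wet", "a_cr_dry",
    "t_f_wet", "t_f_dry", "t_w_wet", "t_w_dry",
    "t_fr_wet", "t_fr_dry", "t_cr_wet", "t_cr_dry",
    "d_lit", "d_cwd",
    "rf_f_wet", "rf_f_dry", "rf_w_wet", "rf_w_dry",
    "rf_fr_wet", "rf_fr_dry", "rf_cr_wet", "rf_cr_dry",
    "rf_lit", "rf_cwd", "rf_som")
}

#' Reference parameter table for the study site
#'
#' Prior medians, prior range descriptors (`lower`, `upper`), the log-space
#' prior SD implied by that range, and posterior medians (wet and dry season
#' for seasonal parameters) with their 15.9th/84.1th percentile bounds, for
#' an eastern Amazonian terra-firme forest. Units: stocks g C m-2;
#' allocation and respired fractions dimensionless; turnover and
#' decomposition rates fraction of pool per day.
#'
#' The range descriptors satisfy `lower = prior * exp(-sigma_log)` and
#' `upper = prior * exp(+sigma_log)` with `sigma_log` one of 0.25, 0.5,
#' 0.75, i.e. they are one prior SD in log space, not hard truncation
#' limits: several posterior medians fall outside them.
#'
#' @return A tibble with one row per base parameter (seasonal parameters
#'   appear once, with wet and dry posterior columns).
#' @export
site_parameter_table <- function() {
  tb <- function(name, seasonal, prior, lower, upper,
                 pos_wet, posl_wet, posu_wet,
                 pos_dry = NA_real_, posl_dry = NA_real_, posu_dry = NA_real_) {
    tibble::tibble(name = name, seasonal = seasonal, prior = prior,
                   lower = lower, upper = upper,
                   sigma_log = round(log(upper / prior) / 0.25) * 0.25,
                   pos_wet = pos_wet, posl_wet = posl_wet, posu_wet = posu_wet,
                   pos_dry = pos_dry, posl_dry = posl_dry, posu_dry = posu_dry)
  }
  rbind(
    tb("c_f0",   FALSE, 384,    299,    493,    421,    411,    431),
    tb("c_w0",   FALSE, 23553,  18343,  30243,  22093,  21015,  23186),
    tb("c_fr0",  FALSE, 371,    289,    476,    469,    373,    568),
    tb("c_cr0",  FALSE, 1593,   966,    2627,   2970,   1814,   4610),
    tb("c_lit0", FALSE, 300,    182,    495,    358,    264,    474),
    tb("c_cwd0", FALSE, 1738,   1354,   2232,   1948,   1550,   2649),
    tb("c_som0", FALSE, 29000,  22585,  37237,  36820,  30368,  45195),
    tb("a_f",    TRUE,  0.43,   0.26,   0.71,   0.40,   0.38,   0.42,   0.31,   0.30,   0.33),
    tb("a_w",    TRUE,  0.26,   0.16,   0.43,   0.24,   0.22,   0.26,   0.18,   0.17,   0.18),
    tb("a_fr",   TRUE,  0.23,   0.14,   0.37,   0.29,   0.25,   0.33,   0.45,   0.41,   0.47),
    tb("a_cr",   TRUE,  0.08,   0.05,   0.13,   0.06,   0.04,   0.10,   0.06,   0.04,   0.09),
    tb("t_f",    TRUE,  2.4e-3, 1.8e-3, 3.0e-3, 1.7e-3, 1.6e-3, 1.7e-3, 2.1e-3, 2.0e-3, 2.2e-3),
    tb("t_w",    TRUE,  2.5e-5, 1.9e-5, 3.2e-5, 2.2e-5, 1.8e-5, 2.6e-5, 2.4e-5, 1.9e-5, 3.1e-5),
    tb("t_fr",   TRUE,  1.4e-3, 6.5e-4, 2.9e-3, 4.5e-3, 3.5e-3, 5.7e-3, 1.5e-3, 9.1e-4, 2.2e-3),
    tb("t_cr",   TRUE,  2.5e-5, 1.5e-5, 4.1e-5, 3.8e-5, 2.1e-5, 6.4e-5, 2.8e-5, 1.8e-5, 4.5e-5),
    tb("d_lit",  FALSE, 1.0e-3, 4.7e-4, 2.1e-3, 1.1e-3, 6.7e-4, 2.0e-3),
    tb("d_cwd",  FALSE, 4.4e-5, 2.1e-5, 9.3e-5, 8.6e-5, 4.9e-5, 1.3e-4),
    tb("rf_f",   TRUE,  0.50,   0.30,   0.82,   0.78,   0.77,   0.79,   0.96,   0.93,   0.99),
    tb("rf_w",   TRUE,  0.50,   0.30,   0.82,   0.61,   0.57,   0.66,   0.80,   0.77,   0.83),
    tb("rf_fr",  TRUE,  0.50,   0.30,   0.82,   0.46,   0.36,   0.53,   0.33,   0.29,   0.37),
    tb("rf_cr",  TRUE,  0.50,   0.30,   0.82,   0.89,   0.61,   0.97,   0.65,   0.44,   0.84),
    tb("rf_lit", FALSE, 1.0e-3, 4.7e-4, 2.1e-3, 9.2e-4, 4.9e-4, 1.7e-3),
    tb("rf_cwd", FALSE, 2.0e-4, 9.4e-5, 4.2e-4, 2.3e-4, 1.7e-4, 2.9e-4),
    tb("rf_som", FALSE, 1.0e-4, 4.7e-5, 2.1e-4, 6.4e-5, 5.2e-5, 7.8e-5)
  )
}

# Expand a per-base-parameter column of the reference table to the 36-slot
# layout (seasonal rows contribute a wet and a dry slot).
expand_to_36 <- function(tab, wet_col, dry_col = wet_col) {
  out <- numeric(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$seasonal[i]) {
      out <- c(out, tab[[wet_col]][i], tab[[dry_col]][i])
    } else {
      out <- c(out, tab[[wet_col]][i])
    }
  }
  stats::setNames(out, param_names())
}

#' Construct a parameter vector
#'
#' @param x Named numeric vector covering all names in [param_names()].
#' @param normalize If `TRUE` (default) the four allocation fractions are
#'   renormalized to sum to one within each season, which mass balance
#'   requires (unallocated GPP would otherwise leak from the budget).
#' @return A named numeric vector of class `param_vector`.
#' @export
param_vector <- function(x, normalize = TRUE) {
  nm <- param_names()
  if (is.null(names(x)) || !all(nm %in% names(x))) {
    stop("parameter vector must be named and cover all 36 parameters")
  }
  p <- as.numeric(x[nm])
  names(p) <- nm
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all parameters must be finite and strictly positive")
  }
  if (normalize) p <- normalize_allocations(p)
  structure(p, class = c("param_vector", "numeric"))
}

#' Renormalize seasonal allocation fractions to sum to one
#'
#' @param p Named numeric vector in the [param_names()] layout.
#' @return The vector with `a_f + a_w + a_fr + a_cr = 1` in each season.
#' @export
normalize_allocations <- function(p) {
  for (season in c("wet", "dry")) {
    idx <- paste0(c("a_f_", "a_w_", "a_fr_", "a_cr_"), season)
    p[idx] <- p[idx] / sum(p[idx])
  }
  p
}

#' Default parameter vectors for the site
#'
#' @param which `"posterior"` for the posterior medians (the synthetic-data
#'   truth) or `"prior"` for the prior medians (the assimilation start
#'   point).
#' @param normalize Passed to [param_vector()].
#' @return A `param_vector`.
#' @export
default_parameters <- function(which = c("posterior", "prior"), normalize = TRUE) {
  which <- match.arg(which)
  tab <- site_parameter_table()
  x <- if (which == "prior") {
    expand_to_36(tab, "prior", "prior")
  } else {
    expand_to_36(tab, "pos_wet", "pos_dry")
  }
  param_vector(x, normalize = normalize)
}

#' Prior medians, log-space SDs and range descriptors in 36-slot layout
#'
#' @return A list with numeric vectors `median`, `sigma_log`, `lower`,
#'   `upper`, each of length 36 and named by [param_names()].
#' @export
prior_spec <- function() {
  tab <- site_parameter_table()
  list(median = expand_to_36(tab, "prior"),
       sigma_log = expand_to_36(tab, "sigma_log"),
       lower = expand_to_36(tab, "lower"),
       upper = expand_to_36(tab, "upper"))
}

#' Validate a parameter vector
#'
#' Checks positivity, finiteness and (optionally) the prior range
#' descriptors. The range check is informational by default because the
#' site posterior itself exceeds some ranges.
#'
#' @param p Parameter vector.
#' @param hard_bounds If `TRUE`, error when any value falls outside
#'   `[lower, upper]`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_parameters <- function(p, hard_bounds = FALSE) {
  nm <- param_names()
  stopifnot(all(nm %in% names(p)))
  p <- p[nm]
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("parameters must be finite and strictly positive")
  }
  rf <- p[grep("^rf_(f|w|fr|cr)_", nm)]
  if (any(rf >= 1)) stop("autotrophic respired fractions must be < 1")
  if (hard_bounds) {
    ps <- prior_spec()
    bad <- which(p < ps$lower | p > ps$upper)
    if (length(bad)) {
      stop("parameters outside prior range: ", paste(nm[bad], collapse = ", "))
    }
  }
  invisible(TRUE)
}

# Season-resolved 13-slot view used by the R reference stepper.
season_params <- function(p, season = c("wet", "dry")) {
  season <- match.arg(season)
  s <- function(base) unname(p[paste0(base, "_", season)])
  list(a_f = s("a_f"), a_w = s("a_w"), a_fr = s("a_fr"), a_cr = s("a_cr"),
       t_f = s("t_f"), t_w = s("t_w"), t_fr = s("t_fr"), t_cr = s("t_cr"),
       rf_f = s("rf_f"), rf_w = s("rf_w"), rf_fr = s("rf_fr"), rf_cr = s("rf_cr"),
       d_lit = unname(p["d_lit"]), d_cwd = unname(p["d_cwd"]),
       rf_lit = unname(p["rf_lit"]), rf_cwd = unname(p["rf_cwd"]),
       rf_som = unname(p["rf_som"]))
}

#' Initial pool stocks from a parameter vector
#'
#' @param p Parameter vector.
#' @return Named numeric vector of the seven pools (g C m-2).
#' @export
initial_pools <- function(p) {
  stats::setNames(as.numeric(p[c("c_f0", "c_w0", "c_fr0", "c_cr0",
                                 "c_lit0", "c_cwd0", "c_som0")]),
                  c("c_f", "c_w", "c_fr", "c_cr", "c_lit", "c_cwd", "c_som"))
}
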