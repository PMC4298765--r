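# Metropolis-Hastings sampling of the 36-parameter posterior. Parameters
# are strictly positive with log-normal priors, so proposals are random
# walks in log space; the four allocation fractions are renormalized to sum
# to one within each season after every proposal.

#' Chain configuration
#'
#' Site-scale defaults match the full analysis (1.2 million steps, 200 000
#' burn-in, proposal SD 0.004 in log space, six chains, 1000 stored runs).
#' [desk_chain_config()] gives the scaled-down setting used for tests and
#' twin experiments.
#'
#' @param n_steps Chain length.
#' @param burn_in Steps discarded before summarization (< `n_steps`).
#' @param step_sd Log-space proposal SD.
#' @param n_chains Number of independent chains.
#' @param seed Root RNG seed; chain `i` uses `seed + i`.
#' @param store_runs Number of posterior draws whose forward runs are kept.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param hard_bounds Reject proposals outside the prior range descriptors.
#'   Off by default: the ranges are one prior SD in log space, not
#'   truncation limits, and the site posterior itself exceeds several of
#'   them.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_steps = 1200000, burn_in = 200000,
                         step_sd = 0.004, n_chains = 6, seed = 1,
                         store_runs = 1000, thin = 1, hard_bounds = FALSE) {
  stopifnot(burn_in < n_steps, step_sd >= 0, n_chains >= 1, thin >= 1)
  structure(list(n_steps = n_steps, burn_in = burn_in, step_sd = step_sd,
                 n_chains = n_chains, seed = seed, store_runs = store_runs,
                 thin = thin, hard_bounds = hard_bounds),
            class = "chain_config")
}

#' @rdname chain_config
#' @export
desk_chain_config <- function(n_steps = 50000, burn_in = 10000,
                              step_sd = 0.004, n_chains = 3, seed = 1,
                              store_runs = 200, thin = 5, hard_bounds = FALSE) {
  chain_config(n_steps, burn_in, step_sd, n_chains, seed, store_runs, thin,
               hard_bounds)
}

ALLOC_WET_IDX <- c(8L, 10L, 12L, 14L)
ALLOC_DRY_IDX <- c(9L, 11L, 13L, 15L)

#' Propose a new parameter vector
#'
#' Perturbs each of the 36 log-parameters independently by
#' `Normal(0, step_sd)` and renormalizes the seasonal allocation fractions.
#'
#' @param current Numeric vector of 36 parameters.
#' @param step_sd Log-space proposal SD.
#' @return Proposed parameter vector (same names/order).
#' @export
propose <- function(current, step_sd) {
  q <- current * exp(stats::rnorm(length(current), 0, step_sd))
  q[ALLOC_WET_IDX] <- q[ALLOC_WET_IDX] / sum(q[ALLOC_WET_IDX])
  q[ALLOC_DRY_IDX] <- q[ALLOC_DRY_IDX] / sum(q[ALLOC_DRY_IDX])
  q
}

#' One Metropolis-Hastings accept/reject decision
#'
#' Accepts the proposal with probability `min(1, exp(delta))` where `delta`
#' is the log-posterior difference; a proposal with log-posterior `-Inf`
#' (e.g. a forward run that drove a pool negative) is never accepted.
#'
#' @param current Current state.
#' @param proposal Proposed state.
#' @param loglik_fn Log-posterior function (finite or `-Inf`).
#' @param current_loglik Optionally the already-known log-posterior of
#'   `current`, to avoid recomputation.
#' @return List `state`, `loglik`, `accepted`.
#' @export
mh_step <- function(current, proposal, loglik_fn, current_loglik = NULL) {
  lp <- if (is.null(current_loglik)) loglik_fn(current) else current_loglik
  lq <- loglik_fn(proposal)
  if (!is.finite(lp) && !is.finite(lq)) {
    stop("chain cannot start: both states have log-posterior -Inf")
  }
  accept <- is.finite(lq) && (lq >= lp || log(stats::runif(1)) < lq - lp)
  if (accept) list(state = proposal, loglik = lq, accepted = TRUE)
  else list(state = current, loglik = lp, accepted = FALSE)
}

#' Generic random-walk Metropolis sampler
#'
#' Used for correctness checks on analytic targets; [run_chain()] is the
#' model-specific driver.
#'
#' @param loglik_fn Log-density of the target.
#' @param init Initial state (numeric vector).
#' @param n_steps,burn_in Chain length and discarded prefix.
#' @param step_sd Proposal SD (raw space, Gaussian).
#' @param seed RNG seed.
#' @return List `draws` (matrix), `acceptance`.
#' @export
run_mh <- function(loglik_fn, init, n_steps, burn_in = 0, step_sd = 1,
                   seed = 1) {
  set.seed(seed)
  d <- length(init)
  x <- as.numeric(init)
  lp <- loglik_fn(x)
  if (!is.finite(lp)) stop("chain cannot start: initial log-density is -Inf")
  keep <- n_steps - burn_in
  draws <- matrix(NA_real_, keep, d)
  acc <- 0L
  for (s in seq_len(n_steps)) {
    q <- x + stats::rnorm(d, 0, step_sd)
    lq <- loglik_fn(q)
    if (is.finite(lq) && (lq >= lp || log(stats::runif(1)) < lq - lp)) {
      x <- q; lp <- lq; acc <- acc + 1L
    }
    if (s > burn_in) draws[s - burn_in, ] <- x
  }
  list(draws = draws, acceptance = acc / n_steps)
}

#' Run one Metropolis-Hastings chain on the model posterior
#'
#' Random-walk proposals in log space with seasonal-allocation
#' renormalization, starting from the prior medians. Rejected steps repeat
#' the current state. Post-burn-in draws are retained (optionally thinned)
#' and a uniformly random subset of `store_runs` draws is flagged for
#' forward-run storage.
#'
#' @param cfg A [chain_config()].
#' @param loglik_fn Log-posterior over the 36-parameter vector (finite or
#'   `-Inf`).
#' @param init Initial parameter vector (default: prior medians).
#' @param seed Seed for this chain (default `cfg$seed`).
#' @return List `draws` (matrix, named columns), `acceptance`,
#'   `stored_params` (matrix of the randomly selected draws), `loglik`
#'   (trace of retained draws).
#' @export
run_chain <- function(cfg, loglik_fn, init = NULL, seed = cfg$seed) {
  set.seed(seed)
  if (is.null(init)) init <- default_parameters("prior")
  x <- unname(as.numeric(init[param_names()]))
  lp <- loglik_fn(x)
  if (!is.finite(lp)) stop("chain cannot start: initial log-posterior is -Inf")
  ps <- prior_spec()
  lower <- unname(ps$lower); upper <- unname(ps$upper)
  rf_ix <- 26:33  # autotrophic respired fractions must stay below 1

  keep <- (cfg$n_steps - cfg$burn_in) %/% cfg$thin
  draws <- matrix(NA_real_, keep, 36)
  ll <- numeric(keep)
  acc <- 0L
  j <- 0L
  for (s in seq_len(cfg$n_steps)) {
    q <- propose(x, cfg$step_sd)
    lq <- if (any(q[rf_ix] >= 1) ||
              (cfg$hard_bounds && any(q < lower | q > upper))) -Inf
          else loglik_fn(q)
    if (is.finite(lq) && (lq >= lp || log(stats::runif(1)) < lq - lp)) {
      x <- q; lp <- lq; acc <- acc + 1L
    }
    if (s > cfg$burn_in && (s - cfg$burn_in) %% cfg$thin == 0L) {
      j <- j + 1L
      draws[j, ] <- x
      ll[j] <- lp
    }
  }
  colnames(draws) <- param_names()
  stored <- draws[sort(sample.int(nrow(draws), min(cfg$store_runs, nrow(draws)))), ,
                  drop = FALSE]
  list(draws = draws, acceptance = acc / cfg$n_steps, stored_params = stored,
       loglik = ll)
}

#' Run several chains and assemble a posterior ensemble
#'
#' @param cfg A [chain_config()].
#' @param loglik_fn Log-posterior function.
#' @param init Initial parameter vector (default: prior medians).
#' @return List of class `posterior_ensemble`: `draws` (all chains pooled),
#'   `chains` (list of per-chain draw matrices), `acceptance` (per chain),
#'   `gelman_rubin` (per parameter), `summary` (tibble of percentiles),
#'   `stored_params`, `config`.
#' @export
run_chains <- function(cfg, loglik_fn, init = NULL) {
  chains <- lapply(seq_len(cfg$n_chains), function(i) {
    run_chain(cfg, loglik_fn, init = init, seed = cfg$seed + i)
  })
  draw_list <- lapply(chains, `[[`, "draws")
  pooled <- do.call(rbind, draw_list)
  gr <- if (cfg$n_chains >= 2) gelman_rubin(draw_list) else NULL
  stored <- do.call(rbind, lapply(chains, `[[`, "stored_params"))
  if (nrow(stored) > cfg$store_runs) {
    stored <- stored[sort(sample.int(nrow(stored), cfg$store_runs)), , drop = FALSE]
  }
  structure(list(draws = pooled, chains = draw_list,
                 acceptance = vapply(chains, `[[`, numeric(1), "acceptance"),
                 gelman_rubin = gr, summary = posterior_summary(pooled),
                 stored_params = stored, config = cfg),
            class = "posterior_ensemble")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance form: with `m` chains of length `n`,
#' `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, the statistic is `sqrt(((n - 1)/n * W + B/n) / W)`. Values below
#' 1.2 are taken as converged.
#'
#' @param chains List (length >= 2) of equal-length draw matrices or
#'   vectors.
#' @return Named numeric vector, one statistic per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("need at least two chains")
  mats <- lapply(chains, function(x) if (is.matrix(x)) x else matrix(x, ncol = 1))
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal post-burn-in lengths")
  k <- ncol(mats[[1]])
  out <- numeric(k)
  for (p in seq_len(k)) {
    cols <- vapply(mats, function(m) m[, p], numeric(n))
    W <- mean(apply(cols, 2, stats::var))
    B_over_n <- stats::var(colMeans(cols))
    vhat <- (n - 1) / n * W + B_over_n
    out[p] <- sqrt(vhat / W)
  }
  names(out) <- colnames(mats[[1]])
  out
}

#' Posterior percentile summary
#'
#' Empirical 50th, 15.9th and 84.1th percentiles per parameter — equivalent
#' to the median and plus/minus one SD for log-normal marginals.
#'
#' @param draws Matrix of posterior draws (columns = parameters) or a
#'   `posterior_ensemble`.
#' @return Tibble `name`, `median`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws) {
  if (inherits(draws, "posterior_ensemble")) draws <- draws$draws
  if (!is.matrix(draws)) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) == 0) stop("empty ensemble")
  q <- apply(draws, 2, stats::quantile, probs = c(0.159, 0.5, 0.841),
             names = FALSE)
  tibble::tibble(name = colnames(draws) %||% paste0("p", seq_len(ncol(draws))),
                 median = q[2, ], lower = q[1, ], upper = q[3, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat("posterior_ensemble:", nrow(x$draws), "pooled draws from",
      length(x$chains), "chain(s)\n")
  cat("  acceptance:", paste(sprintf("%.1f%%", 100 * x$acceptance), collapse = ", "), "\n")
  if (!is.null(x$gelman_rubin)) {
    cat("  max Gelman-Rubin:", round(max(x$gelman_rubin), 3), "\n")
  }
  invisible(x)
}

#' Build a fast log-posterior over the model and observation streams
#'
#' Precomputes observation indices so each evaluation is one compiled
#' forward run plus vectorized residuals. The result equals
#' [misfit()]`$loglik` applied to [predict_stream()] outputs plus the
#' steady-state pseudo-observations; a forward run that drives a pool
#' negative returns `-Inf`.
#'
#' @param streams Named list of observation tibbles.
#' @param driver Meteorological driver.
#' @param mask Season mask aligned with the driver.
#' @param moisture Normalized [moisture_response()].
#' @param cfg A [gpp_config()].
#' @param priors A [prior_spec()] (or `NULL` to omit the prior term).
#' @param steady_sd_fraction SE fraction for the steady-state
#'   pseudo-observations; `NULL` disables them.
#' @param t_ref Q10 reference temperature.
#' @return Function mapping a 36-parameter numeric vector to a log-posterior.
#' @export
loglik_factory <- function(streams, driver, mask, moisture,
                           cfg = gpp_config(), priors = prior_spec(),
                           steady_sd_fraction = 0.02,
                           t_ref = T_REF_DEFAULT) {
  stopifnot(inherits(moisture, "moisture_response"), isTRUE(moisture$normalized))
  dates <- driver$date
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  dry <- as.integer(mask)
  tmin <- driver$tmin_c; tmax <- driver$tmax_c
  rad <- driver$rad_mj_m2; co2 <- driver$co2_ppm; swc <- driver$swc_m3_m3
  use_acm <- cfg$form == "acm"
  standin <- c(cfg$g_max, cfg$k, cfg$i_half)

  # flux-matrix column indices (see flux_names())
  FX <- stats::setNames(seq_along(flux_names()), flux_names())

  pre <- lapply(names(streams), function(id) {
    o <- streams[[id]]
    w <- stream_window(id)
    if (w == "daily") {
      idx <- match(as.Date(o$date), dates)
      if (any(is.na(idx))) stop("stream ", id, ": dates outside driver window")
      list(type = "daily", idx = idx, value = o$value, se = o$se)
    } else if (w == "monthly") {
      ym <- format(dates, "%Y-%m")
      key <- sprintf("%04d-%02d", o$year, o$month)
      groups <- lapply(key, function(k) which(ym == k))
      if (any(vapply(groups, length, integer(1)) == 0)) {
        stop("stream ", id, ": months outside driver window")
      }
      list(type = "monthly", groups = groups, value = o$value, se = o$se)
    } else {
      yr <- as.integer(format(dates, "%Y"))
      dry_ix <- lapply(o$year, function(y) which(yr == y & mask))
      wet_ix <- lapply(o$year, function(y) which(yr == y & !mask))
      list(type = "annual", dry_ix = dry_ix, wet_ix = wet_ix,
           value = o$value, se = o$se)
    }
  })
  names(pre) <- names(streams)

  have_prior <- !is.null(priors)
  if (have_prior) {
    log_p0 <- log(unname(priors$median))
    sig <- unname(priors$sigma_log)
  }

  function(p) {
    res <- run_forward_cpp(p, dry, tmin, tmax, rad, co2, swc, doy,
                           moisture$w_opt, moisture$s, use_acm, standin,
                           cfg$acm_coef, cfg$leaf_n, cfg$psi_d, cfg$rtot,
                           cfg$lat_deg, LEAF_C_PER_AREA, t_ref)
    if (!res$ok) return(-Inf)
    fx <- res$fluxes
    total <- 0
    for (id in names(pre)) {
      s <- pre[[id]]
      m <- switch(id,
        nee = fx[s$idx, FX[["nee"]]],
        leaf_resp = fx[s$idx, FX[["r_f"]]],
        stem_resp = fx[s$idx, FX[["r_w"]]],
        cwd_resp = fx[s$idx, FX[["r_cwd"]]],
        soil_resp_het = fx[s$idx, FX[["r_lit"]]] + fx[s$idx, FX[["r_som"]]],
        soil_resp_aut = fx[s$idx, FX[["r_fr"]]] + fx[s$idx, FX[["r_cr"]]],
        lai = res$pools[s$idx, 1] / LEAF_C_PER_AREA,
        agb = res$pools[s$idx, 1] + res$pools[s$idx, 2],
        litterfall = vapply(s$groups, function(g)
          sum(fx[g, FX[["litterfall"]]]), numeric(1)),
        growth_ratio = {
          gw <- fx[, FX[["growth_w"]]]
          vapply(seq_along(s$value), function(i)
            mean(gw[s$dry_ix[[i]]]) / mean(gw[s$wet_ix[[i]]]), numeric(1))
        },
        stop("unknown stream id: ", id))
      total <- total + sum(((m - s$value) / s$se)^2)
    }
    if (!is.null(steady_sd_fraction)) {
      start <- p[1:7]
      end <- res$pools[n, ]
      total <- total + sum(((end - start) / (steady_sd_fraction * start))^2)
    }
    if (have_prior) {
      total <- total + sum(((log(p) - log_p0) / sig)^2)
    }
    -0.5 * total
  }
}
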