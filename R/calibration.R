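#' Fit the five mean-retina summary curves of one retina
#'
#' Profiles a cell table and fits the Hill-family curves used for model
#' parameterization: fraction of cells expressing M- and S-opsin, fraction of
#' S-only-fated cells, and mean M- and S-opsin intensity, each versus D-V
#' position.
#'
#' @param table A cell table (classified on demand).
#' @param bin_width_um Profile bin width.
#' @param tau_s,tau_m Classification thresholds.
#' @return Named list of [fit_hill()] objects:
#'   `m_fraction`, `s_fraction`, `s_only_fraction`, `m_intensity`,
#'   `s_intensity`.
#' @export
profile_retina_fits <- function(table, bin_width_um = 100, tau_s = 20,
                                tau_m = 20) {
  if (all(is.na(table$class_label))) table <- classify_cells(table, tau_s, tau_m)
  sonly <- if (!all(table$fate_truth == "UNKNOWN")) {
    table$fate_truth == "S_ONLY"
  } else {
    !cec_indicator(table, tau_s, tau_m)
  }
  list(
    m_fraction = fit_hill(
      fraction_profile(table, "m", bin_width_um),
      direction = "decreasing"
    ),
    s_fraction = fit_hill(
      fraction_profile(table, "s", bin_width_um),
      direction = "increasing"
    ),
    s_only_fraction = fit_hill(
      fraction_profile(table, sonly, bin_width_um),
      direction = "increasing"
    ),
    m_intensity = fit_hill(
      intensity_profile(table, "m", bin_width_um = bin_width_um),
      value = "mean_intensity", direction = "decreasing"
    ),
    s_intensity = fit_hill(
      intensity_profile(table, "s", bin_width_um = bin_width_um),
      value = "mean_intensity", direction = "increasing"
    )
  )
}

#' Build mean-retina target curves from per-retina fits
#'
#' Averages the fitted Hill parameters across retinas, curve by curve, after
#' aligning every retina to the common S-transition midpoint (each curve's
#' midpoint is recentred by its retina's S-fraction midpoint before
#' averaging, then the mean S midpoint is restored). Parameter-wise variances
#' are returned alongside for ensemble sampling.
#'
#' @param fits A list of per-retina fit sets from [profile_retina_fits()].
#' @return A `mean_retina_targets` object: per curve, mean parameters
#'   (`base`, `amplitude`, `midpoint_um`, `n`, `direction`) and variances.
#' @export
build_mean_targets <- function(fits) {
  stopifnot(length(fits) >= 1)
  curve_names <- names(fits[[1]])
  s_mids <- purrr::map_dbl(fits, ~ .x$s_fraction$midpoint_um)
  mean_s_mid <- mean(s_mids)
  curves <- purrr::map(setNames(curve_names, curve_names), function(cn) {
    per <- purrr::imap(fits, function(f, i) {
      x <- f[[cn]]
      c(
        base = x$base, amplitude = x$amplitude,
        midpoint_um = x$midpoint_um - s_mids[[i]] + mean_s_mid,
        n = x$n
      )
    })
    mat <- do.call(rbind, per)
    list(
      base = mean(mat[, "base"]), amplitude = mean(mat[, "amplitude"]),
      midpoint_um = mean(mat[, "midpoint_um"]), n = mean(mat[, "n"]),
      direction = fits[[1]][[cn]]$direction,
      var = apply(mat, 2, function(v) if (length(v) > 1) stats::var(v) else 0)
    )
  })
  structure(curves, class = "mean_retina_targets")
}

#' @export
print.mean_retina_targets <- function(x, ...) {
  cat("<mean_retina_targets>\n")
  for (cn in names(x)) {
    cat(sprintf(
      "  %-16s %s base %.3g amp %.3g mid %.0f n %.2f\n",
      cn, x[[cn]]$direction, x[[cn]]$base, x[[cn]]$amplitude,
      x[[cn]]$midpoint_um, x[[cn]]$n
    ))
  }
  invisible(x)
}

eval_target_curve <- function(curve, y) {
  curve$base + curve$amplitude *
    hill_core(y, curve$midpoint_um, curve$n, curve$direction)
}

#' Calibration objective: distance of a simulation to the mean retina
#'
#' Profiles the simulated table (the same five observables as
#' [profile_retina_fits()], as binned values on a fixed grid) and sums the
#' squared deviations from the target curves, each curve normalized by its
#' target range over the grid. Zero iff the profiled simulation matches every
#' target exactly on the grid.
#'
#' @param sim_table A simulated cell table.
#' @param targets A [build_mean_targets()] object.
#' @param grid_um Evaluation grid spacing (default 100 um).
#' @param tau_s,tau_m Classification thresholds.
#' @return Scalar objective (>= 0); per-curve residuals in attribute
#'   `residuals`.
#' @export
calibration_objective <- function(sim_table, targets, grid_um = 100,
                                  tau_s = 20, tau_m = 20) {
  table <- classify_cells(sim_table, tau_s, tau_m)
  sonly <- if (!all(table$fate_truth == "UNKNOWN")) {
    table$fate_truth == "S_ONLY"
  } else {
    !cec_indicator(table, tau_s, tau_m)
  }
  profs <- list(
    m_fraction = fraction_profile(table, "m", grid_um),
    s_fraction = fraction_profile(table, "s", grid_um),
    s_only_fraction = fraction_profile(table, sonly, grid_um),
    m_intensity = intensity_profile(table, "m", bin_width_um = grid_um),
    s_intensity = intensity_profile(table, "s", bin_width_um = grid_um)
  )
  resid <- purrr::imap_dbl(profs, function(prof, cn) {
    if (!is.finite(targets[[cn]]$n)) {
      return(NA_real_) # degenerate target curve: excluded from the sum
    }
    val_col <- if ("fraction" %in% names(prof)) "fraction" else "mean_intensity"
    keep <- !prof$empty
    y <- prof$bin_center_um[keep]
    obs <- prof[[val_col]][keep]
    tgt <- eval_target_curve(targets[[cn]], y)
    rng <- max(diff(range(tgt)), 1e-9)
    sum(((obs - tgt) / rng)^2)
  })
  structure(sum(resid, na.rm = TRUE), residuals = resid)
}

#' Calibrate simulator rates against mean-retina targets
#'
#' Derivative-free minimization (Nelder-Mead with restarts) of
#' [calibration_objective()] over a chosen set of free rate parameters,
#' searched in log space within +/- 2 decades of the initial guess. Each
#' evaluation runs the simulator on a width-reduced strip (the D-V axis,
#' which carries all the signal, is kept at full length) with a fixed seed,
#' so the objective is deterministic given the seed. Every evaluation is
#' logged; the best configuration found within the budget is returned,
#' re-validated at `final_width_frac` scale.
#'
#' @param initial A [sim_config()] starting point.
#' @param targets A [build_mean_targets()] object.
#' @param budget Maximum number of objective evaluations (0 returns the
#'   initial configuration, flagged).
#' @param free Names of the free (log-searched) rate parameters.
#' @param search_width_frac,final_width_frac Strip-width fractions used
#'   during the search and for the final evaluation.
#' @param seed Seed shared by all evaluations (common random numbers).
#' @return A `calibration_result`: `config` (best found), `objective`,
#'   `residuals`, `trace` (tibble of evaluations), `improved` flag.
#' @export
calibrate <- function(initial, targets, budget = 100,
                      free = c("beta_M", "beta_S_high", "K_fate"),
                      search_width_frac = 0.05, final_width_frac = 0.2,
                      seed = 1L) {
  stopifnot(inherits(initial, "sim_config"))
  stopifnot(all(free %in% names(initial)))
  trace <- list()
  n_eval <- 0L

  sized_config <- function(config, frac) {
    config$domain_um[["width"]] <- max(
      initial$domain_um[["width"]] * frac,
      2 * config$hex_row_pitch_um
    )
    config
  }
  make_config <- function(logx) {
    config <- initial
    for (i in seq_along(free)) config[[free[i]]] <- unname(exp(logx[i]))
    config
  }
  fn <- function(logx) {
    if (n_eval >= budget) {
      return(NA_real_)
    }
    config <- tryCatch(validate_sim_config(make_config(logx)),
      error = function(e) NULL
    )
    if (is.null(config)) {
      return(1e6)
    }
    tab <- run_simulation(sized_config(config, search_width_frac), seed = seed)
    obj <- tryCatch(as.numeric(calibration_objective(tab, targets)),
      error = function(e) 1e6
    )
    n_eval <<- n_eval + 1L
    trace[[n_eval]] <<- c(eval = n_eval, objective = obj, setNames(exp(logx), free))
    obj
  }

  x0 <- log(unlist(initial[free]))
  best_x <- x0
  best_obj <- Inf
  if (budget > 0) {
    remaining <- function() budget - n_eval
    restarts <- 0L
    x_start <- x0
    while (remaining() > length(free) + 1 && restarts < 3) {
      opt <- tryCatch(
        stats::optim(x_start, function(x) {
          v <- fn(pmin(pmax(x, x0 - 2 * log(10)), x0 + 2 * log(10)))
          if (is.na(v)) best_obj + 1 else v
        }, method = "Nelder-Mead", control = list(maxit = remaining())),
        error = function(e) NULL
      )
      if (!is.null(opt) && opt$value < best_obj) {
        best_obj <- opt$value
        best_x <- pmin(pmax(opt$par, x0 - 2 * log(10)), x0 + 2 * log(10))
      }
      restarts <- restarts + 1L
      # restart from a jittered best point
      x_start <- best_x + stats::rnorm(length(free), 0, 0.1)
    }
  }
  trace_df <- if (length(trace) > 0) {
    tibble::as_tibble(as.data.frame(do.call(rbind, trace)))
  } else {
    tibble(eval = numeric(), objective = numeric())
  }
  improved <- is.finite(best_obj) &&
    nrow(trace_df) > 0 && best_obj < trace_df$objective[1]
  final_config <- if (improved) {
    validate_sim_config(make_config(best_x))
  } else {
    initial
  }
  final_tab <- run_simulation(
    sized_config(final_config, final_width_frac),
    seed = seed
  )
  final_obj <- calibration_objective(final_tab, targets)
  structure(
    list(
      config = final_config,
      objective = as.numeric(final_obj),
      residuals = attr(final_obj, "residuals"),
      trace = trace_df,
      improved = improved,
      budget_exhausted = n_eval >= budget
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> objective %.4g after %d evaluations%s\n",
    x$objective, nrow(x$trace),
    if (!x$improved) " [no improvement over initial]" else ""
  ))
  invisible(x)
}

#' Ensemble of simulations with perturbed parameters
#'
#' Runs `n_runs` simulations, each with the listed parameters independently
#' redrawn from normal distributions (truncated to positive) around the
#' configuration values, and computes [transition_stats()] for each run —
#' the protocol behind the retina-variability comparison (the reference
#' protocol uses 100 runs).
#'
#' @param config A [sim_config()].
#' @param param_sds Named list of standard deviations for the perturbed
#'   parameters.
#' @param n_runs Number of runs.
#' @param base_seed First seed; run `i` uses `base_seed + i - 1` for both the
#'   parameter draw and the simulation.
#' @return Tibble with one row per run: perturbed parameter values,
#'   `s_midpoint_um`, `cec_fraction_at_midpoint`, `cec_slope_at_midpoint`.
#' @export
variability_ensemble <- function(config, param_sds = list(), n_runs = 100,
                                 base_seed = config$seed) {
  stopifnot(all(names(param_sds) %in% names(config)))
  purrr::map_dfr(seq_len(n_runs), function(i) {
    seed_i <- base_seed + i - 1
    cfg <- config
    if (length(param_sds) > 0) {
      withr::local_seed(as.integer(seed_i))
      for (f in names(param_sds)) {
        s <- param_sds[[f]]
        if (s <= 0) next
        draw <- rnorm(1, config[[f]], s)
        tries <- 0L
        while (draw <= 0 && tries < 100L) {
          draw <- rnorm(1, config[[f]], s)
          tries <- tries + 1L
        }
        cfg[[f]] <- max(draw, .Machine$double.eps)
      }
    }
    tab <- run_simulation(cfg, seed = seed_i)
    stats <- transition_stats(tab)
    dplyr::bind_cols(
      tibble(run = i),
      tibble::as_tibble(cfg[names(param_sds)]),
      stats
    )
  })
}

#' Overlap coefficient of two sample distributions
#'
#' Kernel-density overlap `integral of min(f, g)`, with a shared bandwidth
#' (Silverman's rule on the pooled sample) so neither sample is smoothed
#' more than the other. 1 for identical distributions, ~0 for samples
#' separated by much more than the bandwidth.
#'
#' @param sample_a,sample_b Numeric samples.
#' @param n_grid Grid resolution for the numeric integral.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
distribution_overlap <- function(sample_a, sample_b, n_grid = 1024) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  pooled <- c(sample_a, sample_b)
  bw <- stats::bw.nrd0(pooled)
  if (bw <= 0) bw <- max(abs(pooled)) * 1e-6 + 1e-12
  lo <- min(pooled) - 4 * bw
  hi <- max(pooled) + 4 * bw
  grid <- seq(lo, hi, length.out = n_grid)
  fa <- stats::density(sample_a, bw = bw, from = lo, to = hi, n = n_grid)$y
  fb <- stats::density(sample_b, bw = bw, from = lo, to = hi, n = n_grid)$y
  dx <- grid[2] - grid[1]
  min(sum(pmin(fa, fb)) * dx, 1)
}
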