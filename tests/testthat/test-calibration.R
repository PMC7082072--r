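test_that("mean-retina targets average fitted parameters across retinas", {
  fits <- profile_retina_fits(narrow_strip())
  # identical fit sets in -> the same curves out, zero variance
  targets <- build_mean_targets(list(fits, fits))
  expect_equal(targets$s_fraction$midpoint_um, fits$s_fraction$midpoint_um)
  expect_equal(targets$m_fraction$n, fits$m_fraction$n)
  expect_true(all(vapply(targets, function(cv) all(cv$var == 0), logical(1))))
  # a single retina gives its own curves back with zero variance
  single <- build_mean_targets(list(fits))
  expect_equal(single$s_only_fraction$n, fits$s_only_fraction$n)

  # midpoints average arithmetically after S-midpoint alignment
  fits_b <- fits
  for (cn in names(fits_b)) fits_b[[cn]]$midpoint_um <- fits_b[[cn]]$midpoint_um + 300
  two <- build_mean_targets(list(fits, fits_b))
  # every curve is offset by a constant relative to its own S midpoint, so
  # alignment makes the mean midpoint of curve X = mean over retinas
  expect_equal(
    two$m_fraction$midpoint_um - two$s_fraction$midpoint_um,
    fits$m_fraction$midpoint_um - fits$s_fraction$midpoint_um
  )
  expect_equal(
    two$s_fraction$midpoint_um,
    mean(c(fits$s_fraction$midpoint_um, fits_b$s_fraction$midpoint_um))
  )
})

test_that("the calibration objective is an exact normalized least-squares sum", {
  tab <- classify_cells(narrow_strip())
  fits <- profile_retina_fits(narrow_strip())
  targets <- build_mean_targets(list(fits))
  obj <- calibration_objective(narrow_strip(), targets, grid_um = 200)
  expect_gte(as.numeric(obj), 0)
  expect_identical(length(attr(obj, "residuals")), 5L)

  # independent arithmetic oracle: recompute the sum from scratch
  oracle <- local({
    p <- cell_meta(narrow_strip())$params
    total <- 0
    curves <- list(
      m_fraction = fraction_profile(tab, "m", 200),
      s_fraction = fraction_profile(tab, "s", 200),
      s_only_fraction = fraction_profile(tab, tab$fate_truth == "S_ONLY", 200),
      m_intensity = intensity_profile(tab, "m", bin_width_um = 200),
      s_intensity = intensity_profile(tab, "s", bin_width_um = 200)
    )
    for (cn in names(curves)) {
      if (!is.finite(targets[[cn]]$n)) next
      prof <- curves[[cn]]
      val <- if ("fraction" %in% names(prof)) prof$fraction else prof$mean_intensity
      keep <- !prof$empty
      tg <- targets[[cn]]
      r <- (prof$bin_center_um[keep] / tg$midpoint_um)^tg$n
      hill <- if (tg$direction == "increasing") r / (1 + r) else 1 / (1 + r)
      pred <- tg$base + tg$amplitude * hill
      rng <- max(diff(range(pred)), 1e-9)
      total <- total + sum(((val[keep] - pred) / rng)^2)
    }
    total
  })
  expect_equal(as.numeric(obj), oracle, tolerance = 1e-10)

  # a mismatched table scores strictly worse than the table behind the targets
  shifted <- generate_cell_table(generator_params(
    strip_length_um = 6000, strip_width_um = 150,
    s_transition_midpoint_um = 2800, s_only_midpoint_um = 2800, seed = 5
  ))
  expect_gt(
    as.numeric(calibration_objective(shifted, targets, grid_um = 200)),
    as.numeric(obj)
  )
})

test_that("a zero budget returns the initial configuration flagged", {
  cfg <- sim_config(
    domain_um = c(length = 1000, width = 60, depth = 5),
    t_end = 30
  )
  fits <- profile_retina_fits(narrow_strip())
  targets <- build_mean_targets(list(fits))
  res <- calibrate(cfg, targets, budget = 0, final_width_frac = 1)
  expect_false(res$improved)
  expect_identical(res$config$beta_M, cfg$beta_M)
  expect_identical(nrow(res$trace), 0L)
})

test_that("variability ensembles perturb parameters as requested", {
  cfg <- sim_config(
    domain_um = c(length = 5000, width = 30, depth = 5),
    t_end = 100
  )
  # zero SD: configurations identical, statistics differ only by SSA noise
  ens0 <- variability_ensemble(cfg, list(beta_M = 0), n_runs = 2, base_seed = 3)
  expect_true(all(ens0$beta_M == cfg$beta_M))

  sd_in <- 5
  ens <- variability_ensemble(cfg, list(beta_M = sd_in), n_runs = 16, base_seed = 3)
  expect_identical(nrow(ens), 16L)
  expect_true(all(ens$beta_M > 0))
  # sample SD of the perturbed parameter within 4 SE of the requested SD
  se_sd <- sd_in / sqrt(2 * (16 - 1))
  expect_lt(abs(sd(ens$beta_M) - sd_in), 4 * se_sd)
  expect_true(all(is.finite(ens$cec_fraction_at_midpoint)))
})

test_that("distribution overlap matches the closed-form Gaussian value", {
  withr::local_seed(8)
  a <- rnorm(4000, 0, 1)
  expect_gt(distribution_overlap(a, rnorm(4000, 0, 1)), 0.93)
  expect_lt(distribution_overlap(a, rnorm(4000, 50, 1)), 0.01)
  # equal-variance normals a distance d apart: overlap = 2 Phi(-d / 2)
  d <- 1.5
  b <- rnorm(4000, d, 1)
  expect_lt(abs(distribution_overlap(a, b) - 2 * pnorm(-d / 2)), 0.05)
})
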