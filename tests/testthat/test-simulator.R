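test_that("the default lattice tiles the full strip with exactly 23760 cones", {
  lat <- build_hex_lattice(5000, 1000, 5000 / 330, 1000 / 72)
  expect_identical(nrow(lat), 23760L)
  expect_true(all(lat$y_um >= 0 & lat$y_um <= 5000))
  expect_true(all(lat$x_um >= 0 & lat$x_um <= 1000))
  expect_true(!is.unsorted(lat$y_um)) # dorsal -> ventral ordering
})

test_that("degenerate and regular lattice geometry behave as specified", {
  # spacing equal to the width leaves a single row spanning the length
  one_row <- build_hex_lattice(1000, 12, 10)
  expect_identical(length(unique(round(one_row$x_um, 6))), 1L)
  expect_gt(nrow(one_row), 50)
  expect_error(build_hex_lattice(10, 10, 50), "spacing")

  # true hexagonal pitch: interior nearest-neighbour distances equal spacing
  lat <- build_hex_lattice(300, 300, 20)
  interior <- lat[lat$x_um > 40 & lat$x_um < 260 & lat$y_um > 40 & lat$y_um < 260, ]
  d <- as.matrix(stats::dist(cbind(lat$x_um, lat$y_um)))
  nn <- vapply(interior$cell_id, function(i) min(d[i, -i]), numeric(1))
  expect_true(all(abs(nn - 20) < 1e-9))
})

test_that("the diffusion solver holds its fixed points and refuses unstable steps", {
  cfg <- unit_config()
  field <- init_t3_field(cfg)
  # uniform field with equal boundaries is a fixed point
  cfg_u <- unit_config(c_dorsal = 0.5, c_ventral = 0.5)
  fu <- init_t3_field(cfg_u)
  expect_equal(unclass(step_field(fu, cfg_u)), unclass(fu), tolerance = 1e-14)
  # the analytic linear ramp is stationary under Dirichlet ends
  stepped <- field
  for (i in 1:200) stepped <- step_field(stepped, cfg)
  y <- attr(field, "y_um")
  ramp <- cfg$c_dorsal + (cfg$c_ventral - cfg$c_dorsal) * y / max(y)
  expect_lt(max(abs(stepped - ramp)), 1e-6)
  expect_error(step_field(field, cfg, dt = 1e4), "stability")
})

test_that("a perturbed field relaxes to the linear ramp steady state", {
  cfg <- unit_config()
  field <- init_t3_field(cfg)
  withr::with_seed(1, {
    field[2:(nrow(field) - 1), ] <- field[2:(nrow(field) - 1), ] +
      matrix(runif((nrow(field) - 2) * ncol(field), -0.2, 0.2),
        nrow(field) - 2, ncol(field)
      )
  })
  field[field < 0] <- 0
  for (i in 1:30000) field <- step_field(field, cfg)
  y <- attr(field, "y_um")
  ramp <- cfg$c_dorsal + (cfg$c_ventral - cfg$c_dorsal) * y / max(y)
  expect_lt(max(abs(field - ramp)), 1e-6)
})

test_that("all-reflecting boundaries conserve mass exactly", {
  cfg <- unit_config()
  field <- init_t3_field(cfg)
  total0 <- sum(field)
  for (i in 1:500) field <- step_field(field, cfg, boundary = "noflux")
  expect_equal(sum(field), total0, tolerance = 1e-12)
})

test_that("the transient decay of a sine mode converges at second order", {
  # manufactured solution u = sin(pi y / L) exp(-D (pi/L)^2 t), zero ends
  L <- 1000
  D <- 100
  t_end <- 100
  err_at <- function(h) {
    cfg <- sim_config(
      domain_um = c(length = L, width = 4 * h, depth = 5),
      pde_grid_spacing_um = h, D_T3 = D, c_dorsal = 0, c_ventral = 0,
      dt_macro = 0.2 * h^2 / (4 * D)
    )
    field <- init_t3_field(cfg)
    y <- attr(field, "y_um")
    field[] <- matrix(sin(pi * y / L), nrow(field), ncol(field))
    dt <- cfg$dt_macro
    for (i in seq_len(round(t_end / dt))) field <- step_field(field, cfg, dt = dt)
    exact <- sin(pi * y / L) * exp(-D * (pi / L)^2 * t_end)
    max(abs(field[, 1] - exact))
  }
  e1 <- err_at(50)
  e2 <- err_at(25)
  ratio <- e1 / e2
  expect_gt(ratio, 3) # ~4 for a second-order scheme
  expect_lt(ratio, 5.5)
})

test_that("T3 exchange is inert when empty and hits its birth-death mean", {
  cfg <- unit_config()
  out <- exchange_t3(0, c_local = 0, cfg, dt = 100, seed = 1)
  expect_identical(out$t3_free, 0)
  expect_identical(out$net_uptake, 0L)

  # long-run mean of the uptake/release birth-death process: k_in c / k_out
  c_local <- 0.5
  expected <- cfg$k_exchange_in * c_local / cfg$k_exchange_out
  t3 <- 0
  samples <- numeric(1500)
  for (i in seq_along(samples)) {
    t3 <- exchange_t3(t3, c_local, cfg, dt = 2, seed = i, available = 1e9)$t3_free
    samples[i] <- t3
  }
  keep <- samples[-(1:50)] # discard the burn-in
  n_eff <- length(keep) / 3 # ~decorrelated every 1/k_out = 1 s, dt = 2 s
  se <- sd(keep) / sqrt(n_eff)
  expect_lt(abs(mean(keep) - expected), 3 * se + 0.5)
})

test_that("a closed cell-field system conserves molecules exactly", {
  cfg <- sim_config(
    domain_um = c(length = 200, width = 100, depth = 5),
    pde_grid_spacing_um = 50, dt_macro = 0.5,
    c_dorsal = 0.6, c_ventral = 0.6, molecules_per_conc_um3 = 0.08
  )
  field <- init_t3_field(cfg)
  vol_mol <- cfg$molecules_per_conc_um3 * conemosaic:::voxel_volume(cfg)
  cells <- c(0, 0, 0)
  voxel <- c(2L, 4L, 7L) # linear indices into the field
  total0 <- sum(field) * vol_mol + sum(cells)
  for (step in 1:10000) {
    field <- step_field(field, cfg, boundary = "noflux")
    for (j in seq_along(cells)) {
      out <- exchange_t3(cells[j], field[voxel[j]], cfg,
        dt = cfg$dt_macro,
        seed = step * 10 + j, available = floor(field[voxel[j]] * vol_mol)
      )
      cells[j] <- out$t3_free
      field[voxel[j]] <- field[voxel[j]] - out$net_uptake / vol_mol
    }
  }
  expect_true(all(field >= 0))
  expect_equal(sum(field) * vol_mol + sum(cells), total0, tolerance = 1e-9)
})

test_that("propensities match the nine reaction formulas", {
  cfg <- unit_config(
    k_on = 0.02, k_off = 1.3, thrb2_total = 200,
    k_fateS_max = 0.02, K_fate = 60, h_fate = 7, k_fateC = 0.05,
    beta_S_high = 15, beta_M = 49, K_M = 150, h_M = 3,
    beta_S_cec = 7.5, K_Srep = 50, h_Srep = 90, phi = 0.025
  )
  st <- cell_state(fate = 0, t3 = 12, ri = 150, ra = 50, s = 7, m = 3)
  a <- propensities(st, c_local = 0.4, cfg)
  hill_rep <- function(x, K, h) 1 / (1 + (x / K)^h)
  hill_act <- function(x, K, h) (x / K)^h / (1 + (x / K)^h)
  expect_equal(unname(a["bind"]), 0.02 * 12 * 150)
  expect_equal(unname(a["unbind"]), 1.3 * 50)
  expect_equal(unname(a["fate_S"]), 0.02 * hill_rep(50, 60, 7))
  expect_equal(unname(a["fate_C"]), 0.05)
  expect_equal(unname(a["s_production_S"]), 0) # U cells make no opsin
  expect_equal(unname(a["m_production_C"]), 0)
  expect_equal(unname(a["s_degradation"]), 0.025 * 7)
  expect_equal(unname(a["m_degradation"]), 0.025 * 3)

  # fate-dependent production, including the half-max M case
  st_c <- cell_state(fate = 2, t3 = 12, ri = 50, ra = 150, s = 0, m = 0)
  a_c <- propensities(st_c, 0.4, cfg)
  expect_equal(unname(a_c["m_production_C"]), 49 * hill_act(150, 150, 3))
  expect_equal(unname(a_c["m_production_C"]), 49 / 2)
  expect_equal(
    unname(a_c["s_production_C"]),
    7.5 * (50 / 200) * hill_rep(150, 50, 90)
  )
  expect_equal(unname(a_c["fate_S"]), 0)
  expect_equal(unname(a_c["fate_C"]), 0)

  st_s <- cell_state(fate = 1, t3 = 0, ri = 200, ra = 0)
  a_s <- propensities(st_s, 0, cfg)
  expect_equal(unname(a_s["s_production_S"]), 15)

  # zero active receptor: U -> S repression is fully released
  a_u0 <- propensities(cell_state(fate = 0, t3 = 0, ri = 200, ra = 0), 0, cfg)
  expect_equal(unname(a_u0["fate_S"]), 0.02)
  # everything zero except the constant U -> C channel
  cfg0 <- unit_config(
    k_on = 0, k_off = 0, k_fateS_max = 0, k_fateC = 0.05,
    beta_S_high = 0, beta_M = 0, beta_S_cec = 0, phi = 0
  )
  a0 <- propensities(cell_state(fate = 0, t3 = 0, ri = 200, ra = 0), 0, cfg0)
  expect_identical(sum(a0 > 0), 1L)
  expect_equal(unname(a0["fate_C"]), 0.05)
})

test_that("capacity factors scale only the production propensities", {
  cfg <- unit_config()
  st <- cell_state(fate = 2, t3 = 10, ri = 100, ra = 100)
  a1 <- propensities(st, 0.5, cfg, cap_s = 1, cap_m = 1)
  a2 <- propensities(st, 0.5, cfg, cap_s = 2, cap_m = 3)
  expect_equal(unname(a2["s_production_C"]), 2 * unname(a1["s_production_C"]))
  expect_equal(unname(a2["m_production_C"]), 3 * unname(a1["m_production_C"]))
  expect_equal(unname(a2["bind"]), unname(a1["bind"]))
})

test_that("the SSA is inert with zero propensities", {
  cfg0 <- unit_config(
    k_on = 0, k_off = 0, k_fateS_max = 0, k_fateC = 0,
    beta_S_high = 0, beta_M = 0, beta_S_cec = 0, phi = 0
  )
  st <- cell_state(fate = 0, t3 = 5, ri = 150, ra = 50, s = 9, m = 4)
  out <- gillespie_advance(st, 0.5, duration = 1e6, cfg0, seed = 3)
  expect_equal(unname(out), unname(st))
})

test_that("opsin birth-death statistics match the analytic stationary law", {
  # fate fixed S with only production + degradation: mean beta/phi, Fano ~ 1
  beta <- 20
  phi <- 0.1
  cfg <- unit_config(
    k_on = 0, k_off = 0, k_fateS_max = 0, k_fateC = 0,
    beta_S_high = beta, beta_M = 0, beta_S_cec = 0, phi = phi
  )
  st <- cell_state(fate = 1, t3 = 0, ri = 200, ra = 0, s = 0)
  burn <- gillespie_advance(st, 0, 100, cfg, seed = 1)
  samples <- numeric(1200)
  state <- burn
  for (i in seq_along(samples)) {
    state <- gillespie_advance(state, 0, 2, cfg, seed = 1000 + i)
    samples[i] <- state[["s_opsin"]]
  }
  m <- mean(samples)
  v <- var(samples)
  n_eff <- length(samples) / (2 / phi / 2) # correlation time 1/phi = 10 s, dt 2 s
  se_mean <- sqrt(beta / phi) / sqrt(n_eff)
  expect_lt(abs(m - beta / phi), 3 * se_mean + 1)
  expect_lt(abs(v / m - 1), 0.2) # Poisson Fano factor
})

test_that("receptor binding reaches its exact stationary distribution", {
  # T3 + R <-> R* with both totals conserved; detailed balance gives
  # P(k+1)/P(k) = kon (T0 - k)(R0 - k) / (koff (k + 1))
  kon <- 0.05
  koff <- 1
  T0 <- 30L
  R0 <- 20L
  cfg <- unit_config(
    k_on = kon, k_off = koff, thrb2_total = R0,
    k_fateS_max = 0, k_fateC = 0, beta_S_high = 0, beta_M = 0,
    beta_S_cec = 0, phi = 0
  )
  log_p <- cumsum(c(0, log(kon * (T0 - 0:(R0 - 1)) * (R0 - 0:(R0 - 1))) -
    log(koff * (1:R0))))
  p_exact <- exp(log_p - max(log_p))
  p_exact <- p_exact / sum(p_exact)

  state <- cell_state(fate = 0, t3 = T0, ri = R0, ra = 0)
  state <- gillespie_advance(state, 0, 20, cfg, seed = 5) # burn-in
  n_samp <- 20000
  counts <- integer(R0 + 1)
  conserved <- TRUE
  for (i in seq_len(n_samp)) {
    state <- gillespie_advance(state, 0, 1.0, cfg, seed = 5000 + i)
    k <- as.integer(state[["thrb2_active"]])
    counts[k + 1] <- counts[k + 1] + 1
    conserved <- conserved &&
      as.integer(state[["thrb2_inactive"]]) + k == R0
  }
  expect_true(conserved) # receptor copy number holds after every segment
  # chi-squared against the exact law over the populated states
  keep <- p_exact * n_samp >= 5
  chi2 <- sum((counts[keep] - n_samp * p_exact[keep])^2 / (n_samp * p_exact[keep]))
  df <- sum(keep) - 1
  # samples 1 s apart are nearly independent (relaxation ~ 0.03 s); allow a
  # generous factor over the chi-squared 99.9% quantile
  expect_lt(chi2, 2 * qchisq(0.999, df))
  # and the mode sits where the closed form puts it
  expect_lt(abs(which.max(counts) - which.max(p_exact)), 2)
})

test_that("simulations are deterministic and reproducible via ensembles", {
  cfg <- sim_config(
    domain_um = c(length = 600, width = 60, depth = 5),
    t_end = 20
  )
  a <- run_simulation(cfg, seed = 7)
  b <- run_simulation(cfg, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ens <- run_ensemble(cfg, n_runs = 1, base_seed = 7)
  expect_identical(as.data.frame(ens[[1]]), as.data.frame(a))
  c2 <- run_simulation(cfg, seed = 8)
  expect_false(identical(a$s_intensity, c2$s_intensity))
})

test_that("fate dynamics respect irreversibility and the single-exit race", {
  # with the CEC channel closed every decided cell is S-only
  cfg <- sim_config(
    domain_um = c(length = 1000, width = 60, depth = 5),
    k_fateC = 0, k_fateS_max = 0.1, K_fate = 1e4, t_end = 120
  )
  tab <- run_simulation(cfg, seed = 2)
  decided <- tab$fate_truth != "UNKNOWN"
  expect_gt(mean(decided), 0.9)
  expect_true(all(tab$fate_truth[decided] == "S_ONLY"))
})

test_that("the calibrated simulation reproduces the emergent patterning", {
  tab <- small_simulation()
  expect_identical(cell_meta(tab)$n_undecided, 0L)
  tabc <- classify_cells(tab)
  cec <- tabc[tabc$fate_truth == "CEC", ]
  bins <- floor(cec$y_um / 500)
  m_means <- tapply(cec$m_intensity, bins, mean)
  # mean M per CEC cell decreases dorsal -> ventral
  expect_lt(cor(seq_along(m_means), m_means, method = "spearman"), -0.9)
  # mean S per CEC cell increases ventral of the transition
  s_fit <- fit_hill(fraction_profile(tabc, "s"), direction = "increasing")
  mid <- transition_midpoint(s_fit)
  ventral <- cec[cec$y_um > mid, ]
  vbins <- floor(ventral$y_um / 400)
  s_means <- tapply(ventral$s_intensity, vbins, mean)
  expect_gt(cor(seq_along(s_means), s_means, method = "spearman"), 0.9)
  # the S transition is sharper than the M transition
  m_fit <- fit_hill(fraction_profile(tabc, "m"), direction = "decreasing")
  expect_gt(s_fit$n, m_fit$n)
})

test_that("the receptor knockout abolishes M-opsin and flattens S expression", {
  cfg <- knockout_thrb2(sim_config(
    domain_um = c(length = 5000, width = 60, depth = 5)
  ))
  expect_identical(cfg$k_on, 0)
  tab <- run_simulation(cfg, seed = 4)
  expect_identical(max(tab$m_intensity), 0)
  # S-expressing fraction has no D-V structure left
  tabc <- classify_cells(tab)
  prof <- fraction_profile(tabc, "s", bin_width_um = 250)
  fit <- fit_hill(prof)
  expect_true(fit$degenerate || fit$amplitude < 0.05)
})
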