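#' Configuration of the hybrid multiscale cone-patterning simulator
#'
#' The simulator couples a deterministic T3 (triiodothyronine) diffusion
#' field over a retinal strip to an independent stochastic reaction network
#' in each cone, sampled exactly with Gillespie's direct method. T3 diffuses
#' with constant-concentration (Dirichlet) dorsal/ventral boundaries,
#' establishing a D-V gradient in relative units; cones on a hexagonal
#' lattice randomly exchange T3 molecules with their local microenvironment.
#' Intracellular T3 binds the receptor Thr-beta-2; the active (T3-bound)
#' receptor represses commitment to the S-only fate, activates M-opsin
#' production in co-expression-competent (CEC) cells, and represses CEC
#' S-opsin production (which the inactive receptor promotes). The per-cell
#' reaction set is:
#'
#' 1. `T3 + Thrb2 -> Thrb2*` at `k_on * T3 * Thrb2_inactive`
#' 2. `Thrb2* -> Thrb2 + T3` at `k_off * Thrb2_active`
#' 3. (U only) `U -> S` at `k_fateS_max * K_fate^h / (K_fate^h + Thrb2*^h)`,
#'    `h = h_fate`
#' 4. (U only) `U -> C` at `k_fateC`
#' 5. (S fate) S-opsin production at `beta_S_high` (constitutive)
#' 6. (C fate) M-opsin production at `beta_M * Hill+(Thrb2*; K_M, h_M)`
#' 7. (C fate) S-opsin production at
#'    `beta_S_cec * (Thrb2_inactive / thrb2_total) * Hill-(Thrb2*; K_Srep, h_Srep)`
#' 8./9. first-order opsin degradation at `phi`
#'
#' Production propensities (5-7) are additionally scaled by per-cell
#' lognormal capacity factors (CV `capacity_cv`, independent for S and M),
#' modelling extrinsic expression variability; `capacity_cv = 0` disables
#' them.
#'
#' Defaults are the calibrated parameterization produced against the
#' mean-retina target curves (see the methods vignette for the recipe and
#' for what each rate controls). Rates are per second; concentrations are
#' relative units.
#'
#' @param domain_um Length (D-V), width, depth of the modeled strip.
#' @param hex_spacing_um,hex_row_pitch_um Lattice geometry; the defaults tile
#'   the full strip with exactly 23,760 cones (330 positions along D-V x 72
#'   rows across the width).
#' @param pde_grid_spacing_um Node spacing of the diffusion grid.
#' @param D_T3 Diffusion coefficient (um^2/s).
#' @param c_dorsal,c_ventral Relative T3 concentration pinned at the ends
#'   (T3 is highest dorsally).
#' @param k_exchange_in,k_exchange_out Cell/microenvironment exchange rates
#'   (molecules per unit concentration per s; per molecule per s).
#' @param k_on,k_off T3-receptor binding/unbinding rates.
#' @param thrb2_total Receptor copies per cell (conserved).
#' @param k_fateS_max,K_fate,h_fate,k_fateC Fate-decision rates: the U->S
#'   propensity is maximal at zero active receptor and repressed with
#'   coefficient `h_fate`; U->C is constant.
#' @param beta_S_high Constitutive S-opsin production of S-fated cells
#'   (position-independent).
#' @param beta_M,K_M,h_M M-opsin activation by the active receptor.
#' @param beta_S_cec,K_Srep,h_Srep CEC S-opsin production, promoted by the
#'   inactive receptor and repressed by the active one; `h_Srep` is
#'   calibrated so the emergent S transition has Hill coefficient ~30.
#' @param phi Opsin degradation rate constant (1/s).
#' @param capacity_cv CV of the per-cell extrinsic expression-capacity
#'   factors.
#' @param molecules_per_conc_um3 Conversion between relative concentration
#'   and molecule counts in a voxel.
#' @param dt_macro Operator-splitting macro time step (s); must satisfy the
#'   explicit-scheme stability bound.
#' @param t_end Simulated duration (s).
#' @param intensity_scale Arbitrary-units intensity per opsin molecule in the
#'   emitted cell table.
#' @param knockout_thrb2 If `TRUE`, receptor activation is disabled
#'   (`k_on = 0`): the receptor knockout.
#' @param seed Base RNG seed; each cell derives its own counter-based stream.
#' @return A `sim_config` list.
#' @seealso [run_simulation()], [knockout_thrb2()], [build_hex_lattice()]
#' @export
sim_config <- function(domain_um = c(length = 5000, width = 1000, depth = 5),
                       hex_spacing_um = 5000 / 330,
                       hex_row_pitch_um = 1000 / 72,
                       pde_grid_spacing_um = 50,
                       D_T3 = 100,
                       c_dorsal = 1,
                       c_ventral = 0.05,
                       k_exchange_in = 50,
                       k_exchange_out = 1,
                       k_on = 0.02,
                       k_off = 1,
                       thrb2_total = 200L,
                       k_fateS_max = 0.05 / 3,
                       K_fate = 58.5,
                       h_fate = 7.5,
                       k_fateC = 0.05,
                       beta_S_high = 15,
                       beta_M = 49,
                       K_M = 150,
                       h_M = 3,
                       beta_S_cec = 7.5,
                       K_Srep = 55,
                       h_Srep = 90,
                       phi = 0.025,
                       capacity_cv = 0.5,
                       molecules_per_conc_um3 = 10,
                       dt_macro = 0.5,
                       t_end = 250,
                       intensity_scale = 1,
                       knockout_thrb2 = FALSE,
                       seed = 1L) {
  if (is.null(names(domain_um))) names(domain_um) <- c("length", "width", "depth")
  config <- list(
    domain_um = domain_um,
    hex_spacing_um = hex_spacing_um,
    hex_row_pitch_um = hex_row_pitch_um,
    pde_grid_spacing_um = pde_grid_spacing_um,
    D_T3 = D_T3, c_dorsal = c_dorsal, c_ventral = c_ventral,
    k_exchange_in = k_exchange_in, k_exchange_out = k_exchange_out,
    k_on = k_on, k_off = k_off, thrb2_total = as.integer(thrb2_total),
    k_fateS_max = k_fateS_max, K_fate = K_fate, h_fate = h_fate,
    k_fateC = k_fateC,
    beta_S_high = beta_S_high,
    beta_M = beta_M, K_M = K_M, h_M = h_M,
    beta_S_cec = beta_S_cec, K_Srep = K_Srep, h_Srep = h_Srep,
    phi = phi, capacity_cv = capacity_cv,
    molecules_per_conc_um3 = molecules_per_conc_um3,
    dt_macro = dt_macro, t_end = t_end,
    intensity_scale = intensity_scale,
    knockout_thrb2 = isTRUE(knockout_thrb2),
    seed = as.integer(seed)
  )
  if (config$knockout_thrb2) config$k_on <- 0
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  rates <- c(
    "D_T3", "k_exchange_in", "k_exchange_out", "k_on", "k_off",
    "k_fateS_max", "k_fateC", "beta_S_high", "beta_M", "beta_S_cec", "phi"
  )
  for (f in rates) {
    if (!is.numeric(config[[f]]) || config[[f]] < 0) {
      abort(sprintf("sim_config$%s must be >= 0", f))
    }
  }
  for (f in c("h_fate", "h_M", "h_Srep")) {
    if (config[[f]] <= 0) abort(sprintf("sim_config$%s must be > 0", f))
  }
  for (f in c("K_fate", "K_M", "K_Srep")) {
    if (config[[f]] <= 0) abort(sprintf("sim_config$%s must be > 0", f))
  }
  if (config$c_dorsal < 0 || config$c_ventral < 0) {
    abort("boundary concentrations must be >= 0")
  }
  if (any(config$domain_um <= 0)) abort("domain dimensions must be > 0")
  if (config$thrb2_total < 1) abort("thrb2_total must be >= 1")
  if (config$capacity_cv < 0) abort("capacity_cv must be >= 0")
  if (config$dt_macro <= 0 || config$t_end <= 0) {
    abort("dt_macro and t_end must be > 0")
  }
  h <- config$pde_grid_spacing_um
  if (config$D_T3 > 0 && config$dt_macro > h^2 / (4 * config$D_T3)) {
    abort(sprintf(
      "dt_macro = %g violates the explicit stability bound h^2/(4D) = %g",
      config$dt_macro, h^2 / (4 * config$D_T3)
    ))
  }
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %g x %g x %g um strip, t_end %gs, dt %gs%s\n",
    x$domain_um[["length"]], x$domain_um[["width"]], x$domain_um[["depth"]],
    x$t_end, x$dt_macro, if (x$knockout_thrb2) " [Thrb2 knockout]" else ""
  ))
  invisible(x)
}

#' Thr-beta-2 knockout configuration
#'
#' Returns the configuration with receptor activation disabled (`k_on = 0`)
#' and all other parameters intact: the active receptor never forms, so the
#' U->S fate propensity runs at its maximum everywhere, M-opsin production is
#' zero, and CEC S-opsin production runs at its repression-free level.
#'
#' @param config A [sim_config()].
#' @return The knockout configuration.
#' @export
knockout_thrb2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$k_on <- 0
  config$knockout_thrb2 <- TRUE
  config
}

#' Hexagonal cone lattice
#'
#' Positions cones hexagonally: positions along the D-V axis at `spacing_um`
#' within each row, rows stacked across the strip width at `row_pitch_um`
#' (default `spacing * sqrt(3)/2`, the regular hexagonal pitch), alternate
#' rows offset by half a spacing. Cells are ordered dorsal to ventral. The
#' default full-strip configuration tiles exactly 23,760 cones.
#'
#' @param length_um,width_um Strip dimensions.
#' @param spacing_um Within-row (nearest-neighbour) spacing.
#' @param row_pitch_um Row separation.
#' @return Tibble with `cell_id`, `x_um`, `y_um`.
#' @export
build_hex_lattice <- function(length_um, width_um, spacing_um,
                              row_pitch_um = spacing_um * sqrt(3) / 2) {
  stopifnot(spacing_um > 0, row_pitch_um > 0)
  if (spacing_um >= length_um && row_pitch_um >= width_um) {
    abort("lattice spacing must be smaller than the domain")
  }
  n_y <- max(1L, floor(length_um / spacing_um + 1e-9))
  n_rows <- max(1L, floor(width_um / row_pitch_um + 1e-9))
  row <- rep(seq_len(n_rows), each = n_y)
  pos <- rep(seq_len(n_y), times = n_rows)
  y <- (pos - 1) * spacing_um + spacing_um / 4 +
    ifelse(row %% 2 == 0, spacing_um / 2, 0)
  x <- (row - 0.5) * row_pitch_um
  out <- tibble(x_um = x, y_um = y) |>
    dplyr::arrange(.data$y_um, .data$x_um) |>
    dplyr::mutate(cell_id = dplyr::row_number(), .before = 1)
  out
}

#' Steady-state T3 field
#'
#' The diffusion field on the node grid, initialized at its analytic steady
#' state: the linear ramp `c(y) = c_dorsal + (c_ventral - c_dorsal) * y / L`
#' (the adult gradient is maintained; its developmental establishment is not
#' modeled).
#'
#' @param config A [sim_config()].
#' @return A `t3_field`: matrix (rows = D-V nodes) with grid metadata
#'   attributes.
#' @export
init_t3_field <- function(config) {
  h <- config$pde_grid_spacing_um
  len <- config$domain_um[["length"]]
  wid <- config$domain_um[["width"]]
  n_y <- round(len / h) + 1
  n_x <- round(wid / h) + 1
  y <- seq(0, len, length.out = n_y)
  ramp <- config$c_dorsal + (config$c_ventral - config$c_dorsal) * y / len
  field <- matrix(ramp, nrow = n_y, ncol = n_x)
  structure(field,
    grid_spacing_um = h, y_um = y,
    class = c("t3_field", "matrix", "array")
  )
}

#' One explicit diffusion step
#'
#' Forward-Euler step of the 2D diffusion equation with the 5-point stencil.
#' Dirichlet boundaries re-pin the dorsal/ventral node rows after the step;
#' side boundaries are zero-flux. `boundary = "noflux"` makes every boundary
#' reflecting (mass conserving; used by conservation checks). Refuses time
#' steps violating the stability bound `h^2 / (4 D)`.
#'
#' @param field Field matrix (rows = D-V).
#' @param config A [sim_config()] supplying `D_T3`, grid spacing and boundary
#'   concentrations.
#' @param dt Time step (defaults to `config$dt_macro`).
#' @param boundary `"dirichlet"` (default) or `"noflux"`.
#' @return The stepped field (attributes preserved).
#' @export
step_field <- function(field, config, dt = config$dt_macro,
                       boundary = c("dirichlet", "noflux")) {
  boundary <- match.arg(boundary)
  h <- attr(field, "grid_spacing_um") %||% config$pde_grid_spacing_um
  out <- cpp_step_field(
    unclass(field), config$D_T3, dt, h,
    config$c_dorsal, config$c_ventral,
    if (boundary == "dirichlet") 0L else 1L
  )
  attributes(out) <- attributes(field)
  out
}

#' Stochastic T3 exchange between cells and the field (single cell)
#'
#' Exact sampling of the uptake/release birth-death process for one cell over
#' `dt` against a frozen local concentration: uptake events at
#' `k_exchange_in * c_local` (capped so the voxel content cannot go
#' negative), release at `k_exchange_out * T3_free`. Exposed mainly for
#' verification; [run_simulation()] performs the same exchange for all cells
#' inside its macro loop.
#'
#' @param t3_free Current free T3 molecule count in the cell.
#' @param c_local Local relative concentration.
#' @param config A [sim_config()].
#' @param dt Duration.
#' @param seed RNG seed.
#' @param available Molecules available in the voxel (default: converted from
#'   `c_local` with the voxel volume).
#' @return List with `t3_free` (new count) and `net_uptake` (molecules moved
#'   cell-ward).
#' @export
exchange_t3 <- function(t3_free, c_local, config, dt, seed = 1,
                        available = NULL) {
  vol <- voxel_volume(config)
  available <- available %||% floor(c_local * config$molecules_per_conc_um3 * vol)
  cpp_exchange(t3_free, c_local, available, config, dt, seed)
}

voxel_volume <- function(config) {
  config$pde_grid_spacing_um^2 * config$domain_um[["depth"]]
}

#' Reaction propensities of one cell
#'
#' Evaluates the nine reaction propensities of the per-cell network (see
#' [sim_config()] for the reaction list) at a given state. Fate-dependent
#' reactions are zero outside their fate; the repressing Hill terms equal 1
#' at zero active receptor.
#'
#' @param state Named numeric vector or list with `fate` (0 = U, 1 = S,
#'   2 = C), `t3_free`, `thrb2_inactive`, `thrb2_active`, `s_opsin`,
#'   `m_opsin`.
#' @param c_local Local concentration (not used by the intracellular
#'   reactions; accepted for interface symmetry with [exchange_t3()]).
#' @param config A [sim_config()].
#' @param cap_s,cap_m Capacity factors.
#' @return Named numeric vector of 9 propensities.
#' @export
propensities <- function(state, c_local, config, cap_s = 1, cap_m = 1) {
  st <- as_state_vector(state)
  out <- cpp_propensities(st, c_local, config, cap_s, cap_m)
  names(out) <- c(
    "bind", "unbind", "fate_S", "fate_C",
    "s_production_S", "m_production_C", "s_production_C",
    "s_degradation", "m_degradation"
  )
  out
}

as_state_vector <- function(state) {
  if (is.list(state)) state <- unlist(state)
  nm <- c("fate", "t3_free", "thrb2_inactive", "thrb2_active", "s_opsin", "m_opsin")
  if (!is.null(names(state)) && all(nm %in% names(state))) {
    state <- state[nm]
  }
  stopifnot(length(state) == 6)
  as.numeric(state)
}

#' Advance one cell by exact stochastic simulation
#'
#' Gillespie's direct method over the per-cell reaction set for `duration`
#' with a frozen local concentration: exponential waiting times from the
#' total propensity, reactions chosen proportionally to their propensities.
#' Receptor conservation is asserted after every event.
#'
#' @inheritParams propensities
#' @param duration Simulated time span.
#' @param seed RNG seed.
#' @return The advanced state (named numeric vector).
#' @export
gillespie_advance <- function(state, c_local, duration, config, seed = 1,
                              cap_s = 1, cap_m = 1) {
  st <- as_state_vector(state)
  out <- cpp_gillespie(st, c_local, duration, config, seed, cap_s, cap_m)
  names(out) <- c(
    "fate", "t3_free", "thrb2_inactive", "thrb2_active", "s_opsin", "m_opsin"
  )
  out
}

#' Run the hybrid multiscale simulation
#'
#' Initializes the T3 field at its analytic steady gradient and every cone at
#' hormonal equilibrium with its local concentration (fate undifferentiated,
#' opsins zero), then iterates the time-stepping reconciliation loop: one
#' explicit diffusion step, stochastic cell/field molecule exchange, then
#' exact SSA advancement of each cell over the macro step. Net molecule
#' transfers are debited from the local field voxels. At `t_end` the cell
#' states are emitted as a cell table in the shared schema
#' (`s_intensity` / `m_intensity` = opsin counts times `intensity_scale`,
#' `fate_truth` from the fate-determinant state).
#'
#' Cells still undifferentiated at `t_end` are reported in the metadata
#' (`n_undecided`) and carry `fate_truth = "UNKNOWN"`.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [cell_table()] with `source = "simulated"` metadata.
#' @examples
#' \donttest{
#' cfg <- sim_config(domain_um = c(length = 5000, width = 100, depth = 5))
#' tab <- run_simulation(cfg)
#' dplyr::count(tab, fate_truth)
#' }
#' @export
run_simulation <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  seed <- as.integer(seed %||% config$seed)
  lattice <- build_hex_lattice(
    config$domain_um[["length"]], config$domain_um[["width"]],
    config$hex_spacing_um, config$hex_row_pitch_um
  )
  n <- nrow(lattice)
  field <- init_t3_field(config)
  h <- attr(field, "grid_spacing_um")
  node_row <- pmin(pmax(round(lattice$y_um / h) + 1L, 1L), nrow(field))
  node_col <- pmin(pmax(round(lattice$x_um / h) + 1L, 1L), ncol(field))
  node_idx <- cbind(node_row, node_col)
  lin_idx <- (node_col - 1L) * nrow(field) + node_row

  init <- cpp_init_cells(field[node_idx], config, seed, config$capacity_cv)
  state <- init$state
  caps <- init$caps

  vol_mol <- config$molecules_per_conc_um3 * voxel_volume(config)
  n_steps <- ceiling(config$t_end / config$dt_macro)
  for (step in seq_len(n_steps)) {
    field <- step_field(field, config)
    c_local <- field[node_idx]
    adv <- cpp_advance_cells(
      state, c_local, floor(c_local * vol_mol), caps,
      config$dt_macro, config, seed, step
    )
    state <- adv$state
    # debit net uptake from the voxels (concentration units)
    delta <- rowsum(as.numeric(adv$net_uptake), lin_idx)
    voxels <- as.integer(rownames(delta))
    field[voxels] <- pmax(field[voxels] - delta[, 1] / vol_mol, 0)
    # Dirichlet ends stay pinned
    field[1, ] <- config$c_dorsal
    field[nrow(field), ] <- config$c_ventral
  }

  fate <- c("UNKNOWN", "S_ONLY", "CEC")[state[, 1] + 1]
  tab <- cell_table(
    tibble(
      cell_id = lattice$cell_id,
      x_um = lattice$x_um,
      y_um = lattice$y_um,
      area_um2 = pi * (config$hex_spacing_um / 2 * 0.6)^2,
      s_intensity = state[, 5] * config$intensity_scale,
      m_intensity = state[, 6] * config$intensity_scale,
      class_label = NA_character_,
      fate_truth = fate
    ),
    meta = list(
      source = "simulated",
      strip_length_um = unname(config$domain_um[["length"]]),
      strip_width_um = unname(config$domain_um[["width"]]),
      config = config,
      seed = seed,
      n_undecided = sum(state[, 1] == 0)
    )
  )
  tab
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` simulations with seeds `base_seed + run - 1`; each output is
#' a cell table suitable for profiling-module aggregation. With `n_runs = 1`
#' and the same seed this reproduces [run_simulation()] exactly.
#'
#' @param config A [sim_config()].
#' @param n_runs Number of runs (the reference protocol uses 100).
#' @param base_seed First seed.
#' @return List of cell tables.
#' @export
run_ensemble <- function(config = sim_config(), n_runs = 100,
                         base_seed = config$seed) {
  purrr::map(
    seq_len(n_runs),
    function(i) run_simulation(config, seed = base_seed + i - 1)
  )
}
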