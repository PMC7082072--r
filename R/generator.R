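#' Parameters for the synthetic retina generator
#'
#' Bundles the statistical description of a mouse retinal strip that the
#' generator emulates: a jittered hexagonal cone mosaic along a
#' dorsal-ventral (D-V) strip, a binary S-only vs co-expression-competent
#' (CEC) fate split whose S-only probability rises from ~1% dorsally to
#' ~20-30% ventrally, and position-dependent expressing fractions and
#' intensity levels for S- and M-opsin.
#'
#' The expressing-fraction parameters describe the *observable* transitions
#' (fractions of all cones expressing each opsin versus D-V position), the
#' quantities obtained by profiling real images: the S-opsin fraction is an
#' extremely sharp Hill transition (coefficient ~30) and the M-opsin fraction
#' a gradual one (coefficient ~2-3). The per-cell CEC Bernoulli probabilities
#' are derived from these targets (see [cec_s_probability()]), so that
#' profiling a default table recovers the stated coefficients.
#'
#' @param strip_length_um,strip_width_um Strip dimensions; the long axis is
#'   D-V with `y_um = 0` at the dorsal edge.
#' @param mean_cell_spacing_um Target nearest-neighbour spacing of the
#'   hexagonal mosaic.
#' @param s_transition_midpoint_um D-V position of the half-maximal point of
#'   the S-expressing-fraction transition.
#' @param s_fraction_hill_n Hill coefficient of the S-expressing-fraction
#'   transition (default 30).
#' @param s_fraction_base,s_fraction_amplitude Offset and rise of the total
#'   S-expressing-fraction target curve.
#' @param m_fraction_midpoint_um,m_fraction_hill_n Midpoint and coefficient
#'   (default 2.5) of the M-expressing-fraction transition.
#' @param m_fraction_base,m_fraction_amplitude Offset and fall of the total
#'   M-expressing-fraction target curve.
#' @param s_only_frac_dorsal,s_only_frac_ventral S-only fate probability at
#'   the dorsal end and its ventral plateau.
#' @param s_only_hill_n,s_only_midpoint_um Shape of the monotone S-only
#'   probability interpolant; the midpoint defaults to the S transition
#'   midpoint.
#' @param s_only_level Mean S intensity of S-only cones (arbitrary units,
#'   position-independent by default).
#' @param dorsal_s_enhancement Optional multiplicative enhancement of the
#'   S-only level at the dorsal edge, decaying linearly to 1 at the ventral
#'   end (default 1 = off).
#' @param cec_m_max Cap on the latent M intensity of CEC cones (reached at
#'   the dorsal end).
#' @param cec_s_max Latent S intensity of CEC cones at the ventral end; the
#'   level rises approximately linearly ventral of the transition.
#' @param cec_s_sdlog,cec_m_sdlog Log-scale SD of the latent CEC intensity
#'   distributions. CEC expression presence and level come from one latent
#'   lognormal draw per channel censored at `expression_threshold`, so that
#'   the expressing fractions follow the Hill targets exactly while
#'   intensities form a continuum through the detection threshold (as in
#'   real immunofluorescence) instead of jumping from background.
#' @param expression_threshold Detection threshold tying presence to level
#'   (matches the default [classify_cells()] thresholds).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise on the S-only level and the background.
#' @param background_level Mean intensity of non-expressing channels.
#' @param mean_area_um2,sd_area_um2 Outer-segment area distribution.
#' @param jitter_frac Uniform positional jitter, as a fraction of spacing.
#' @param seed RNG seed used by [generate_cell_table()].
#' @return A `generator_params` list.
#' @seealso [generate_cell_table()], [sample_retina_params()]
#' @export
generator_params <- function(strip_length_um = 6000,
                             strip_width_um = 600,
                             mean_cell_spacing_um = 8,
                             s_transition_midpoint_um = 3600,
                             s_fraction_hill_n = 30,
                             s_fraction_base = 0.01,
                             s_fraction_amplitude = 0.97,
                             m_fraction_midpoint_um = 3000,
                             m_fraction_hill_n = 2.5,
                             m_fraction_base = 0.02,
                             m_fraction_amplitude = 0.95,
                             s_only_frac_dorsal = 0.01,
                             s_only_frac_ventral = 0.25,
                             s_only_hill_n = 4,
                             s_only_midpoint_um = NULL,
                             s_only_level = 700,
                             dorsal_s_enhancement = 1,
                             cec_m_max = 400,
                             cec_s_max = 250,
                             cec_s_sdlog = 0.6,
                             cec_m_sdlog = 1.1,
                             expression_threshold = 20,
                             noise_cv = 0.25,
                             background_level = 5,
                             mean_area_um2 = 20,
                             sd_area_um2 = 3,
                             jitter_frac = 0.15,
                             seed = 1L) {
  params <- list(
    strip_length_um = strip_length_um,
    strip_width_um = strip_width_um,
    mean_cell_spacing_um = mean_cell_spacing_um,
    s_transition_midpoint_um = s_transition_midpoint_um,
    s_fraction_hill_n = s_fraction_hill_n,
    s_fraction_base = s_fraction_base,
    s_fraction_amplitude = s_fraction_amplitude,
    m_fraction_midpoint_um = m_fraction_midpoint_um,
    m_fraction_hill_n = m_fraction_hill_n,
    m_fraction_base = m_fraction_base,
    m_fraction_amplitude = m_fraction_amplitude,
    s_only_frac_dorsal = s_only_frac_dorsal,
    s_only_frac_ventral = s_only_frac_ventral,
    s_only_hill_n = s_only_hill_n,
    s_only_midpoint_um = s_only_midpoint_um %||% s_transition_midpoint_um,
    s_only_level = s_only_level,
    dorsal_s_enhancement = dorsal_s_enhancement,
    cec_m_max = cec_m_max,
    cec_s_max = cec_s_max,
    cec_s_sdlog = cec_s_sdlog,
    cec_m_sdlog = cec_m_sdlog,
    expression_threshold = expression_threshold,
    noise_cv = noise_cv,
    background_level = background_level,
    mean_area_um2 = mean_area_um2,
    sd_area_um2 = sd_area_um2,
    jitter_frac = jitter_frac,
    seed = as.integer(seed)
  )
  class(params) <- "generator_params"
  validate_generator_params(params)
  params
}

validate_generator_params <- function(p) {
  positive <- c(
    "strip_length_um", "strip_width_um", "mean_cell_spacing_um",
    "s_transition_midpoint_um", "m_fraction_midpoint_um",
    "s_only_midpoint_um", "s_only_level", "cec_m_max", "cec_s_max",
    "mean_area_um2"
  )
  for (f in positive) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      abort(sprintf("generator_params$%s must be > 0", f))
    }
  }
  hill <- c("s_fraction_hill_n", "m_fraction_hill_n", "s_only_hill_n")
  for (f in hill) {
    if (p[[f]] <= 0) abort(sprintf("generator_params$%s must be > 0", f))
  }
  fracs <- c(
    "s_fraction_base", "s_fraction_amplitude", "m_fraction_base",
    "m_fraction_amplitude", "s_only_frac_dorsal", "s_only_frac_ventral",
    "jitter_frac"
  )
  for (f in fracs) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      abort(sprintf("generator_params$%s must lie in [0, 1]", f))
    }
  }
  if (p$noise_cv < 0) abort("generator_params$noise_cv must be >= 0")
  if (p$background_level < 0) abort("generator_params$background_level must be >= 0")
  if (p$dorsal_s_enhancement < 1) {
    abort("generator_params$dorsal_s_enhancement must be >= 1")
  }
  if (p$mean_cell_spacing_um >= min(p$strip_length_um, p$strip_width_um)) {
    abort("mean_cell_spacing_um must be smaller than both strip dimensions")
  }
  invisible(p)
}

#' Ground-truth probability and intensity curves of the generator
#'
#' These closed-form curves define the generator's statistical model and are
#' exported so that tests and analyses can compare binned observations against
#' the exact interpolants.
#'
#' * `s_only_probability()`: probability that a cone at position `y` is an
#'   S-only cone (monotone Hill-type rise from the dorsal value to the ventral
#'   plateau).
#' * `s_expressing_fraction()` / `m_expressing_fraction()`: expected fraction
#'   of *all* cones expressing S- (resp. M-) opsin at `y`. The S curve is the
#'   sharp transition (coefficient ~30, floored by the S-only probability
#'   since S-only cones always express S); the M curve is the gradual one
#'   (coefficient ~2-3, capped by the CEC fraction since only CEC cones can
#'   express M).
#' * `cec_s_probability()` / `cec_m_probability()`: conditional Bernoulli
#'   probabilities that a CEC cone expresses each opsin, derived from the
#'   total-fraction targets.
#' * `cec_s_intensity_mean()` / `cec_m_intensity_mean()`: noiseless mean
#'   intensities of expressing CEC cones (M decreasing D->V with midpoint at
#'   the transition; S rising approximately linearly ventral of it).
#'
#' @param y_um D-V position(s) in micrometres.
#' @param params A [generator_params()] object.
#' @return Numeric vector of probabilities or intensities.
#' @export
s_only_probability <- function(y_um, params) {
  hill_up(y_um,
    midpoint = params$s_only_midpoint_um, n = params$s_only_hill_n,
    base = params$s_only_frac_dorsal,
    amplitude = params$s_only_frac_ventral - params$s_only_frac_dorsal
  )
}

#' @rdname s_only_probability
#' @export
s_expressing_fraction <- function(y_um, params) {
  target <- hill_up(y_um,
    midpoint = params$s_transition_midpoint_um,
    n = params$s_fraction_hill_n,
    base = params$s_fraction_base,
    amplitude = params$s_fraction_amplitude
  )
  pmax(target, s_only_probability(y_um, params))
}

#' @rdname s_only_probability
#' @export
m_expressing_fraction <- function(y_um, params) {
  target <- hill_down(y_um,
    midpoint = params$m_fraction_midpoint_um,
    n = params$m_fraction_hill_n,
    base = params$m_fraction_base,
    amplitude = params$m_fraction_amplitude
  )
  pmin(target, 1 - s_only_probability(y_um, params))
}

#' @rdname s_only_probability
#' @export
cec_s_probability <- function(y_um, params) {
  p_s <- s_only_probability(y_um, params)
  target <- hill_up(y_um,
    midpoint = params$s_transition_midpoint_um,
    n = params$s_fraction_hill_n,
    base = params$s_fraction_base,
    amplitude = params$s_fraction_amplitude
  )
  pmin(pmax((target - p_s) / pmax(1 - p_s, 1e-12), 0), 1)
}

#' @rdname s_only_probability
#' @export
cec_m_probability <- function(y_um, params) {
  p_s <- s_only_probability(y_um, params)
  target <- hill_down(y_um,
    midpoint = params$m_fraction_midpoint_um,
    n = params$m_fraction_hill_n,
    base = params$m_fraction_base,
    amplitude = params$m_fraction_amplitude
  )
  pmin(pmax(target / pmax(1 - p_s, 1e-12), 0), 1)
}

# Latent location parameter (median) of a censored lognormal whose mass
# above the detection threshold equals the expressing-fraction target: the
# level and the presence of expression are two views of one latent draw, so
# intensities pass through the detection threshold continuously.
censored_latent_median <- function(frac, sdlog, threshold, z_clip = 3) {
  z <- qnorm(pmin(pmax(frac, 1e-12), 1 - 1e-12))
  threshold * exp(sdlog^2 / 2 + sdlog * pmin(pmax(z, -z_clip), z_clip))
}

#' @rdname s_only_probability
#' @export
cec_m_intensity_mean <- function(y_um, params) {
  pmin(
    censored_latent_median(
      cec_m_probability(y_um, params),
      params$cec_m_sdlog, params$expression_threshold
    ),
    params$cec_m_max
  )
}

#' @rdname s_only_probability
#' @export
cec_s_intensity_mean <- function(y_um, params) {
  mid <- params$s_transition_midpoint_um
  len <- params$strip_length_um
  latent <- censored_latent_median(
    cec_s_probability(y_um, params),
    params$cec_s_sdlog, params$expression_threshold
  )
  ramp <- params$cec_s_max * pmax(y_um - mid, 0) / max(len - mid, 1)
  pmax(latent, ramp)
}

# Multiplicative lognormal noise with a given CV around a positive mean;
# cv = 0 returns the mean exactly.
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) {
    return(rep_len(mean, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Jittered hexagonal mosaic filling [0, width] x [0, length]; row pitch
# spacing * sqrt(3)/2, alternate rows offset by spacing / 2.
hex_mosaic <- function(length_um, width_um, spacing_um, jitter_frac) {
  pitch <- spacing_um * sqrt(3) / 2
  n_rows <- max(1L, floor(length_um / pitch))
  n_cols <- max(1L, floor(width_um / spacing_um))
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  x <- (col - 0.5) * spacing_um + ifelse(row %% 2 == 0, spacing_um / 2, 0)
  y <- (row - 0.5) * pitch
  n <- length(x)
  if (jitter_frac > 0) {
    x <- x + runif(n, -jitter_frac, jitter_frac) * spacing_um
    y <- y + runif(n, -jitter_frac, jitter_frac) * spacing_um
  }
  tibble(
    x_um = pmin(pmax(x, 0), width_um),
    y_um = pmin(pmax(y, 0), length_um)
  )
}

#' Generate a ground-truth synthetic retinal strip
#'
#' Places cones on a jittered hexagonal mosaic filling the strip, assigns each
#' a binary fate (S-only with probability [s_only_probability()], else CEC),
#' and draws intensities. S-only cones carry high, position-independent S
#' intensity (multiplicative lognormal noise, `noise_cv`) and background M.
#' CEC cones draw each channel from a censored lognormal around the
#' position-dependent latent levels ([cec_s_intensity_mean()],
#' [cec_m_intensity_mean()]): presence of expression is marginally Bernoulli
#' with exactly the derived fraction curves ([cec_s_probability()],
#' [cec_m_probability()]) — the latent level and the presence come from one
#' shared uniform per channel — while intensities pass continuously through
#' the detection threshold, as real immunofluorescence does. The CEC M level
#' decreases D->V; the CEC S level rises approximately linearly ventral of
#' the transition. The true fate is recorded in `fate_truth`; `class_label`
#' is left unset for [classify_cells()].
#'
#' The output is deterministic given `params` (including `params$seed`).
#'
#' @param params A [generator_params()] object.
#' @return A [cell_table()] with `source = "synthetic"` metadata.
#' @examples
#' tab <- generate_cell_table(generator_params(
#'   strip_length_um = 1000, strip_width_um = 100, seed = 7
#' ))
#' dplyr::count(tab, fate_truth)
#' @export
generate_cell_table <- function(params = generator_params()) {
  validate_generator_params(params)
  withr::local_seed(params$seed)

  pos <- hex_mosaic(
    params$strip_length_um, params$strip_width_um,
    params$mean_cell_spacing_um, params$jitter_frac
  )
  n <- nrow(pos)
  y <- pos$y_um

  p_sonly <- s_only_probability(y, params)
  is_sonly <- runif(n) < p_sonly
  cec <- !is_sonly

  bg <- params$background_level
  cv <- params$noise_cv
  enh <- 1 + (params$dorsal_s_enhancement - 1) *
    (1 - y / params$strip_length_um)

  # background (measurement-noise) floor in both channels
  s_int <- rlnorm_cv(n, bg, cv)
  m_int <- rlnorm_cv(n, bg, cv)
  s_int[is_sonly] <- pmax(
    rlnorm_cv(sum(is_sonly), params$s_only_level * enh[is_sonly], cv),
    s_int[is_sonly]
  )
  # CEC channels: one shared uniform per channel drives both the latent
  # (censored lognormal) level and, marginally, the Bernoulli presence
  censored_draw <- function(mean_level, sdlog) {
    u <- runif(length(mean_level))
    mean_level * exp(-sdlog^2 / 2 + sdlog * qnorm(1 - u))
  }
  s_int[cec] <- pmax(
    censored_draw(cec_s_intensity_mean(y[cec], params), params$cec_s_sdlog),
    s_int[cec]
  )
  m_int[cec] <- pmax(
    censored_draw(cec_m_intensity_mean(y[cec], params), params$cec_m_sdlog),
    m_int[cec]
  )

  area <- pmax(rnorm(n, params$mean_area_um2, params$sd_area_um2), 5)

  cell_table(
    tibble(
      cell_id = seq_len(n),
      x_um = pos$x_um,
      y_um = y,
      area_um2 = area,
      s_intensity = s_int,
      m_intensity = m_int,
      class_label = NA_character_,
      fate_truth = if_else(is_sonly, "S_ONLY", "CEC")
    ),
    meta = list(
      source = "synthetic",
      strip_length_um = params$strip_length_um,
      strip_width_um = params$strip_width_um,
      axis = "y_um increases dorsal -> ventral",
      params = params
    )
  )
}

# Validity ranges used when resampling perturbed parameters.
generator_param_bounds <- function(field) {
  fracs <- c(
    "s_fraction_base", "s_fraction_amplitude", "m_fraction_base",
    "m_fraction_amplitude", "s_only_frac_dorsal", "s_only_frac_ventral",
    "jitter_frac"
  )
  if (field %in% fracs) {
    return(c(0, 1))
  }
  if (field %in% c("noise_cv", "background_level")) {
    return(c(0, Inf))
  }
  c(.Machine$double.eps, Inf)
}

#' Sample generator parameters for a variable retina
#'
#' Draws each varied field independently from a normal distribution centred on
#' the mean parameterization, resampled into its validity range (lengths and
#' Hill coefficients stay positive, fractions stay in `[0, 1]`). Fields with
#' zero (or absent) standard deviation are returned unchanged, so `sd` lists
#' only the fields that vary between retinas.
#'
#' @param mean A [generator_params()] object: the mean retina.
#' @param sd Named list/vector of standard deviations (same field names);
#'   non-listed fields do not vary.
#' @param seed RNG seed for the draw.
#' @return A valid `generator_params` object.
#' @export
sample_retina_params <- function(mean, sd = list(), seed = 1L) {
  validate_generator_params(mean)
  stopifnot(all(names(sd) %in% names(mean)))
  withr::local_seed(as.integer(seed))
  out <- mean
  for (field in names(sd)) {
    s <- sd[[field]]
    if (is.null(s) || !is.numeric(s) || s < 0) {
      abort(sprintf("sd for field '%s' must be a number >= 0", field))
    }
    if (s == 0) next
    bounds <- generator_param_bounds(field)
    draw <- rnorm(1, mean[[field]], s)
    tries <- 0L
    while ((draw < bounds[1] || draw > bounds[2]) && tries < 1000L) {
      draw <- rnorm(1, mean[[field]], s)
      tries <- tries + 1L
    }
    if (draw < bounds[1] || draw > bounds[2]) {
      draw <- min(max(draw, bounds[1]), bounds[2])
    }
    out[[field]] <- draw
  }
  out$seed <- mean$seed
  validate_generator_params(out)
  out
}
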