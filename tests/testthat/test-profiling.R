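tiny_table <- function(y, s, m, fate = "UNKNOWN") {
  cell_table(
    tibble::tibble(
      cell_id = seq_along(y), x_um = 0, y_um = y, area_um2 = 20,
      s_intensity = s, m_intensity = m,
      class_label = NA_character_, fate_truth = fate
    ),
    meta = list(source = "synthetic", strip_length_um = max(y) + 1, strip_width_um = 10)
  )
}

test_that("classification covers the four classes and is threshold-monotone", {
  tab <- tiny_table(1:4, s = c(5, 5, 0.5, 0.5), m = c(0.5, 5, 5, 0.5))
  out <- classify_cells(tab, tau_s = 1, tau_m = 1)
  expect_identical(
    out$class_label,
    c("S_ONLY", "COEXPRESSING", "M_ONLY", "NONE")
  )
  tab2 <- classify_cells(narrow_strip(), tau_s = 20)
  for (tau in c(40, 100, 400)) {
    higher <- classify_cells(narrow_strip(), tau_s = tau)
    expect_lte(
      sum(higher$class_label %in% c("S_ONLY", "COEXPRESSING")),
      sum(tab2$class_label %in% c("S_ONLY", "COEXPRESSING"))
    )
  }
})

test_that("classified counts match fate-truth expectations binomially", {
  tab <- classify_cells(narrow_strip())
  p <- cell_meta(narrow_strip())$params
  # every S-only-fated cell expresses S above threshold
  sonly <- tab[tab$fate_truth == "S_ONLY", ]
  expect_gt(mean(sonly$class_label == "S_ONLY"), 0.99)
  # total S-expressing count tracks the analytic composite curve
  expected <- sum(s_expressing_fraction(tab$y_um, p))
  observed <- sum(tab$class_label %in% c("S_ONLY", "COEXPRESSING"))
  expect_lt(abs(observed - expected), 4 * sqrt(expected) + 10)
})

test_that("fraction profiles count exactly and flag empty bins", {
  y <- c(rep(50, 5), rep(150, 5))
  hit <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  tab <- tiny_table(y, s = 1, m = 1)
  prof <- fraction_profile(tab, hit, bin_width_um = 100, strip_length_um = 300)
  expect_equal(prof$fraction[1:2], c(0.6, 0.2))
  expect_true(prof$empty[3])
  expect_true(is.na(prof$fraction[3]))
  # all cells satisfying the predicate gives an all-ones profile
  all_prof <- fraction_profile(tab, rep(TRUE, 10), bin_width_um = 100)
  expect_true(all(all_prof$fraction[!all_prof$empty] == 1))
})

test_that("alignment maps every S midpoint to zero", {
  p1 <- generator_params(strip_length_um = 6000, strip_width_um = 150, seed = 2)
  p2 <- generator_params(
    strip_length_um = 6000, strip_width_um = 150,
    s_transition_midpoint_um = 3200,
    s_only_midpoint_um = 3200, seed = 3
  )
  tabs <- list(generate_cell_table(p1), generate_cell_table(p2))
  aligned <- align_tables(tabs)
  # single table: shift is minus its fitted midpoint
  one <- align_tables(tabs[1])
  expect_equal(
    cell_meta(one[[1]])$y_shift_um,
    cell_meta(aligned[[1]])$y_shift_um
  )
  # two copies of one table align identically
  twins <- align_tables(list(tabs[[1]], tabs[[1]]))
  expect_identical(twins[[1]]$y_um, twins[[2]]$y_um)
  # after alignment both midpoints sit at 0 (within fit error); offset the
  # coordinates so the Hill position model stays on a positive domain
  for (tab in aligned) {
    tab$y_um <- tab$y_um + 4000
    fit <- fit_hill(
      fraction_profile(classify_cells(tab), "s", strip_length_um = 8000),
      direction = "increasing"
    )
    expect_lt(abs(transition_midpoint(fit) - 4000), 50)
  }
  # and the recorded shifts reflect the different generative midpoints
  shifts <- vapply(aligned, function(t) cell_meta(t)$y_shift_um, numeric(1))
  expect_lt(abs((shifts[1] - shifts[2]) - (3200 - 3600)), 60)
})

test_that("joint distributions normalize exactly and find the two ventral modes", {
  one <- joint_distribution(tiny_table(5, 100, 100), n_bins = 10)
  expect_identical(nrow(one), 1L)
  expect_equal(one$prob, 1)
  expect_equal(one$log10_prob, 0)

  tab <- narrow_strip()
  jd <- joint_distribution(tab, dv_window_um = c(4500, 4750), n_bins = 40)
  expect_equal(sum(jd$prob), 1)
  # S-only mode (high S) and CEC mode (lower S) along the S axis
  s_marginal <- tapply(jd$prob, jd$s_mid, sum)
  modes <- conemosaic:::count_density_modes(
    log1p(tab$s_intensity[tab$y_um >= 4500 & tab$y_um < 4750 & tab$s_intensity > 20]),
    min_height = 0.05
  )
  expect_gte(modes, 2)
})

test_that("per-bin intensity distributions normalize and expose dorsal bimodality", {
  tab <- tiny_table(c(1, 2, 3), s = c(7, 7, 7), m = c(1, 1, 1))
  d <- intensity_dv_distribution(tab, "s", dv_bin_um = 10, intensity_bins = 5)
  expect_identical(length(unique(d$intensity_mid)), 1L)
  expect_equal(sum(d$prob), 1)

  strip <- narrow_strip()
  dd <- intensity_dv_distribution(strip, "s", dv_bin_um = 250)
  sums <- tapply(dd$prob, dd$bin_center_um, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # dorsal S intensities are bimodal: background CEC vs bright S-only cones
  # (the S-only mode holds ~2% of cells, so lower the peak-height cutoff)
  dorsal_s <- strip$s_intensity[strip$y_um < 1500]
  expect_gte(
    conemosaic:::count_density_modes(log1p(dorsal_s), min_height = 0.005),
    2
  )
})

test_that("transition statistics evaluate the CEC curve at the S midpoint", {
  # position-independent 80% CEC with a sharp S transition
  withr::local_seed(7)
  n <- 8000
  y <- runif(n, 0, 6000)
  cec <- runif(n) < 0.8
  s <- ifelse(!cec, 700, ifelse(y > 3000, 250, 5))
  tab <- tiny_table(y, s = s, m = 5, fate = ifelse(cec, "CEC", "S_ONLY"))
  ts <- transition_stats(tab)
  expect_lt(abs(ts$s_midpoint_um - 3000), 60)
  expect_lt(abs(ts$cec_fraction_at_midpoint - 0.8), 0.03)
  expect_lt(abs(ts$cec_slope_at_midpoint), 5e-5)

  # generator oracle: fraction and slope match the S-only interpolant
  strip <- narrow_strip()
  p <- cell_meta(strip)$params
  ts2 <- transition_stats(strip)
  mid <- ts2$s_midpoint_um
  truth_frac <- 1 - s_only_probability(mid, p)
  eps <- 1
  truth_slope <- (s_only_probability(mid - eps, p) - s_only_probability(mid + eps, p)) / (2 * eps)
  expect_lt(abs(ts2$cec_fraction_at_midpoint - truth_frac), 0.03)
  expect_lt(abs(ts2$cec_slope_at_midpoint - truth_slope), 5e-5)

  # a flat S profile cannot define a midpoint
  flat <- tiny_table(seq(1, 5900, length.out = 400), s = 5, m = 5, fate = "CEC")
  expect_error(transition_stats(flat), "degenerate")
})
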