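# A deterministic tile with hand-planted Gaussian blobs.
blob_tile <- function(blobs, h = 80, w = 80, sigma_px = 3, background = 0,
                      noise_sd = 0, pixel_size_um = 0.5, seed = 1) {
  img_s <- matrix(0, h, w)
  for (b in blobs) {
    rr <- outer(
      exp(-((seq_len(h) - b$row)^2) / (2 * sigma_px^2)),
      exp(-((seq_len(w) - b$col)^2) / (2 * sigma_px^2))
    )
    img_s <- img_s + b$amp * rr
  }
  withr::local_seed(seed)
  img_s <- pmax(img_s + background + matrix(rnorm(h * w, 0, noise_sd), h, w), 0)
  image_tile(list(img_s, matrix(background, h, w)),
    pixel_size_um = pixel_size_um
  )
}

test_that("normalization is an affine-invariant percentile stretch", {
  tile <- blob_tile(list(list(row = 40, col = 40, amp = 100)), noise_sd = 2, background = 5)
  n1 <- normalize_channel(tile, "s")
  expect_true(all(n1$pixels[, , 1] >= 0 & n1$pixels[, , 1] <= 1))
  # affine copy normalizes identically
  tile2 <- tile
  tile2$pixels[, , 1] <- 3.7 * tile$pixels[, , 1] + 11
  n2 <- normalize_channel(tile2, "s")
  expect_equal(n2$pixels[, , 1], n1$pixels[, , 1], tolerance = 1e-12)
})

test_that("a constant channel normalizes to zeros with a degenerate flag", {
  tile <- image_tile(list(matrix(7, 20, 20), matrix(0, 20, 20)), pixel_size_um = 1)
  expect_warning(out <- normalize_channel(tile, "s"), "dynamic range")
  expect_true(all(out$pixels[, , 1] == 0))
  expect_identical(out$degenerate, "s")
})

test_that("small-feature suppression removes impulses and keeps blobs", {
  tile <- blob_tile(list(list(row = 40, col = 40, amp = 1)), sigma_px = 4)
  tile$pixels[10, 10, 1] <- 2 # single-pixel impulse
  out <- suppress_small_features(tile, "s", max_feature_px = 3)
  expect_lt(out$pixels[10, 10, 1], 0.05) # impulse flattened to background
  peak <- max(out$pixels[30:50, 30:50, 1])
  expect_gt(peak, 0.9) # blob (much larger than scale) retained within 10%
  # an empty image passes through unchanged
  empty <- image_tile(list(matrix(0, 30, 30), matrix(0, 30, 30)), pixel_size_um = 1)
  expect_equal(
    suppress_small_features(empty, "s", 3)$pixels[, , 1],
    matrix(0, 30, 30)
  )
})

test_that("seed peaks resolve separated blobs and merge close ones", {
  two <- blob_tile(list(
    list(row = 20, col = 20, amp = 1),
    list(row = 60, col = 60, amp = 0.8)
  ))
  pk <- find_seed_peaks(two, "s", min_separation_px = 4, min_prominence = 0.1)
  expect_identical(nrow(pk), 2L)
  expect_true(any(abs(pk$row - 20) <= 2 & abs(pk$col - 20) <= 2))
  expect_true(any(abs(pk$row - 60) <= 2 & abs(pk$col - 60) <= 2))

  blank <- image_tile(list(matrix(0, 40, 40), matrix(0, 40, 40)), pixel_size_um = 1)
  expect_identical(nrow(find_seed_peaks(blank, "s")), 0L)

  close_pair <- blob_tile(list(
    list(row = 40, col = 38, amp = 1),
    list(row = 40, col = 44, amp = 0.6)
  ))
  pk2 <- find_seed_peaks(close_pair, "s",
    min_separation_px = 10, min_prominence = 0.1
  )
  expect_identical(nrow(pk2), 1L)
  expect_lt(abs(pk2$col - 38), 3) # the brighter of the two wins
})

test_that("active contours recover the half-max disk of a planted Gaussian", {
  sigma_px <- 4
  tile <- blob_tile(list(list(row = 40, col = 40, amp = 1)),
    sigma_px = sigma_px, pixel_size_um = 1
  )
  ct <- segment_from_seed(tile, "s", c(40, 40),
    init_radius_um = 3,
    window_radius_um = 20, area_bounds_um2 = c(5, 400)
  )
  expect_true(ct$accepted)
  # Chan-Vese on a noiseless Gaussian converges near the half-max level set
  half_max_area <- pi * (sigma_px * sqrt(2 * log(2)))^2
  expect_lt(abs(ct$area_px - half_max_area) / half_max_area, 0.3)
  expect_lt(sqrt(sum((ct$centroid_px - c(40, 40))^2)), 1.5)
  expect_gt(ct$solidity, 0.8)
  # vertices form a closed boundary around the centroid
  expect_gt(nrow(ct$vertices), 8)
})

test_that("background seeds and border blobs are rejected, never crash", {
  tile <- blob_tile(list(list(row = 40, col = 40, amp = 1)),
    noise_sd = 0.01, background = 0.05, pixel_size_um = 1
  )
  bg <- segment_from_seed(tile, "s", c(10, 70), window_radius_um = 12)
  expect_false(bg$accepted)
  expect_identical(bg$reason, "low_intensity")

  edge_tile <- blob_tile(list(list(row = 3, col = 40, amp = 1)), pixel_size_um = 1)
  edge <- segment_from_seed(edge_tile, "s", c(3, 40), window_radius_um = 12)
  expect_false(edge$accepted)
  expect_identical(edge$reason, "border_contact")
  expect_error(segment_from_seed(tile, "s", c(500, 500)), "outside")
})

test_that("channel reconciliation merges by IoU and keeps singletons", {
  tab <- one_cell_table_at <- cell_table(
    tibble::tibble(
      cell_id = 1:2, x_um = c(15, 45), y_um = c(20, 40), area_um2 = 20,
      s_intensity = c(600, 4), m_intensity = c(4, 400),
      class_label = NA_character_, fate_truth = "UNKNOWN"
    ),
    meta = list(source = "synthetic", strip_length_um = 60, strip_width_um = 60)
  )
  tile <- render_tiles(tab, pixel_size_um = 0.5, noise_sd = 1, seed = 2)
  tile <- normalize_channel(tile, "s")
  tile <- normalize_channel(tile, "m")
  cs <- segment_channel(tile, "s")
  cm <- segment_channel(tile, "m")
  expect_identical(length(cs), 1L)
  expect_identical(length(cm), 1L)
  # disjoint contours stay two cells
  cells <- reconcile_channels(cs, cm, tile)
  expect_identical(nrow(cells), 2L)
  # identical contours merge into one cell carrying both intensities
  merged <- reconcile_channels(cs, cs, tile)
  expect_identical(nrow(merged), 1L)
  expect_gt(merged$s_intensity[1], 100)
})

test_that("segmentation of a rendered mosaic recovers planted cells", {
  tab <- render_window_table(seed = 5)
  tile <- render_tiles(tab, pixel_size_um = 0.5, seed = 2)
  cells <- segment_tile(tile)
  # score against plainly visible cells (amplitude well above the noise floor)
  visible <- tab$s_intensity > 50 | tab$m_intensity > 50
  d2 <- outer(cells$y_um, tab$y_um, "-")^2 + outer(cells$x_um, tab$x_um, "-")^2
  precision <- mean(apply(d2, 1, min) < 2.5^2)
  recall <- mean(apply(d2[, visible, drop = FALSE], 2, min) < 2.5^2)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # determinism: the identical tile segments identically
  again <- segment_tile(render_tiles(tab, pixel_size_um = 0.5, seed = 2))
  expect_identical(as.data.frame(cells), as.data.frame(again))
})

test_that("measured interior intensity is linear in planted amplitude", {
  base_amp <- 300
  mk <- function(amp) {
    cell_table(
      tibble::tibble(
        cell_id = 1L, x_um = 20, y_um = 20, area_um2 = 20,
        s_intensity = amp, m_intensity = 4,
        class_label = NA_character_, fate_truth = "UNKNOWN"
      ),
      meta = list(source = "synthetic", strip_length_um = 40, strip_width_um = 40)
    )
  }
  measure <- function(amp) {
    tile <- render_tiles(mk(amp),
      pixel_size_um = 0.5, background_level = 0,
      noise_sd = 0, seed = 1
    )
    tile <- normalize_channel(tile, "s")
    ct <- segment_from_seed(tile, "s", c(41, 41), intensity_margin_sd = 0)
    ct$mean_s
  }
  expect_lt(abs(measure(2 * base_amp) / measure(base_amp) - 2), 0.05 * 2)
})

test_that("density maps count expressing pixels exactly", {
  # checkerboard of pure-S and pure-M pixels within one bin
  s <- matrix(0, 10, 10)
  m <- matrix(0, 10, 10)
  chk <- (row(s) + col(s)) %% 2 == 0
  s[chk] <- 100
  m[!chk] <- 100
  tile <- image_tile(list(s, m), pixel_size_um = 1)
  dm <- density_map(tile, bin_px = 10, signal_thresholds = c(50, 50))
  expect_identical(nrow(dm), 1L)
  expect_equal(dm$d_sonly, 0.5)
  expect_equal(dm$d_monly, 0.5)
  expect_equal(dm$d_both, 0)
  expect_equal(dm$d_sonly + dm$d_monly + dm$d_both, 1)

  # only S signal: S-only density 1 in all non-empty bins
  tile_s <- image_tile(list(matrix(100, 20, 20), matrix(0, 20, 20)), pixel_size_um = 1)
  dm_s <- density_map(tile_s, bin_px = 10, signal_thresholds = c(50, 50))
  expect_true(all(dm_s$d_sonly == 1))
  expect_true(all(!dm_s$empty))

  # everything below threshold: all bins empty
  dm_e <- density_map(tile_s, bin_px = 10, signal_thresholds = c(500, 500))
  expect_true(all(dm_e$empty))
})

test_that("marginal profiles average non-empty bins exactly", {
  dm <- tibble::tibble(
    bin_row = rep(1:3, each = 2), bin_col = rep(1:2, 3),
    d_sonly = c(0.1, 0.3, 0.2, 0.4, 0.3, 0.5),
    d_monly = 1 - c(0.1, 0.3, 0.2, 0.4, 0.3, 0.5),
    d_both = 0, n_expressing = 10, empty = FALSE
  )
  prof <- marginal_profile(dm, "dv")
  expect_equal(prof$d_sonly, c(0.2, 0.3, 0.4)) # linear in row index
  # a uniform map gives a constant profile
  dm$d_sonly <- 0.25
  expect_true(all(marginal_profile(dm, "dv")$d_sonly == 0.25))
  # a single non-empty bin per row passes its value through
  dm$empty <- rep(c(FALSE, TRUE), 3)
  expect_equal(marginal_profile(dm, "dv")$d_sonly, rep(0.25, 3))
  expect_equal(marginal_profile(dm, "dv")$n_bins, rep(1L, 3))
})
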