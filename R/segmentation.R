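#' Normalize one channel of a tile
#'
#' Robust percentile stretch: intensities are mapped to `[0, 1]` linearly
#' between the 1st and 99.5th percentiles and clipped. The transform is
#' monotone, and affine transforms of the input (`a*I + b`, `a > 0`) produce
#' identical output. A constant channel has no dynamic range: it becomes all
#' zeros and the tile records a degenerate flag.
#'
#' @param tile An [image_tile()].
#' @param channel `"s"` or `"m"`.
#' @param probs Lower/upper stretch percentiles.
#' @return The tile with the channel normalized (raw channels are kept in
#'   `tile$raw` for intensity measurement).
#' @export
normalize_channel <- function(tile, channel = c("s", "m"),
                              probs = c(0.01, 0.995)) {
  channel <- match.arg(channel)
  idx <- if (channel == "s") 1 else 2
  img <- tile$pixels[, , idx]
  if (is.null(tile$raw)) tile$raw <- tile$pixels
  q <- stats::quantile(img, probs, names = FALSE)
  if (diff(q) <= .Machine$double.eps^0.5) {
    warn(sprintf("channel %s has no dynamic range; normalized to zeros", channel))
    tile$pixels[, , idx] <- 0
    tile$degenerate <- unique(c(tile$degenerate, channel))
    return(tile)
  }
  out <- (img - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  tile$pixels[, , idx] <- out
  tile$normalized <- unique(c(tile$normalized, channel))
  tile
}

odd_brush <- function(size_px, shape = "disc") {
  size <- max(3L, 2L * floor(size_px / 2) + 1L)
  EBImage::makeBrush(size, shape = shape)
}

#' Suppress small bright features
#'
#' Grayscale morphological opening with a disc whose diameter matches the
#' feature scale: bright structures smaller than `max_feature_px` are
#' attenuated to the local background while cell-sized structures are
#' preserved (peak intensity within ~10%).
#'
#' @param tile An [image_tile()] (normalize first).
#' @param channel `"s"` or `"m"`.
#' @param max_feature_px Scale (in pixels) below which bright features are
#'   removed.
#' @return The tile with the channel filtered.
#' @export
suppress_small_features <- function(tile, channel = c("s", "m"),
                                    max_feature_px = 3) {
  channel <- match.arg(channel)
  stopifnot(max_feature_px >= 1)
  idx <- if (channel == "s") 1 else 2
  img <- tile$pixels[, , idx]
  tile$pixels[, , idx] <- EBImage::opening(img, odd_brush(max_feature_px))
  tile
}

#' Find seed peaks in one channel
#'
#' Local intensity maxima above a prominence threshold, separated by at least
#' `min_separation_px` (the brighter peak wins when two candidates are
#' closer). Output is deterministically ordered row-major.
#'
#' @param tile An [image_tile()] (normalized and filtered).
#' @param channel `"s"` or `"m"`.
#' @param min_separation_px Minimum peak separation in pixels.
#' @param min_prominence Minimum (normalized) intensity of a peak.
#' @return Tibble with `row`, `col` (1-based pixel indices) and `value`.
#' @export
find_seed_peaks <- function(tile, channel = c("s", "m"),
                            min_separation_px = 6, min_prominence = 0.1) {
  channel <- match.arg(channel)
  stopifnot(min_separation_px > 0, min_prominence > 0)
  img <- tile_channel(tile, channel)
  mx <- EBImage::dilate(img, odd_brush(2 * min_separation_px + 1))
  peak_mask <- img >= mx - 1e-12 & img >= min_prominence
  if (!any(peak_mask)) {
    return(tibble(row = integer(), col = integer(), value = numeric()))
  }
  # connected plateau components (e.g. from percentile clipping) collapse to
  # their centroid instead of seeding once per plateau pixel
  lab <- EBImage::bwlabel(peak_mask * 1)
  cand <- do.call(rbind, lapply(seq_len(max(lab)), function(l) {
    pts <- which(lab == l, arr.ind = TRUE)
    round(colMeans(pts))
  }))
  vals <- img[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) {
      keep[1] <- TRUE
      next
    }
    acc <- which(keep)
    d2 <- (cand[acc, 1] - cand[i, 1])^2 + (cand[acc, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  out <- tibble(
    row = as.integer(cand[keep, 1]),
    col = as.integer(cand[keep, 2]),
    value = vals[keep]
  )
  dplyr::arrange(out, .data$row, .data$col)
}

# Background statistics of a raw channel by iterative sigma clipping, so
# that bright cell pixels (which can cover half the tile at mosaic density)
# do not inflate the estimate.
background_stats <- function(tile, channel) {
  raw <- if (!is.null(tile$raw)) {
    tile$raw[, , if (channel == "s") 1 else 2]
  } else {
    tile_channel(tile, channel)
  }
  x <- as.vector(raw)
  for (i in 1:6) {
    m <- stats::median(x)
    s <- stats::mad(x)
    if (s == 0) break
    keep <- x <= m + 3 * s
    if (all(keep)) break
    x <- x[keep]
  }
  c(mean = stats::median(x), sd = max(stats::mad(x), 1e-12))
}

#' Active-contour segmentation from a seed peak
#'
#' Region-based morphological active contour: the contour is initialized as
#' a small circle at the seed and iterated within a local window, alternating
#' a region-competition update (a pixel joins the interior when it exceeds
#' the half-maximum level between the robust interior peak and the exterior
#' mean, so the contour settles on the outer segment's half-max level set)
#' with a morphological opening/closing smoothing step, keeping the connected
#' component containing the seed, until stable or `max_iter` iterations.
#'
#' The result passes validation checks before being accepted: area within
#' `area_bounds_um2`, solidity at least `min_solidity`, interior mean above
#' the background mean by `intensity_margin_sd` background SDs, and no
#' contact with the image border (truncated outer segments are rejected).
#' Rejections carry a reason code instead of a contour.
#'
#' @param tile An [image_tile()] (channel normalized).
#' @param channel `"s"` or `"m"`.
#' @param seed_point Numeric `c(row, col)` in pixels.
#' @param init_radius_um Radius of the circular initialization.
#' @param max_iter Iteration cap.
#' @param window_radius_um Half-width of the local segmentation window.
#' @param area_bounds_um2 Acceptable outer-segment area range.
#' @param min_solidity Minimum area / convex-hull-area ratio.
#' @param intensity_margin_sd Required interior-mean margin over background.
#' @return A `cell_contour` (list with `vertices`, `area_px`, `centroid_px`,
#'   `pixels`, per-channel interior means, `accepted = TRUE`) or a rejection
#'   (`accepted = FALSE`, `reason`).
#' @export
segment_from_seed <- function(tile, channel = c("s", "m"), seed_point,
                              init_radius_um = 3, max_iter = 200,
                              window_radius_um = 10,
                              area_bounds_um2 = c(5, 80),
                              min_solidity = 0.8,
                              intensity_margin_sd = 3) {
  channel <- match.arg(channel)
  img <- tile_channel(tile, channel)
  px <- tile$pixel_size_um
  h <- nrow(img)
  w <- ncol(img)
  r0 <- round(seed_point[1])
  c0 <- round(seed_point[2])
  if (r0 < 1 || r0 > h || c0 < 1 || c0 > w) {
    abort("seed point lies outside the image")
  }
  win <- max(ceiling(window_radius_um / px), ceiling(init_radius_um / px) + 3)
  rows <- max(1, r0 - win):min(h, r0 + win)
  cols <- max(1, c0 - win):min(w, c0 + win)
  sub <- img[rows, cols]
  sr <- r0 - rows[1] + 1
  sc <- c0 - cols[1] + 1

  rr <- row(sub) - sr
  cc <- col(sub) - sc
  mask <- (rr^2 + cc^2) <= (init_radius_um / px)^2
  brush <- EBImage::makeBrush(3, "diamond")
  for (iter in seq_len(max_iter)) {
    c_in <- mean(sub[mask])
    # median exterior level: robust to bright neighbours inside the window
    c_out <- stats::median(sub[!mask])
    if (!is.finite(c_out)) c_out <- 0
    if (c_in <= c_out) {
      return(reject_contour("low_intensity"))
    }
    # region criterion: the half-maximum level set of the (robust) peak over
    # the local exterior level, so the contour sizes the outer segment at
    # half-max rather than at the interior-mean/exterior-mean midpoint
    peak <- stats::quantile(sub[mask], 0.95, names = FALSE)
    cand <- sub > (peak + c_out) / 2
    sm <- EBImage::closing(EBImage::opening(cand * 1, brush), brush) > 0.5
    lab <- EBImage::bwlabel(sm * 1)
    if (lab[sr, sc] == 0) {
      # seed fell off the mask: keep the previous mask
      break
    }
    new_mask <- lab == lab[sr, sc]
    if (identical(new_mask, mask)) {
      mask <- new_mask
      break
    }
    mask <- new_mask
  }
  if (sum(mask) == 0) {
    return(reject_contour("empty_mask"))
  }
  # border contact (window clipped at the image edge = image border contact;
  # contact with an interior window edge means the contour escaped its window)
  on_edge <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  if (on_edge) {
    return(reject_contour("border_contact"))
  }

  area_px <- sum(mask)
  area_um2 <- area_px * px^2
  if (area_um2 < area_bounds_um2[1] || area_um2 > area_bounds_um2[2]) {
    return(reject_contour("area_out_of_bounds"))
  }
  pts <- which(mask, arr.ind = TRUE)
  solidity <- area_px / chull_area(pts)
  if (is.finite(solidity) && solidity < min_solidity) {
    return(reject_contour("low_solidity"))
  }
  bg <- background_stats(tile, channel)
  raw_list <- lapply(c("s", "m"), function(ch) {
    raw <- if (!is.null(tile$raw)) {
      tile$raw[, , if (ch == "s") 1 else 2]
    } else {
      tile_channel(tile, ch)
    }
    raw[rows, cols]
  })
  mean_raw <- vapply(raw_list, function(m) mean(m[mask]), numeric(1))
  this_mean <- mean_raw[if (channel == "s") 1 else 2]
  if (this_mean < bg["mean"] + intensity_margin_sd * bg["sd"]) {
    return(reject_contour("low_intensity"))
  }

  oc <- EBImage::ocontour(mask * 1)[[1]]
  # ocontour returns 0-based (dim1, dim2) coordinates of the window
  vertices <- cbind(
    row = oc[, 1] + rows[1],
    col = oc[, 2] + cols[1]
  )
  centroid <- c(
    row = mean(pts[, 1]) + rows[1] - 1,
    col = mean(pts[, 2]) + cols[1] - 1
  )
  lin <- (pts[, 2] + cols[1] - 2) * h + (pts[, 1] + rows[1] - 1)
  structure(
    list(
      accepted = TRUE,
      vertices = vertices,
      area_px = area_px,
      area_um2 = area_um2,
      centroid_px = centroid,
      solidity = solidity,
      source_channel = toupper(channel),
      mean_s = mean_raw[1],
      mean_m = mean_raw[2],
      pixels = as.integer(lin),
      iterations = iter
    ),
    class = "cell_contour"
  )
}

reject_contour <- function(reason) {
  structure(list(accepted = FALSE, reason = reason), class = "cell_contour")
}

# Pixel count of the convex hull of a pixel set, estimated from the hull of
# the pixel centers via Pick's theorem (lattice points ~ area + perimeter/2
# + 1); used for the solidity validation check.
chull_area <- function(pts) {
  if (nrow(pts) < 3) {
    return(nrow(pts))
  }
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  j <- c(2:n, 1)
  area <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
  perim <- sum(sqrt((hp[j, 1] - hp[, 1])^2 + (hp[j, 2] - hp[, 2])^2))
  max(area + perim / 2 + 1, nrow(pts) * .Machine$double.eps + 1)
}

#' Segment every cell in one channel
#'
#' Runs the per-channel pipeline: [normalize_channel()],
#' [suppress_small_features()], [find_seed_peaks()], then an independent
#' [segment_from_seed()] per peak, keeping accepted contours.
#'
#' @inheritParams segment_from_seed
#' @param cell_radius_um Expected outer-segment radius; sets the
#'   small-feature scale (1/3 of the radius) and the peak separation.
#' @param min_prominence Peak threshold on the normalized channel; by
#'   default derived from the channel's (sigma-clipped) background as
#'   mean + 5 SD, so heavy-tailed bright cells cannot push dim outer
#'   segments below a fixed cutoff.
#' @param ... Passed to [segment_from_seed()].
#' @return List of accepted `cell_contour`s, with attributes `n_seeds` and
#'   `rejections` (reason table).
#' @export
segment_channel <- function(tile, channel = c("s", "m"), cell_radius_um = 2.5,
                            min_prominence = NULL, ...) {
  channel <- match.arg(channel)
  px <- tile$pixel_size_um
  if (!channel %in% (tile$normalized %||% character())) {
    tile <- normalize_channel(tile, channel)
  }
  if (channel %in% (tile$degenerate %||% character())) {
    out <- list()
    attr(out, "n_seeds") <- 0L
    attr(out, "rejections") <- table(character())
    return(out)
  }
  tile <- suppress_small_features(tile, channel,
    max_feature_px = max(1, round(cell_radius_um / 3 / px))
  )
  if (is.null(min_prominence)) {
    norm <- tile$pixels[, , if (channel == "s") 1 else 2]
    x <- as.vector(norm)
    for (i in 1:6) {
      s <- stats::mad(x)
      if (s == 0) break
      keep <- x <= stats::median(x) + 3 * s
      if (all(keep)) break
      x <- x[keep]
    }
    min_prominence <- max(stats::median(x) + 5 * stats::mad(x), 0.02)
  }
  peaks <- find_seed_peaks(tile, channel,
    min_separation_px = max(2, round(0.8 * cell_radius_um / px)),
    min_prominence = min_prominence
  )
  contours <- purrr::pmap(
    list(peaks$row, peaks$col),
    function(r, c) segment_from_seed(tile, channel, c(r, c), ...)
  )
  ok <- purrr::map_lgl(contours, "accepted")
  rejections <- table(purrr::map_chr(contours[!ok], "reason"))
  out <- dedupe_contours(contours[ok])
  attr(out, "n_seeds") <- nrow(peaks)
  attr(out, "rejections") <- rejections
  out
}

# Two seeds on one outer segment converge to near-identical contours; keep
# the brighter of any pair overlapping by more than half.
dedupe_contours <- function(contours) {
  if (length(contours) < 2) {
    return(contours)
  }
  brightness <- purrr::map_dbl(contours, function(ct) {
    max(ct$mean_s, ct$mean_m)
  })
  ord <- order(-brightness)
  kept <- list()
  kept_pixels <- list()
  for (i in ord) {
    pix <- contours[[i]]$pixels
    dup <- FALSE
    for (kp in kept_pixels) {
      inter <- length(intersect(pix, kp))
      if (inter / (length(pix) + length(kp) - inter) > 0.5) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1]] <- contours[[i]]
      kept_pixels[[length(kept_pixels) + 1]] <- pix
    }
  }
  # restore deterministic (row-major seed) ordering
  first_pix <- purrr::map_dbl(kept, function(ct) min(ct$pixels))
  kept[order(first_pix)]
}

#' Reconcile contours across the two channels into a cell table
#'
#' Contours from the S and M channels whose pixel-set intersection-over-union
#' reaches `iou_threshold` are merged into a single cell (pixel union);
#' unmatched contours become single-channel cells. Each cell carries the mean
#' raw S and M interior intensities over its final pixel set and its centroid
#' converted to micrometres.
#'
#' @param contours_s,contours_m Lists of accepted `cell_contour`s from
#'   [segment_channel()] on the same tile.
#' @param tile The source [image_tile()].
#' @param iou_threshold Minimum IoU for merging (default 0.3).
#' @return A [cell_table()] (`class_label` unset, `fate_truth = "UNKNOWN"`).
#' @export
reconcile_channels <- function(contours_s, contours_m, tile,
                               iou_threshold = 0.3) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  px <- tile$pixel_size_um
  h <- dim(tile$pixels)[1]
  ns <- length(contours_s)
  nm <- length(contours_m)
  pairs <- NULL
  if (ns > 0 && nm > 0) {
    cs <- t(vapply(contours_s, function(x) x$centroid_px, numeric(2)))
    cm <- t(vapply(contours_m, function(x) x$centroid_px, numeric(2)))
    max_d2 <- (30 / px)^2 # contours further apart than 30 um cannot overlap
    cand <- which(outer(cs[, 1], cm[, 1], "-")^2 +
      outer(cs[, 2], cm[, 2], "-")^2 <= max_d2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      iou <- vapply(seq_len(nrow(cand)), function(k) {
        a <- contours_s[[cand[k, 1]]]$pixels
        b <- contours_m[[cand[k, 2]]]$pixels
        inter <- length(intersect(a, b))
        if (inter == 0) {
          return(0)
        }
        inter / (length(a) + length(b) - inter)
      }, numeric(1))
      ord <- order(-iou)
      used_s <- logical(ns)
      used_m <- logical(nm)
      keep <- integer(0)
      for (k in ord) {
        if (iou[k] < iou_threshold) break
        i <- cand[k, 1]
        j <- cand[k, 2]
        if (used_s[i] || used_m[j]) next
        used_s[i] <- TRUE
        used_m[j] <- TRUE
        keep <- c(keep, k)
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  matched_s <- if (is.null(pairs)) integer(0) else pairs[, 1]
  matched_m <- if (is.null(pairs)) integer(0) else pairs[, 2]

  raw_s <- if (!is.null(tile$raw)) tile$raw[, , 1] else tile$pixels[, , 1]
  raw_m <- if (!is.null(tile$raw)) tile$raw[, , 2] else tile$pixels[, , 2]
  cell_from_pixels <- function(pix) {
    rows <- ((pix - 1) %% h) + 1
    cols <- ((pix - 1) %/% h) + 1
    tibble(
      x_um = (mean(cols) - 0.5) * px,
      y_um = (mean(rows) - 0.5) * px,
      area_um2 = length(pix) * px^2,
      s_intensity = mean(raw_s[pix]),
      m_intensity = mean(raw_m[pix])
    )
  }
  rows <- list()
  if (!is.null(pairs) && nrow(pairs) > 0) {
    rows <- c(rows, purrr::map(seq_len(nrow(pairs)), function(k) {
      cell_from_pixels(union(
        contours_s[[pairs[k, 1]]]$pixels,
        contours_m[[pairs[k, 2]]]$pixels
      ))
    }))
  }
  rows <- c(
    rows,
    purrr::map(setdiff(seq_len(ns), matched_s), function(i) {
      cell_from_pixels(contours_s[[i]]$pixels)
    }),
    purrr::map(setdiff(seq_len(nm), matched_m), function(j) {
      cell_from_pixels(contours_m[[j]]$pixels)
    })
  )
  cells <- dplyr::bind_rows(rows)
  if (nrow(cells) == 0) {
    cells <- tibble(
      x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
      s_intensity = numeric(), m_intensity = numeric()
    )
  }
  cells <- dplyr::arrange(cells, .data$y_um, .data$x_um)
  cell_table(
    dplyr::mutate(cells,
      cell_id = dplyr::row_number(),
      class_label = NA_character_, fate_truth = "UNKNOWN"
    ),
    meta = list(
      source = "experimental",
      strip_length_um = dim(tile$pixels)[1] * px,
      strip_width_um = dim(tile$pixels)[2] * px,
      pixel_size_um = px
    )
  )
}

#' Segment a two-channel tile end to end
#'
#' Convenience wrapper: [segment_channel()] on both channels followed by
#' [reconcile_channels()].
#'
#' @inheritParams segment_channel
#' @inheritParams reconcile_channels
#' @return A [cell_table()].
#' @export
segment_tile <- function(tile, cell_radius_um = 2.5, min_prominence = NULL,
                         iou_threshold = 0.3, ...) {
  tile <- normalize_channel(tile, "s")
  tile <- normalize_channel(tile, "m")
  cs <- segment_channel(tile, "s",
    cell_radius_um = cell_radius_um,
    min_prominence = min_prominence, ...
  )
  cm <- segment_channel(tile, "m",
    cell_radius_um = cell_radius_um,
    min_prominence = min_prominence, ...
  )
  reconcile_channels(cs, cm, tile, iou_threshold = iou_threshold)
}

#' Binned density map of expression classes
#'
#' Subdivides the tile into square bins (default 25 x 25 pixels) and, within
#' each bin, counts the pixels with S-only signal, M-only signal, or both,
#' normalized by the number of expressing pixels in the bin. Bins without
#' expressing pixels are flagged empty; in every non-empty bin the three
#' densities sum to 1 exactly.
#'
#' @param tile An [image_tile()].
#' @param bin_px Bin side length in pixels.
#' @param signal_thresholds Length-2 thresholds (S, M) for "signal present";
#'   default: per-channel background mean + 3 SD (robust estimates).
#' @return Tibble with `bin_row`, `bin_col`, `d_sonly`, `d_monly`, `d_both`,
#'   `n_expressing`, `empty`.
#' @export
density_map <- function(tile, bin_px = 25, signal_thresholds = NULL) {
  stopifnot(bin_px >= 1)
  s <- if (!is.null(tile$raw)) tile$raw[, , 1] else tile$pixels[, , 1]
  m <- if (!is.null(tile$raw)) tile$raw[, , 2] else tile$pixels[, , 2]
  if (is.null(signal_thresholds)) {
    bs <- background_stats(tile, "s")
    bm <- background_stats(tile, "m")
    signal_thresholds <- c(
      bs["mean"] + 3 * bs["sd"],
      bm["mean"] + 3 * bm["sd"]
    )
  }
  s_on <- s > signal_thresholds[1]
  m_on <- m > signal_thresholds[2]
  br <- ceiling(row(s) / bin_px)
  bc <- ceiling(col(s) / bin_px)
  key <- paste(br, bc, sep = ":")
  agg <- tibble(
    key = key,
    bin_row = as.vector(br),
    bin_col = as.vector(bc),
    sonly = as.vector(s_on & !m_on),
    monly = as.vector(m_on & !s_on),
    both = as.vector(s_on & m_on)
  ) |>
    dplyr::group_by(.data$bin_row, .data$bin_col) |>
    dplyr::summarise(
      n_sonly = sum(.data$sonly), n_monly = sum(.data$monly),
      n_both = sum(.data$both), .groups = "drop"
    ) |>
    dplyr::mutate(n_expressing = .data$n_sonly + .data$n_monly + .data$n_both)
  agg |>
    dplyr::mutate(
      empty = .data$n_expressing == 0,
      d_sonly = ifelse(.data$empty, NA_real_, .data$n_sonly / .data$n_expressing),
      d_monly = ifelse(.data$empty, NA_real_, .data$n_monly / .data$n_expressing),
      d_both = ifelse(.data$empty, NA_real_, .data$n_both / .data$n_expressing)
    ) |>
    dplyr::select(
      "bin_row", "bin_col", "d_sonly", "d_monly", "d_both",
      "n_expressing", "empty"
    ) |>
    dplyr::arrange(.data$bin_row, .data$bin_col)
}

#' Marginal density profile of a density map
#'
#' Averages the binned class densities over non-empty bins per D-V row
#' (`axis = "dv"`) or per T-N column (`axis = "tn"`).
#'
#' @param map A [density_map()] result.
#' @param axis `"dv"` or `"tn"`.
#' @return Tibble with `bin`, mean `d_sonly`, `d_monly`, `d_both`, and
#'   `n_bins` (non-empty bins averaged).
#' @export
marginal_profile <- function(map, axis = c("dv", "tn")) {
  axis <- match.arg(axis)
  key <- if (axis == "dv") "bin_row" else "bin_col"
  map |>
    dplyr::filter(!.data$empty) |>
    dplyr::group_by(bin = .data[[key]]) |>
    dplyr::summarise(
      d_sonly = mean(.data$d_sonly),
      d_monly = mean(.data$d_monly),
      d_both = mean(.data$d_both),
      n_bins = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin)
}
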