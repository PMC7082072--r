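#' Classify cones by opsin expression
#'
#' Assigns `class_label` from thresholded intensities: `S_ONLY` if only
#' `s_intensity > tau_s`, `M_ONLY` if only `m_intensity > tau_m`,
#' `COEXPRESSING` if both, `NONE` if neither. Classification is
#' threshold-monotone: raising `tau_s` never increases the S-expressing count.
#'
#' @param table A cell table (any source).
#' @param tau_s,tau_m Intensity thresholds for calling S/M expression
#'   (arbitrary units). The default (20) corresponds to the background-derived
#'   mean + 3 SD rule on default synthetic tiles.
#' @return The table with `class_label` filled in.
#' @export
classify_cells <- function(table, tau_s = 20, tau_m = 20) {
  stopifnot(tau_s >= 0, tau_m >= 0)
  s <- table$s_intensity > tau_s
  m <- table$m_intensity > tau_m
  table$class_label <- dplyr::case_when(
    s & m ~ "COEXPRESSING",
    s ~ "S_ONLY",
    m ~ "M_ONLY",
    TRUE ~ "NONE"
  )
  table
}

# Predicate helpers usable with fraction_profile().
expresses_s <- function(table) table$class_label %in% c("S_ONLY", "COEXPRESSING")
expresses_m <- function(table) table$class_label %in% c("M_ONLY", "COEXPRESSING")

#' D-V fraction profile of a cell predicate
#'
#' Bins cells along the D-V axis and computes, per bin, the fraction of cells
#' satisfying a predicate (e.g. "expresses S-opsin"). Bins without cells are
#' flagged `empty` and excluded from downstream fits.
#'
#' @param table A cell table.
#' @param predicate Either a logical vector (one value per row), or a function
#'   of the table returning one, or one of the shortcuts `"s"` / `"m"`
#'   (expressing S/M per `class_label`), `"s_only"`, `"m_only"`,
#'   `"coexpressing"`, `"cec"` / `"fate_s_only"` (from `fate_truth`).
#' @param bin_width_um D-V bin width (default 100).
#' @param strip_length_um Override for the strip length (defaults to table
#'   metadata, falling back to the observed range).
#' @return A tibble with `bin_center_um`, `fraction`, `n_cells`, `n_hit`,
#'   `empty`.
#' @examples
#' tab <- classify_cells(generate_cell_table(generator_params(
#'   strip_length_um = 2000, strip_width_um = 100
#' )))
#' fraction_profile(tab, "s", bin_width_um = 250)
#' @export
fraction_profile <- function(table, predicate, bin_width_um = 100,
                             strip_length_um = NULL) {
  stopifnot(bin_width_um > 0)
  hit <- resolve_predicate(table, predicate)
  len <- strip_length_um %||% strip_length(table)
  breaks <- seq(0, len + bin_width_um, by = bin_width_um)
  # alignment can shift y below 0; bin from the observed minimum then
  y0 <- min(table$y_um, 0)
  if (y0 < 0) breaks <- seq(floor(y0 / bin_width_um) * bin_width_um, len + bin_width_um, by = bin_width_um)
  idx <- findInterval(table$y_um, breaks, rightmost.closed = TRUE)
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  n_cells <- tabulate(idx, nbins = length(centers))
  n_hit <- tabulate(idx[hit], nbins = length(centers))
  tibble(
    bin_center_um = centers,
    fraction = ifelse(n_cells > 0, n_hit / n_cells, NA_real_),
    n_cells = n_cells,
    n_hit = n_hit,
    empty = n_cells == 0
  )
}

resolve_predicate <- function(table, predicate) {
  if (is.logical(predicate)) {
    stopifnot(length(predicate) == nrow(table))
    return(predicate)
  }
  if (is.function(predicate)) {
    return(resolve_predicate(table, predicate(table)))
  }
  if (is.character(predicate) && length(predicate) == 1) {
    need_class <- c("s", "m", "s_only", "m_only", "coexpressing")
    if (predicate %in% need_class && all(is.na(table$class_label))) {
      abort("class_label is unset; run classify_cells() first")
    }
    out <- switch(predicate,
      s = expresses_s(table),
      m = expresses_m(table),
      s_only = table$class_label == "S_ONLY",
      m_only = table$class_label == "M_ONLY",
      coexpressing = table$class_label == "COEXPRESSING",
      cec = table$fate_truth == "CEC",
      fate_s_only = table$fate_truth == "S_ONLY",
      abort(sprintf("unknown predicate shortcut '%s'", predicate))
    )
    return(out & !is.na(out))
  }
  abort("predicate must be a logical vector, function, or shortcut string")
}

#' Mean-intensity D-V profile
#'
#' Per D-V bin, the mean intensity of one channel over cells satisfying an
#' optional predicate. The same binning conventions as [fraction_profile()].
#'
#' @inheritParams fraction_profile
#' @param channel `"s"` or `"m"`.
#' @return A tibble with `bin_center_um`, `mean_intensity`, `n_cells`, `empty`.
#' @export
intensity_profile <- function(table, channel = c("s", "m"), predicate = NULL,
                              bin_width_um = 100, strip_length_um = NULL) {
  channel <- match.arg(channel)
  keep <- if (is.null(predicate)) rep(TRUE, nrow(table)) else resolve_predicate(table, predicate)
  sub <- table[keep, ]
  len <- strip_length_um %||% strip_length(table)
  breaks <- seq(0, len + bin_width_um, by = bin_width_um)
  idx <- findInterval(sub$y_um, breaks, rightmost.closed = TRUE)
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  vals <- if (channel == "s") sub$s_intensity else sub$m_intensity
  n_cells <- tabulate(idx, nbins = length(centers))
  sums <- vapply(seq_along(centers), function(b) sum(vals[idx == b]), numeric(1))
  tibble(
    bin_center_um = centers,
    mean_intensity = ifelse(n_cells > 0, sums / n_cells, NA_real_),
    n_cells = n_cells,
    empty = n_cells == 0
  )
}

#' Align retinas on the S-opsin transition midpoint
#'
#' The S transition is sharp and retinas lack an external landmark, so its
#' fitted midpoint serves as the alignment reference: each table's `y_um` is
#' shifted so that the midpoint of its S-expressing-fraction Hill fit maps to
#' 0. The applied shift is recorded in the table metadata (`y_shift_um`).
#'
#' @param tables A list of cell tables (classified; [classify_cells()] is
#'   applied when `class_label` is unset).
#' @param bin_width_um Bin width for the S-fraction profiles.
#' @param tau_s,tau_m Classification thresholds if needed.
#' @return A list of shifted cell tables.
#' @export
align_tables <- function(tables, bin_width_um = 100, tau_s = 20, tau_m = 20) {
  stopifnot(is.list(tables))
  purrr::map(tables, function(tab) {
    if (all(is.na(tab$class_label))) tab <- classify_cells(tab, tau_s, tau_m)
    prof <- fraction_profile(tab, "s", bin_width_um = bin_width_um)
    fit <- fit_hill(prof, direction = "increasing")
    shift <- -transition_midpoint(fit)
    tab$y_um <- tab$y_um + shift
    meta <- cell_meta(tab)
    meta$y_shift_um <- shift
    attr(tab, "meta") <- meta
    tab
  })
}

#' Joint S/M intensity distribution in a D-V window
#'
#' Normalized 2D histogram of `(s_intensity, m_intensity)` over the cells in a
#' D-V window, with the log10 probability of each occupied bin (empty bins are
#' `NA`). Probabilities sum to 1 exactly before the log.
#'
#' @param table A cell table.
#' @param dv_window_um Numeric length-2 window `c(from, to)` in `y_um`;
#'   `NULL` uses the whole strip.
#' @param n_bins Number of bins per intensity axis.
#' @param intensity_range Optional common range `c(lo, hi)` for both axes.
#' @return A `joint2d` object: tibble of occupied bins (`s_mid`, `m_mid`,
#'   `prob`, `log10_prob`) with bin edges and the window in attributes.
#' @export
joint_distribution <- function(table, dv_window_um = NULL, n_bins = 50,
                               intensity_range = NULL) {
  stopifnot(n_bins >= 1)
  sub <- table
  if (!is.null(dv_window_um)) {
    stopifnot(length(dv_window_um) == 2)
    sub <- table[table$y_um >= dv_window_um[1] & table$y_um < dv_window_um[2], ]
  }
  if (nrow(sub) == 0) abort("no cells in the requested D-V window")
  rng <- intensity_range %||% c(0, max(sub$s_intensity, sub$m_intensity) * 1.001)
  s_edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  m_edges <- s_edges
  si <- pmin(pmax(findInterval(sub$s_intensity, s_edges, rightmost.closed = TRUE), 1L), n_bins)
  mi <- pmin(pmax(findInterval(sub$m_intensity, m_edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0, n_bins, n_bins)
  for (k in seq_along(si)) counts[si[k], mi[k]] <- counts[si[k], mi[k]] + 1
  prob <- counts / sum(counts)
  occ <- which(prob > 0, arr.ind = TRUE)
  mids <- (s_edges[-1] + s_edges[-(n_bins + 1)]) / 2
  pv <- prob[occ]
  out <- tibble(
    s_mid = mids[occ[, 1]],
    m_mid = mids[occ[, 2]],
    prob = pv,
    log10_prob = log10(pv)
  )
  structure(out,
    class = c("joint2d", class(out)),
    s_edges = s_edges, m_edges = m_edges,
    dv_window_um = dv_window_um, n_cells = nrow(sub)
  )
}

#' @export
autoplot.joint2d <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s_mid, .data$m_mid,
    fill = .data$log10_prob
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 P") +
    ggplot2::labs(
      x = "S-opsin intensity (a.u.)", y = "M-opsin intensity (a.u.)"
    ) +
    ggplot2::theme_minimal()
}

#' Per-bin intensity distributions along the D-V axis
#'
#' For each D-V bin, the normalized histogram of one channel's intensity over
#' cells satisfying a predicate — the data behind "ranked intensity versus
#' position" panels, and the substrate for detecting per-bin bimodality (e.g.
#' the two distinct S-intensity lines formed dorsally by high S-only cones vs
#' low CEC cones).
#'
#' @inheritParams fraction_profile
#' @param channel `"s"` or `"m"`.
#' @param dv_bin_um D-V bin width.
#' @param intensity_bins Number of intensity bins (common edges across the
#'   strip).
#' @return A tibble with `bin_center_um`, `intensity_mid`, `prob`
#'   (normalized within each D-V bin).
#' @export
intensity_dv_distribution <- function(table, channel = c("s", "m"),
                                      predicate = NULL, dv_bin_um = 250,
                                      intensity_bins = 50) {
  channel <- match.arg(channel)
  keep <- if (is.null(predicate)) rep(TRUE, nrow(table)) else resolve_predicate(table, predicate)
  sub <- table[keep, ]
  if (nrow(sub) == 0) abort("no cells satisfy the predicate")
  vals <- if (channel == "s") sub$s_intensity else sub$m_intensity
  len <- strip_length(table)
  y_breaks <- seq(0, len + dv_bin_um, by = dv_bin_um)
  i_edges <- seq(0, max(vals) * 1.001, length.out = intensity_bins + 1)
  yi <- findInterval(sub$y_um, y_breaks, rightmost.closed = TRUE)
  ii <- pmin(pmax(findInterval(vals, i_edges, rightmost.closed = TRUE), 1L), intensity_bins)
  centers <- (y_breaks[-length(y_breaks)] + y_breaks[-1]) / 2
  mids <- (i_edges[-1] + i_edges[-(intensity_bins + 1)]) / 2
  df <- tibble(bin = yi, int_bin = ii) |>
    dplyr::count(.data$bin, .data$int_bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(prob = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  tibble(
    bin_center_um = centers[df$bin],
    intensity_mid = mids[df$int_bin],
    prob = df$prob,
    n = df$n
  )
}

# Count well-separated modes of a 1D sample via kernel density: local maxima
# whose height exceeds `min_height` times the global maximum and that are
# separated by a dip below `dip_frac` of the smaller adjacent peak.
count_density_modes <- function(x, min_height = 0.1, dip_frac = 0.8,
                                bw = "nrd0") {
  if (length(x) < 10) {
    return(NA_integer_)
  }
  d <- stats::density(x, bw = bw)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- peaks[y[peaks] >= min_height * max(y)]
  if (length(peaks) <= 1) {
    return(length(peaks))
  }
  # merge peaks not separated by a real dip
  keep <- peaks[1]
  for (p in peaks[-1]) {
    valley <- min(y[seq(keep[length(keep)], p)])
    if (valley < dip_frac * min(y[keep[length(keep)]], y[p])) {
      keep <- c(keep, p)
    } else if (y[p] > y[keep[length(keep)]]) {
      keep[length(keep)] <- p
    }
  }
  length(keep)
}

#' Transition statistics: the CEC fraction at the S-opsin midpoint
#'
#' Fits the S-expressing-fraction Hill transition to locate its midpoint, fits
#' the CEC-fraction curve (CEC = not S-only, among all cells) with the same
#' four-parameter Hill family (decreasing), and evaluates the CEC fraction and
#' its analytic derivative at the S midpoint. These two observables are the
#' coupling diagnostics compared between simulated and experiment-like
#' retinas.
#'
#' @param table A cell table. If `fate_truth` is available it defines the CEC
#'   population; otherwise cells are assigned by [cluster_cells()] (the
#'   non-S-only cluster), falling back to thresholds when clustering is
#'   disabled.
#' @param bin_width_um Profile bin width.
#' @param tau_s,tau_m Classification thresholds.
#' @param use_clusters Use density-based clustering to define CEC when truth
#'   is unavailable.
#' @return A one-row tibble: `s_midpoint_um`, `cec_fraction_at_midpoint`,
#'   `cec_slope_at_midpoint` (fraction per um).
#' @export
transition_stats <- function(table, bin_width_um = 100, tau_s = 20,
                             tau_m = 20, use_clusters = TRUE) {
  if (all(is.na(table$class_label))) table <- classify_cells(table, tau_s, tau_m)
  s_prof <- fraction_profile(table, "s", bin_width_um = bin_width_um)
  s_fit <- fit_hill(s_prof, direction = "increasing")
  mid <- transition_midpoint(s_fit) # errors if degenerate

  cec <- cec_indicator(table, tau_s = tau_s, tau_m = tau_m, use_clusters = use_clusters)
  cec_prof <- fraction_profile(table, cec, bin_width_um = bin_width_um)
  cec_fit <- fit_hill(cec_prof, direction = "decreasing")
  frac <- if (cec_fit$degenerate) {
    mean(cec_prof$fraction[!cec_prof$empty])
  } else {
    predict(cec_fit, mid)
  }
  slope <- if (cec_fit$degenerate) 0 else hill_fit_deriv(cec_fit, mid)
  tibble(
    s_midpoint_um = mid,
    cec_fraction_at_midpoint = min(max(frac, 0), 1),
    cec_slope_at_midpoint = slope
  )
}

# Operational CEC membership: ground truth when present; else the non-S-only
# cluster from density-based clustering; else a threshold rule (expresses M,
# or expresses S below the S-only band).
cec_indicator <- function(table, tau_s = 20, tau_m = 20, use_clusters = TRUE) {
  if (!all(is.na(table$fate_truth)) && !all(table$fate_truth == "UNKNOWN")) {
    return(table$fate_truth == "CEC")
  }
  if (use_clusters && nrow(table) >= 100) {
    cl <- tryCatch(
      cluster_cells(table, min_cluster_size = max(20, round(0.005 * nrow(table)))),
      error = function(e) NULL
    )
    if (!is.null(cl) && cl$n_clusters == 2) {
      labs <- cl$labels
      # the S-only cluster has the higher mean S and near-background M
      stats_by <- vapply(
        sort(unique(labs[labs > 0])),
        function(l) mean(table$s_intensity[labs == l]), numeric(1)
      )
      s_only_lab <- sort(unique(labs[labs > 0]))[which.max(stats_by)]
      out <- labs != s_only_lab & labs > 0
      # noise points fall back to the threshold rule
      nz <- labs <= 0
      if (any(nz)) {
        out[nz] <- threshold_cec(table, tau_s, tau_m)[nz]
      }
      return(out)
    }
  }
  threshold_cec(table, tau_s, tau_m)
}

threshold_cec <- function(table, tau_s, tau_m) {
  s_only_lower <- lower_s_only_bound(table, tau_s)
  (table$m_intensity > tau_m) |
    (table$s_intensity > tau_s & table$s_intensity < s_only_lower)
}

# Lower edge of the S-only intensity band: the antimode of the S distribution
# among bright-S cells, or 60% of the brightest decile when unimodal.
lower_s_only_bound <- function(table, tau_s) {
  s <- table$s_intensity[table$s_intensity > tau_s]
  if (length(s) < 50) {
    return(Inf)
  }
  d <- stats::density(s)
  mins <- which(diff(sign(diff(d$y))) == 2) + 1
  if (length(mins) > 0) {
    d$x[mins[which.min(d$y[mins])]]
  } else {
    0.6 * stats::quantile(s, 0.9)
  }
}
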