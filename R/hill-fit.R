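# Numerically stable Hill core: (pos/mid)^n / (1 + (pos/mid)^n) computed as a
# logistic in log space so coefficients up to n = 150 cannot overflow.
hill_core <- function(pos, midpoint, n, direction = "increasing") {
  lr <- rep(-Inf, length(pos))
  ok <- is.finite(pos) & pos > 0
  lr[ok] <- log(pos[ok]) - log(midpoint)
  p <- stats::plogis(n * lr)
  if (direction == "decreasing") 1 - p else p
}

#' Fit a four-parameter Hill transition
#'
#' Fits `value = base + amplitude * Hill(position; midpoint, n)` by
#' Levenberg-Marquardt nonlinear least squares (via `minpack.lm::nlsLM`),
#' where `Hill` is the increasing saturation curve `pos^n / (mid^n + pos^n)`
#' or its decreasing mirror. The direction is auto-detected from the means of
#' the profile ends unless given. Fitting is multi-started over Hill
#' coefficients `n` in {1, 5, 20, 50} with bounds `n` in `[0.3, 150]`,
#' `base >= 0`, `amplitude >= 0`, and midpoint within (an extension of) the
#' profiled range; the best converged start by residual sum of squares wins.
#'
#' A profile whose dynamic range cannot be distinguished from its residual
#' noise is flagged `degenerate` (the fitted `n` is then unreliable), never
#' silently dropped.
#'
#' @param data A data frame, e.g. a [fraction_profile()] result. Rows flagged
#'   in an `empty` column are excluded.
#' @param position,value Column names (unquoted) of the D-V position and the
#'   profiled quantity. Defaults match [fraction_profile()] output.
#' @param direction `"auto"` (default), `"increasing"` or `"decreasing"`.
#' @param n_starts Hill-coefficient starting values for the multi-start.
#' @return A `hill_fit` object with elements `base`, `amplitude`,
#'   `midpoint_um`, `n`, `direction`, `rss`, `converged`, `degenerate` and the
#'   fitted data; see [tidy()], [glance()], [autoplot()] methods.
#' @examples
#' prof <- tibble::tibble(
#'   bin_center_um = seq(50, 5950, by = 100),
#'   fraction = hill_up(bin_center_um, 3000, 30)
#' )
#' fit <- fit_hill(prof)
#' glance(fit)
#' @export
fit_hill <- function(data, position = "bin_center_um", value = "fraction",
                     direction = c("auto", "increasing", "decreasing"),
                     n_starts = c(1, 5, 20, 50)) {
  direction <- match.arg(direction)
  pos_col <- tidyselect_one(data, rlang::enquo(position), "position")
  val_col <- tidyselect_one(data, rlang::enquo(value), "value")
  keep <- rep(TRUE, nrow(data))
  if ("empty" %in% names(data)) keep <- keep & !data$empty
  pos <- data[[pos_col]][keep]
  val <- data[[val_col]][keep]
  ok <- is.finite(pos) & is.finite(val)
  pos <- pos[ok]
  val <- val[ok]
  if (length(pos) < 6) {
    abort("fit_hill needs at least 6 non-empty profile points")
  }
  ord <- order(pos)
  pos <- pos[ord]
  val <- val[ord]

  n_end <- max(3L, ceiling(length(pos) / 10))
  lo_mean <- mean(head(val, n_end))
  hi_mean <- mean(tail(val, n_end))
  if (direction == "auto") {
    direction <- if (hi_mean >= lo_mean) "increasing" else "decreasing"
  }

  rng <- diff(range(val))
  if (rng <= .Machine$double.eps^0.5) {
    return(new_hill_fit(
      base = mean(val), amplitude = 0, midpoint_um = mean(pos),
      n = NA_real_, direction = direction, rss = sum((val - mean(val))^2),
      converged = FALSE, degenerate = TRUE, pos = pos, val = val,
      pos_col = pos_col, val_col = val_col
    ))
  }

  base0 <- min(val)
  amp0 <- rng
  # midpoint start: position where the profile crosses half of its range
  half <- base0 + amp0 / 2
  crossing <- if (direction == "increasing") {
    which(val >= half)[1]
  } else {
    which(val <= half)[1]
  }
  mid0 <- pos[crossing %||% ceiling(length(pos) / 2)]
  if (!is.finite(mid0) || mid0 <= 0) mid0 <- stats::median(pos)

  lower <- c(base = 0, amplitude = 0, midpoint = max(min(pos) / 2, 1e-6), n = 0.3)
  upper <- c(
    base = max(val) + rng, amplitude = 2 * (max(val) + rng),
    midpoint = 1.5 * max(pos), n = 150
  )

  fits <- purrr::map(n_starts, function(n0) {
    start <- list(
      base = max(base0, lower[["base"]]), amplitude = amp0,
      midpoint = min(max(mid0, lower[["midpoint"]]), upper[["midpoint"]]),
      n = n0
    )
    tryCatch(
      minpack.lm::nlsLM(
        val ~ base + amplitude * hill_core(pos, midpoint, n, direction),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    return(new_hill_fit(
      base = base0, amplitude = amp0, midpoint_um = mid0, n = NA_real_,
      direction = direction, rss = NA_real_, converged = FALSE,
      degenerate = TRUE, pos = pos, val = val,
      pos_col = pos_col, val_col = val_col
    ))
  }
  rss <- purrr::map_dbl(fits, stats::deviance)
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  resid_sd <- sqrt(min(rss) / max(length(pos) - 4, 1))
  degenerate <- cf[["amplitude"]] < 3 * resid_sd

  new_hill_fit(
    base = cf[["base"]], amplitude = cf[["amplitude"]],
    midpoint_um = cf[["midpoint"]], n = cf[["n"]], direction = direction,
    rss = min(rss), converged = TRUE, degenerate = degenerate,
    pos = pos, val = val, pos_col = pos_col, val_col = val_col
  )
}

new_hill_fit <- function(base, amplitude, midpoint_um, n, direction, rss,
                         converged, degenerate, pos, val, pos_col, val_col) {
  structure(
    list(
      base = unname(base), amplitude = unname(amplitude),
      midpoint_um = unname(midpoint_um), n = unname(n),
      direction = direction, rss = unname(rss),
      converged = converged, degenerate = degenerate,
      data = tibble(position = pos, value = val),
      position_col = pos_col, value_col = val_col
    ),
    class = "hill_fit"
  )
}

# resolve a tidyselect-ish column argument that may be a bare name or string
tidyselect_one <- function(data, quo, what) {
  expr <- rlang::quo_get_expr(quo)
  nm <- if (rlang::is_string(expr)) expr else rlang::as_name(expr)
  if (!nm %in% names(data)) {
    abort(sprintf("%s column '%s' not found in data", what, nm))
  }
  nm
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit: %s> base=%.4g amplitude=%.4g midpoint=%.4g n=%.4g%s%s\n",
    x$direction, x$base, x$amplitude, x$midpoint_um, x$n,
    if (!x$converged) " [not converged]" else "",
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  pos <- if (is.null(newdata)) {
    object$data$position
  } else if (is.data.frame(newdata)) {
    newdata[[object$position_col]] %||% newdata[[1]]
  } else {
    newdata
  }
  if (is.na(object$n)) {
    return(rep(object$base, length(pos)))
  }
  object$base +
    object$amplitude * hill_core(pos, object$midpoint_um, object$n, object$direction)
}

# Analytic derivative of the fitted curve at positions `pos`.
hill_fit_deriv <- function(fit, pos) {
  if (is.na(fit$n)) {
    return(rep(0, length(pos)))
  }
  d <- hill_up_deriv(pos, fit$midpoint_um, fit$n, fit$amplitude)
  if (fit$direction == "decreasing") -d else d
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(
    term = c("base", "amplitude", "midpoint_um", "n"),
    estimate = c(x$base, x$amplitude, x$midpoint_um, x$n)
  )
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble(
    base = x$base, amplitude = x$amplitude, midpoint_um = x$midpoint_um,
    n = x$n, direction = x$direction, rss = x$rss,
    converged = x$converged, degenerate = x$degenerate,
    n_points = nrow(x$data)
  )
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(position = seq(
    min(object$data$position), max(object$data$position),
    length.out = 200
  ))
  grid$value <- predict(object, grid$position)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(
      x = paste0(object$position_col, " (D-V position, µm)"),
      y = object$value_col,
      title = sprintf(
        "Hill fit (%s): midpoint %.0f µm, n = %.1f",
        object$direction, object$midpoint_um, object$n
      )
    ) +
    ggplot2::theme_minimal()
}

#' Midpoint of a fitted transition
#'
#' Returns the fitted half-maximal D-V position; this is the reference point
#' used to align retinas. Errors on a degenerate fit, where the midpoint is
#' meaningless.
#'
#' @param fit A [fit_hill()] result.
#' @return Position in micrometres.
#' @export
transition_midpoint <- function(fit) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$degenerate || !fit$converged) {
    abort("transition_midpoint is undefined for a degenerate or unconverged fit")
  }
  fit$midpoint_um
}
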