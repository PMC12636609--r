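#' Subtract a buffer blank from a spectrum
#'
#' Pointwise `y_spec - y_blank`; the two spectra must share the same X grid
#' (wavelength or temperature) to within 1e-9.
#'
#' @param spec,blank Data frames with numeric columns `x`, `y`.
#' @return `spec` with the blank-subtracted `y`.
#' @export
subtract_blank <- function(spec, blank) {
  spec <- as_tibble(spec); blank <- as_tibble(blank)
  if (nrow(spec) != nrow(blank) || any(abs(spec$x - blank$x) > 1e-9)) {
    abort("spectrum and blank must share the same x grid")
  }
  spec$y <- spec$y - blank$y
  spec
}

#' Means-movement smoothing of a spectrum
#'
#' Centred moving average of `y` over `width` points, the standard
#' spectropolarimeter smoothing. At the edges the window shrinks
#' symmetrically to the largest centred window that fits, so no phantom
#' values are introduced and `x` is unchanged.
#'
#' @param spec Data frame with numeric columns `x`, `y`, or a bare numeric
#'   vector of `y` values.
#' @param width Odd window width in points (default 15); `width = 1` is the
#'   identity.
#' @return Smoothed spectrum (same type as the input).
#' @export
means_movement_smooth <- function(spec, width = 15) {
  if (width %% 2 == 0) abort("smoothing width must be odd")
  if (width < 1) abort("smoothing width must be >= 1")
  smooth_vec <- function(y) {
    n <- length(y)
    h <- (width - 1) / 2
    vapply(seq_len(n), function(i) {
      hi <- min(h, i - 1, n - i)   # shrink symmetrically at the edges
      mean(y[(i - hi):(i + hi)])
    }, numeric(1))
  }
  if (is.numeric(spec)) return(smooth_vec(spec))
  spec <- as_tibble(spec)
  if (width > 1 && nrow(spec) < width) {
    abort("spectrum too short for the requested smoothing width")
  }
  spec$y <- smooth_vec(spec$y)
  spec
}

#' Two-state van't Hoff melt model
#'
#' Ellipticity of a two-state folding equilibrium with sloping baselines.
#' With `X` in Kelvin and `Q = exp((dH/R) * (1/Tm - 1/X))` the equilibrium
#' constant of unfolding:
#'
#' `Y = [ (m_f X + b_f) + (m_u X + b_u) Q ] / (1 + Q)`
#'
#' At `X = Tm`, `Q = 1` and the signal is the midpoint of the two
#' baselines; the fraction unfolded `Q / (1 + Q)` is exactly 0.5 there.
#' `R = 8.314 J mol^-1 K^-1`.
#'
#' @param x_celsius Temperature in degrees Celsius (vectorised); converted
#'   to Kelvin internally since `1/X` only makes physical sense on an
#'   absolute scale.
#' @param m_folded,b_folded Folded-baseline slope (mdeg/K) and intercept
#'   (mdeg, at 0 K).
#' @param m_unfolded,b_unfolded Unfolded-baseline slope and intercept.
#' @param tm_celsius Melting temperature in degrees Celsius.
#' @param delta_h van't Hoff unfolding enthalpy in J/mol (> 0).
#' @return Ellipticity (mdeg), same length as `x_celsius`.
#' @export
melt_model <- function(x_celsius, m_folded, b_folded, m_unfolded, b_unfolded,
                       tm_celsius, delta_h) {
  R <- 8.314
  X <- x_celsius + 273.15
  Tm <- tm_celsius + 273.15
  Q <- exp((delta_h / R) * (1 / Tm - 1 / X))
  ((m_folded * X + b_folded) + (m_unfolded * X + b_unfolded) * Q) / (1 + Q)
}

#' Fit the two-state melt model to a melting curve
#'
#' Levenberg-Marquardt least squares of [melt_model()]. Initialization:
#' `Tm` at the temperature of steepest change of the smoothed curve,
#' `delta_h` = 150 kJ/mol, baselines from linear fits to the first and last
#' 20% of points. `delta_h` is constrained positive (unfolding is
#' endothermic). A curve with no resolvable transition (fit failure, or a
#' fitted transition amplitude below 5% of the signal range, or a `Tm` more
#' than 20 K outside the data range) is flagged.
#'
#' @param curve Data frame with numeric columns `x` (temperature, Celsius)
#'   and `y` (ellipticity, mdeg); >= 20 points spanning the transition.
#' @param width Smoothing width used only for the `Tm` initial guess.
#' @param init Optional named list overriding any of `m_folded`, `b_folded`,
#'   `m_unfolded`, `b_unfolded`, `tm_celsius`, `delta_h` starting values.
#' @return An object of class `melt_fit` with `estimate` (named vector
#'   including `tm_celsius` and `delta_h` in J/mol), `std_error`, `sigma`,
#'   `residual_norm`, `converged`, `status` (`"ok"`, `"no_transition"`,
#'   `"failed"`), `data`.
#' @export
fit_melt <- function(curve, width = 15, init = NULL) {
  curve <- as_tibble(curve)
  if (!all(c("x", "y") %in% names(curve))) abort("curve needs columns x, y")
  if (nrow(curve) < 20) abort("need >= 20 temperature points")
  curve <- dplyr::arrange(curve, .data$x)
  x <- curve$x; y <- curve$y
  n <- length(x)

  ys <- means_movement_smooth(y, width = min(width, if (n %% 2 == 0) n - 1 else n))
  dy <- diff(ys) / diff(x)
  tm_0 <- x[which.max(abs(dy))]
  k <- max(2, ceiling(0.2 * n))
  lo <- seq_len(k); hi <- (n - k + 1):n
  fit_lo <- lm(y ~ x, data = data.frame(x = x[lo] + 273.15, y = y[lo]))
  fit_hi <- lm(y ~ x, data = data.frame(x = x[hi] + 273.15, y = y[hi]))
  start <- list(mf = unname(coef(fit_lo)[2]), bf = unname(coef(fit_lo)[1]),
                mu = unname(coef(fit_hi)[2]), bu = unname(coef(fit_hi)[1]),
                tm = tm_0, dh_kj = 150)
  if (!is.null(init)) {
    map <- c(m_folded = "mf", b_folded = "bf", m_unfolded = "mu",
             b_unfolded = "bu", tm_celsius = "tm", delta_h = "dh_kj")
    for (nm in names(init)) {
      v <- init[[nm]]
      if (nm == "delta_h") v <- v / 1000
      start[[map[[nm]]]] <- v
    }
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                     ptol = 1e-10, ftol = 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ melt_model(x, mf, bf, mu, bu, tm, dh_kj * 1000),
      data = data.frame(x = x, y = y), start = start,
      lower = c(mf = -Inf, bf = -Inf, mu = -Inf, bu = -Inf,
                tm = -273.15, dh_kj = 1e-3),
      control = ctrl),
    error = function(e) NULL)

  if (is.null(fit)) {
    est <- c(m_folded = start$mf, b_folded = start$bf,
             m_unfolded = start$mu, b_unfolded = start$bu,
             tm_celsius = start$tm, delta_h = start$dh_kj * 1000)
    warn("melt fit did not converge; returning initial guesses")
    return(structure(list(estimate = est,
                          std_error = setNames(rep(NA_real_, 6), names(est)),
                          sigma = NA_real_, residual_norm = NA_real_,
                          converged = FALSE, status = "failed",
                          data = curve, nls = NULL),
                     class = "melt_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 6), names(cf)))
  est <- c(m_folded = unname(cf["mf"]), b_folded = unname(cf["bf"]),
           m_unfolded = unname(cf["mu"]), b_unfolded = unname(cf["bu"]),
           tm_celsius = unname(cf["tm"]), delta_h = unname(cf["dh_kj"]) * 1000)
  std_error <- c(m_folded = unname(se["mf"]), b_folded = unname(se["bf"]),
                 m_unfolded = unname(se["mu"]), b_unfolded = unname(se["bu"]),
                 tm_celsius = unname(se["tm"]),
                 delta_h = unname(se["dh_kj"]) * 1000)
  TmK <- est["tm_celsius"] + 273.15
  amplitude <- abs((est["m_unfolded"] * TmK + est["b_unfolded"]) -
                     (est["m_folded"] * TmK + est["b_folded"]))
  yr <- diff(range(y))
  status <- "ok"
  if (yr <= 0 || amplitude < 0.05 * yr ||
      est["tm_celsius"] < min(x) - 20 || est["tm_celsius"] > max(x) + 20) {
    status <- "no_transition"
    warn("melt fit found no resolvable transition")
  }
  structure(list(estimate = est, std_error = std_error,
                 sigma = summary(fit)$sigma,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 converged = TRUE, status = status, data = curve, nls = fit),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state van't Hoff melt fit\n")
  cat(sprintf("  Tm  = %.2f C\n", x$estimate["tm_celsius"]))
  cat(sprintf("  dH  = %.1f kJ/mol\n", x$estimate["delta_h"] / 1000))
  cat(sprintf("  status = %s (sigma %.3g mdeg)\n", x$status, x$sigma))
  invisible(x)
}

#' @rdname fit_melt
#' @param x,object A `melt_fit` object.
#' @param ... Unused.
#' @method tidy melt_fit
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = unname(x$estimate),
         std.error = unname(x$std_error))
}

#' @rdname fit_melt
#' @method glance melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble(tm_celsius = unname(x$estimate["tm_celsius"]),
         delta_h = unname(x$estimate["delta_h"]),
         sigma = x$sigma, residual_norm = x$residual_norm,
         converged = x$converged, status = x$status, nobs = nrow(x$data))
}

#' @rdname fit_melt
#' @method autoplot melt_fit
#' @export
autoplot.melt_fit <- function(object, ...) {
  e <- object$estimate
  xx <- seq(min(object$data$x), max(object$data$x), length.out = 300)
  pred <- tibble(x = xx, y = melt_model(xx, e["m_folded"], e["b_folded"],
                                        e["m_unfolded"], e["b_unfolded"],
                                        e["tm_celsius"], e["delta_h"]))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = pred, colour = "red") +
    ggplot2::geom_vline(xintercept = e["tm_celsius"], linetype = 2) +
    ggplot2::labs(x = "temperature (°C)", y = "ellipticity (mdeg)",
                  title = sprintf("Tm = %.2f °C", e["tm_celsius"]))
}

#' Classify a CD spectrum as parallel G-quadruplex
#'
#' A parallel rG4 shows a positive ellipticity peak near 265 nm and a
#' negative trough near 240 nm. After means-movement smoothing, the
#' spectrum is called parallel-G4 when the maximum within 265 +/- `window`
#' nm is positive and the minimum within 240 +/- `window` nm is negative.
#'
#' @param spec Data frame with `x` (wavelength, nm) and `y` (mdeg).
#' @param width Smoothing width (see [means_movement_smooth()]).
#' @param window Half-width of the peak search windows in nm.
#' @return Logical scalar.
#' @export
is_parallel_g4 <- function(spec, width = 15, window = 5) {
  s <- means_movement_smooth(as_tibble(spec), width = width)
  peak <- dplyr::filter(s, abs(.data$x - 265) <= window)
  trough <- dplyr::filter(s, abs(.data$x - 240) <= window)
  if (nrow(peak) == 0 || nrow(trough) == 0) {
    abort("spectrum does not cover the 240/265 nm windows")
  }
  max(peak$y) > 0 && min(trough$y) < 0
}
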