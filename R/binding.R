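#' Ligand-depletion binding isotherm
#'
#' Anisotropy of a fixed concentration `l_t` of labelled RNA titrated with
#' protein at total concentration `x`, under the exact (quadratic,
#' ligand-depletion) solution of the 1:1 binding equilibrium:
#'
#' `y = a0 + delta_a_max * [ (x + Lt + Kd) - sqrt((x + Lt + Kd)^2 - 4 x Lt) ] / (2 Lt)`
#'
#' The bracketed term divided by `2 Lt` is the bound fraction of the
#' labelled RNA, so `y` runs from `a0` at `x = 0` to `a0 + delta_a_max` at
#' saturation.
#'
#' @param x Total protein concentration (nM), `>= 0`; vectorised.
#' @param delta_a_max Anisotropy amplitude (baseline-subtracted value at
#'   saturation), dimensionless.
#' @param k_d Dissociation constant (nM), `> 0`.
#' @param l_t Total labelled-RNA concentration (nM), `> 0` (8 nM in the
#'   standard assay).
#' @param a0 Baseline anisotropy offset (0 for baseline-subtracted data).
#' @return Anisotropy values, same length as `x`.
#' @export
binding_model <- function(x, delta_a_max, k_d, l_t = 8, a0 = 0) {
  if (any(x < 0)) abort("protein concentration x must be >= 0")
  if (k_d <= 0 || l_t <= 0) abort("k_d and l_t must be > 0")
  s <- x + l_t + k_d
  disc <- s^2 - 4 * x * l_t
  if (any(disc < -1e-8 * s^2)) abort("negative discriminant in binding model")
  disc[disc < 0] <- 0
  a0 + delta_a_max * (s - sqrt(disc)) / (2 * l_t)
}

#' Fit the ligand-depletion binding isotherm to a titration curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, `minpack.lm::nlsLM`) of
#' [binding_model()] to pooled titration points. Replicate experiments are
#' fitted jointly by pooling their points into one curve. Initial guesses:
#' `k_d` = x at half-maximal y, `delta_a_max = max(y) - min(y)`,
#' `a0 = min(y)`; `k_d` and `delta_a_max` are constrained positive.
#'
#' @param curve Data frame with numeric columns `x` (total protein, nM) and
#'   `y` (anisotropy); >= 5 distinct `x` values.
#' @param l_t Total labelled-RNA concentration (nM), fixed during the fit.
#' @param fit_offset Fit an additive baseline `a0` (default `TRUE`; with
#'   `FALSE`, `a0` is fixed at 0 for baseline-subtracted data).
#' @return An object of class `binding_fit` with elements `estimate`
#'   (named vector), `std_error`, `residual_norm`, `sigma`, `converged`,
#'   `status` (`"ok"`, `"flat"` or `"failed"`), `l_t`, `data`.
#'   A degenerate (flat) curve or optimizer failure is flagged, with the
#'   best-available parameters still returned.
#' @export
fit_binding <- function(curve, l_t = 8, fit_offset = TRUE) {
  curve <- as_tibble(curve)
  if (!all(c("x", "y") %in% names(curve))) abort("curve needs columns x, y")
  if (length(unique(curve$x)) < 5) abort("need >= 5 distinct x values")
  if (l_t <= 0) abort("l_t must be > 0")
  x <- curve$x; y <- curve$y
  a0_0 <- min(y)
  amp_0 <- max(y) - min(y)
  half <- a0_0 + amp_0 / 2
  kd_0 <- x[which.min(abs(y - half))]
  if (kd_0 <= 0) kd_0 <- max(stats::median(x[x > 0], na.rm = TRUE), 1e-3)
  if (amp_0 <= 0) amp_0 <- 1e-6

  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                     ptol = 1e-10, ftol = 1e-12)
  fit <- NULL
  if (fit_offset) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ binding_model(x, dAmax, kd, l_t, a0),
        data = data.frame(x = x, y = y),
        start = list(dAmax = amp_0, kd = kd_0, a0 = a0_0),
        lower = c(dAmax = 1e-12, kd = 1e-9, a0 = -Inf),
        control = ctrl),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ binding_model(x, dAmax, kd, l_t, 0),
        data = data.frame(x = x, y = y),
        start = list(dAmax = amp_0, kd = kd_0),
        lower = c(dAmax = 1e-12, kd = 1e-9),
        control = ctrl),
      error = function(e) NULL)
  }

  if (is.null(fit)) {
    est <- c(delta_a_max = amp_0, k_d = kd_0,
             a0 = if (fit_offset) a0_0 else 0)
    res <- structure(list(estimate = est, std_error = rep(NA_real_, 3),
                          residual_norm = NA_real_, sigma = NA_real_,
                          converged = FALSE, status = "failed", l_t = l_t,
                          fit_offset = fit_offset, data = curve, nls = NULL),
                     class = "binding_fit")
    warn("binding fit did not converge; returning initial guesses")
    return(res)
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  est <- c(delta_a_max = unname(cf["dAmax"]), k_d = unname(cf["kd"]),
           a0 = if (fit_offset) unname(cf["a0"]) else 0)
  std_error <- c(delta_a_max = unname(se["dAmax"]), k_d = unname(se["kd"]),
                 a0 = if (fit_offset) unname(se["a0"]) else NA_real_)
  sigma <- summary(fit)$sigma
  # an amplitude indistinguishable from noise means no binding signal
  status <- if (est["delta_a_max"] < 2 * sigma) "flat" else "ok"
  if (status != "ok") warn("binding fit amplitude is within noise (flat curve)")
  structure(list(estimate = est, std_error = std_error,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 sigma = sigma, converged = TRUE, status = status,
                 l_t = l_t, fit_offset = fit_offset, data = curve, nls = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Ligand-depletion binding isotherm fit\n")
  cat(sprintf("  Kd      = %.4g nM\n", x$estimate["k_d"]))
  cat(sprintf("  dAmax   = %.4g\n", x$estimate["delta_a_max"]))
  cat(sprintf("  a0      = %.4g\n", x$estimate["a0"]))
  cat(sprintf("  Lt      = %.4g nM (fixed)\n", x$l_t))
  cat(sprintf("  status  = %s (residual norm %.3g)\n", x$status,
              x$residual_norm))
  invisible(x)
}

#' @rdname fit_binding
#' @param x,object A `binding_fit` object.
#' @param ... Unused.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = unname(x$estimate),
         std.error = unname(x$std_error))
}

#' @rdname fit_binding
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(k_d = unname(x$estimate["k_d"]),
         delta_a_max = unname(x$estimate["delta_a_max"]),
         sigma = x$sigma, residual_norm = x$residual_norm,
         converged = x$converged, status = x$status, nobs = nrow(x$data))
}

#' @rdname fit_binding
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  xx <- exp(seq(log(max(min(object$data$x[object$data$x > 0]), 1e-3)),
                log(max(object$data$x)), length.out = 200))
  pred <- tibble(x = xx,
                 y = binding_model(xx, object$estimate["delta_a_max"],
                                   object$estimate["k_d"], object$l_t,
                                   object$estimate["a0"]))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total protein (nM)", y = "anisotropy",
                  title = sprintf("Kd = %.3g nM", object$estimate["k_d"]))
}
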