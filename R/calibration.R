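#' Calibrate the surface relaxivity against a known radius sample
#'
#' Estimates \eqn{\rho_2} (and the scale K) by minimising the mean squared
#' difference between a measured multi-TE spherical-mean series and the
#' synthetic relaxation decay of a known radius distribution
#' ([synth_relaxation_series()]). K is profiled analytically for each
#' candidate \eqn{\rho_2}; the optimum is located on a coarse grid over
#' `bounds` and polished by golden-section refinement between the
#' neighbouring grid points. The fit is invariant to rescaling of the
#' measured series.
#'
#' @param measured [spherical_mean_series()] along TE (>= 3 points)
#' @param sample [radius_sample()] with the reference radii
#' @param T2b bulk water T2, ms
#' @param bounds rho2 search interval, nm/ms
#' @param n_grid coarse grid size
#' @return object of class `"calibration_result"`: `rho2` (nm/ms), `K`,
#'   `loss`, `bounds_hit`, `label`
#' @export
calibrate_rho2 <- function(measured, sample, T2b = 3000,
                           bounds = c(0.1, 20), n_grid = 200) {
  stopifnot(inherits(measured, "spherical_mean_series"),
            measured$axis_kind == "TE",
            inherits(sample, "radius_sample"))
  if (length(measured$axis) < 3) stop_domain("need >= 3 TE points")
  s <- measured$mean_signal
  if (stats::sd(s) == 0) stop_domain("degenerate (constant) series")
  TE <- measured$axis
  w <- volume_weights(sample)
  r <- sample$radii
  obj <- function(rho) {
    t2 <- 1 / (1 / T2b + 2 * rho * 1e-3 / r)
    m <- vapply(TE, function(te) sum(w * exp(-te / t2)), 0)
    K <- sum(s * m) / sum(m * m)
    mean((s - K * m)^2)
  }
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  losses <- vapply(grid, obj, 0)
  i <- which.min(losses)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  o <- stats::optimize(obj, c(lo, hi), tol = 1e-9)
  rho <- o$minimum
  t2 <- 1 / (1 / T2b + 2 * rho * 1e-3 / r)
  m <- vapply(TE, function(te) sum(w * exp(-te / t2)), 0)
  span <- bounds[2] - bounds[1]
  structure(list(rho2 = rho, K = sum(s * m) / sum(m * m), loss = o$objective,
                 bounds_hit = (rho - bounds[1]) < 0.01 * span ||
                              (bounds[2] - rho) < 0.01 * span,
                 label = sample$label),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("surface relaxivity calibration%s: rho2 = %.4f nm/ms\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "", x$rho2))
  cat(sprintf("  K = %.5g, loss = %.3e%s\n", x$K, x$loss,
              if (x$bounds_hit) ", AT BOUND" else ""))
  invisible(x)
}

#' Pool per-phantom surface relaxivities
#'
#' Arithmetic mean and SD of calibrated \eqn{\rho_2} values across phantoms,
#' optionally excluding labelled outliers (e.g. a degraded sample whose
#' surface chemistry changed).
#'
#' @param results list of `"calibration_result"` objects
#' @param exclude character vector of labels to drop
#' @return list with `rho2_mean`, `rho2_sd` (0 for a single value), `n`,
#'   `labels`
#' @export
pooled_relaxivity <- function(results, exclude = character()) {
  if (inherits(results, "calibration_result")) results <- list(results)
  labs <- vapply(results, function(x) x$label, "")
  keep <- !(labs %in% exclude)
  if (!any(keep)) stop_domain("no calibration results left after exclusion")
  v <- vapply(results[keep], function(x) x$rho2, 0)
  list(rho2_mean = mean(v),
       rho2_sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v), labels = labs[keep])
}

#' Bulk water T2 from a control (free water) series
#'
#' Mono-exponential fit of the multi-TE spherical-mean decay of a control
#' tube containing only free water; the fitted decay time estimates T2b.
#'
#' @param control [spherical_mean_series()] along TE
#' @param bounds T2 search interval, ms (upper default 10 s: free water at
#'   low field can approach several seconds)
#' @return list with `T2b` (ms) and the underlying `fit`
#' @export
estimate_t2b <- function(control, bounds = c(1, 10000)) {
  fit <- fit_monoexp_t2(control, bounds = bounds)
  list(T2b = fit$T2i, fit = fit)
}
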