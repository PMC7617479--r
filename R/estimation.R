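#' Spherical mean of directional signals
#'
#' Arithmetic mean of the signal over the gradient directions of one shell.
#' With a well-spread direction set this approximates the true orientation
#' average, a rotational invariant independent of the underlying fiber
#' orientation distribution.
#'
#' @param directional_signals numeric vector (or matrix with directions in
#'   columns, averaged per row)
#' @return scalar (or per-row vector)
#' @export
spherical_mean <- function(directional_signals) {
  if (length(directional_signals) == 0) stop_domain("no directional signals")
  if (is.matrix(directional_signals)) rowMeans(directional_signals)
  else mean(directional_signals)
}

#' Mono-exponential T2 fit of a multi-TE series
#'
#' Least-squares fit of \eqn{K e^{-TE/T_{2i}}} to a spherical-mean decay,
#' with T2i bounded in `bounds` (default 1-3000 ms). The scale is profiled
#' analytically and the decay rate found by bounded quasi-Newton search
#' started from a log-linear regression estimate plus a log-spaced grid. A
#' series with no decay pins T2i at the upper bound and sets `bounds_hit`.
#'
#' @param series [spherical_mean_series()] along TE (>= 2 points)
#' @param bounds T2i search interval, ms
#' @return list with `K`, `T2i` (ms), `loss`, `converged`, `bounds_hit`
#' @export
fit_monoexp_t2 <- function(series, bounds = c(1, 3000)) {
  stopifnot(inherits(series, "spherical_mean_series"),
            series$axis_kind == "TE")
  TE <- series$axis; s <- series$mean_signal
  if (length(TE) < 2) stop_domain("need >= 2 TE points")
  fit <- fit_scaled_curve(s, function(T2) exp(-TE / T2), bounds, n_starts = 8)
  ## refine from the log-linear start as well
  sl <- stats::coef(stats::lm(log(s) ~ TE))[2]
  if (is.finite(sl) && sl < 0) {
    t2_0 <- min(max(-1 / sl, bounds[1]), bounds[2])
    o <- stats::optim(t2_0, function(T2) {
      m <- exp(-TE / T2); K <- sum(s * m) / sum(m^2); mean((s - K * m)^2)
    }, method = "L-BFGS-B", lower = bounds[1], upper = bounds[2],
    control = list(factr = 10))
    if (o$value < fit$loss) {
      m <- exp(-TE / o$par)
      fit <- list(par = o$par, scale = sum(s * m) / sum(m^2), loss = o$value,
                  converged = o$convergence == 0,
                  bounds_hit = (o$par - bounds[1]) < 0.01 * diff(bounds) ||
                               (bounds[2] - o$par) < 0.01 * diff(bounds))
    }
  }
  list(K = fit$scale, T2i = fit$par, loss = fit$loss,
       converged = fit$converged, bounds_hit = fit$bounds_hit)
}

#' Diffusion-branch effective radius from a multi-b series
#'
#' Spherical-mean power-law pipeline: fits the one-cylinder spherical-mean
#' diffusion model (full erf expression, van Gelderen radial diffusivity) to
#' a measured multi-shell decay. Thin wrapper over
#' [fit_single_cylinder_diffusion()].
#'
#' @inheritParams fit_single_cylinder_diffusion
#' @return an `"effective_radius_fit"`
#' @export
fit_diffusion_radius <- function(series, protocol, diff = diffusion_params(),
                                 bounds = c(0.05, 15), n_starts = 10) {
  fit_single_cylinder_diffusion(series, protocol, diff, bounds, n_starts)
}

#' Mean SNR from repeated b0 images
#'
#' Voxelwise ratio of mean to standard deviation across repeated b = 0
#' acquisitions, averaged over a mask. With few repeats the raw ratio is
#' biased upward because E(1/s) > 1/sigma; by default the chi-distribution
#' correction factor \eqn{\sqrt{\nu/2}\,\Gamma((\nu-1)/2)/\Gamma(\nu/2)}
#' (nu = repeats - 1) divides it out, making the estimate unbiased for
#' Gaussian noise. Set `correct = FALSE` for the raw convention.
#'
#' Zero-variance voxels are excluded with a warning (they carry no noise
#' information); an error is raised if no voxel remains.
#'
#' @param b0_stack matrix, voxels x repeats (>= 2 repeats)
#' @param mask optional logical vector selecting voxels
#' @param correct apply the finite-sample 1/s bias correction?
#' @return mean SNR over the mask
#' @export
estimate_snr <- function(b0_stack, mask = NULL, correct = TRUE) {
  b0_stack <- as.matrix(b0_stack)
  if (ncol(b0_stack) < 2) stop_domain("need >= 2 b0 repeats")
  if (!is.null(mask)) {
    if (!any(mask)) stop_domain("mask is empty")
    b0_stack <- b0_stack[mask, , drop = FALSE]
  }
  mu <- rowMeans(b0_stack)
  sd <- apply(b0_stack, 1, stats::sd)
  keep <- sd > 0
  if (!all(keep)) warning(sum(!keep), " zero-variance voxel(s) excluded")
  if (!any(keep)) stop_domain("all voxels have zero variance across repeats")
  snr <- mu[keep] / sd[keep]
  if (correct) {
    nu <- ncol(b0_stack) - 1
    snr <- snr / (sqrt(nu / 2) * gamma((nu - 1) / 2) / gamma(nu / 2))
  }
  mean(snr)
}

#' Compare two sets of effective radii by ordinary least squares
#'
#' Regresses `y` on `x` (unweighted OLS), reporting slope, intercept,
#' Pearson correlation and the two-sided p-value from the t distribution
#' with n - 2 degrees of freedom. Used to compare MRI-estimated against
#' distribution-derived effective radii across phantoms.
#'
#' @param x reference radii, um
#' @param y estimated radii, um
#' @return object of class `"regression_report"`: `slope`, `intercept` (um),
#'   `R`, `p` (NA when n < 3), `n`
#' @export
compare_radii <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  if (length(x) < 2) stop_domain("need >= 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_domain("non-finite values")
  if (stats::var(x) == 0) stop_domain("zero variance in x")
  fit <- stats::lm(y ~ x)
  R <- stats::cor(x, y)
  p <- if (length(x) >= 3) stats::cor.test(x, y)$p.value else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 R = R, p = p, n = length(x)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("OLS y ~ x on %d pairs: slope %.4f, intercept %.4f um\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  Pearson R = %.4f, p = %s\n", x$R,
              if (is.na(x$p)) "NA" else format(signif(x$p, 3))))
  invisible(x)
}
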