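#' Spherical-mean diffusion signal of an axisymmetric compartment
#'
#' Powder average of \eqn{\exp(-b[D_\perp + (D_\parallel - D_\perp)\cos^2\theta])}
#' over uniformly distributed orientations:
#' \deqn{\bar S_{Diff}(b) = \sqrt{\frac{\pi}{4\,b(D_\parallel - D_\perp)}}\;
#'   e^{-b D_\perp}\, \mathrm{erf}\!\left(\sqrt{b(D_\parallel - D_\perp)}\right).}
#' The result does not depend on the fiber orientation distribution. Stable
#' limits: returns 1 at b = 0 and \eqn{e^{-bD}} when
#' \eqn{D_\perp = D_\parallel = D}; a Taylor expansion of erf(x)/x is used
#' when \eqn{b(D_\parallel - D_\perp) < 10^{-12}} to avoid 0/0.
#'
#' @param b b-value(s), s/mm^2
#' @param D_par axial diffusivity, um^2/ms
#' @param D_perp radial diffusivity, um^2/ms (must not exceed `D_par`)
#' @return signal in (0, 1]; vectorised with recycling over `b` and `D_perp`
#' @examples
#' smt_diffusion(5000, 2, 0)    # ~0.2802
#' smt_diffusion(0, 2, 0.5)     # 1
#' @export
smt_diffusion <- function(b, D_par, D_perp) {
  if (any(b < 0)) stop_domain("b must be >= 0")
  if (any(D_perp < 0) || D_par <= 0) stop_domain("diffusivities must be >= 0")
  if (any(D_perp > D_par + 1e-12))
    stop_domain("D_perp > D_par: model is prolate-axisymmetric")
  n <- max(length(b), length(D_perp))
  b <- rep_len(b, n); D_perp <- rep_len(pmin(D_perp, D_par), n)
  bm <- b * 1e-3                       # ms/um^2
  x2 <- bm * (D_par - D_perp)
  out <- numeric(n)
  small <- x2 < 1e-12
  ## erf(x)/x = (2/sqrt(pi)) (1 - x^2/3 + x^4/10 - ...)
  out[small] <- exp(-bm[small] * D_par) * (1 - x2[small] / 3)
  if (any(!small)) {
    x <- sqrt(x2[!small])
    erf <- 2 * stats::pnorm(x * sqrt(2)) - 1
    out[!small] <- sqrt(pi / (4 * x2[!small])) * exp(-bm[!small] * D_perp[!small]) * erf
  }
  out
}

#' Intra-pore T2 of a cylinder (Brownstein-Tarr)
#'
#' Surface relaxation shortens the transverse relaxation of confined water
#' according to the pore surface-to-volume ratio; for a cylinder of radius r,
#' \deqn{\frac{1}{T_{2i}(r)} = \frac{1}{T_{2b}} + \frac{2\rho_2}{r},}
#' with the unit conversion \eqn{\rho_2} [nm/ms] \eqn{\to} \eqn{\mu m/ms}
#' (factor 1e-3) applied internally. Monotone increasing in r, approaching
#' the bulk value T2b for wide pores.
#'
#' @param r cylinder radius, um (vectorised)
#' @param relax [relaxation_params()]
#' @return intra-pore T2, ms
#' @examples
#' t2_intra(1, relaxation_params(T2b = 3000, rho2 = 3.7))  # ~129.3 ms
#' @export
t2_intra <- function(r, relax) {
  check_radii(r)
  stopifnot(inherits(relax, "relaxation_params"))
  1 / (1 / relax$T2b + 2 * relax$rho2 * 1e-3 / r)
}

#' Invert the surface-relaxation law: radius from intra-pore T2
#'
#' \deqn{r = \frac{2\rho_2 \times 10^{-3}}{1/T_{2i} - 1/T_{2b}}} (um).
#' Requires \eqn{0 < T_{2i} < T_{2b}} (otherwise the surface term is
#' nonpositive and no finite radius exists) and \eqn{\rho_2 > 0} (otherwise
#' the radius is unidentifiable from T2).
#'
#' @param T2i intra-pore T2, ms
#' @param relax [relaxation_params()]
#' @return radius, um
#' @export
radius_from_t2 <- function(T2i, relax) {
  stopifnot(inherits(relax, "relaxation_params"))
  if (relax$rho2 <= 0)
    stop_domain("rho2 = 0: radius not identifiable from T2")
  if (any(T2i <= 0) || any(T2i >= relax$T2b))
    stop_domain("T2i must lie in (0, T2b) for the surface term to be positive")
  2 * relax$rho2 * 1e-3 / (1 / T2i - 1 / relax$T2b)
}

#' Unified spherical-mean diffusion-relaxation signal of a radius sample
#'
#' Volume-weighted discretisation of the joint model over a measured radius
#' sample:
#' \deqn{\bar S(b, TE) = k \sum_i w_i\,
#'   e^{-TE/T_{2i}(r_i)}\, \bar S_{Diff}(b, r_i), \qquad
#'   w_i = \frac{c_i r_i^2}{\sum_j c_j r_j^2}.}
#' The r^2 weight reflects that each cylinder contributes signal in
#' proportion to its water volume. The radial diffusivity entering
#' \eqn{\bar S_{Diff}} follows the van Gelderen model for the given
#' protocol.
#'
#' @param b b-value(s), s/mm^2
#' @param TE echo time(s), ms (recycled against `b`)
#' @param sample [radius_sample()]
#' @param relax [relaxation_params()]
#' @param diff [diffusion_params()]
#' @param protocol [acquisition_protocol()] supplying delta/Delta (the
#'   gradient amplitude matching each `b` is derived from the timings)
#' @param k positive overall scale (proportional to total pore volume)
#' @return signal values, one per (b, TE) pair
#' @export
joint_signal <- function(b, TE, sample, relax, diff, protocol, k = 1) {
  stopifnot(inherits(sample, "radius_sample"))
  if (k <= 0) stop_domain("k must be > 0")
  n <- max(length(b), length(TE))
  b <- rep_len(b, n); TE <- rep_len(TE, n)
  w <- volume_weights(sample)
  r <- sample$radii
  vapply(seq_len(n), function(i) {
    sd <- if (b[i] == 0) rep(1, length(r)) else {
      p <- acquisition_protocol(protocol$delta, protocol$Delta, b = b[i],
                                TE = TE[i], n_directions = protocol$n_directions)
      dp <- radial_diffusivity_vg(r, p, diff)
      smt_diffusion(b[i], diff$D_par, dp)
    }
    k * sum(w * exp(-TE[i] / t2_intra(r, relax)) * sd)
  }, 0)
}
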