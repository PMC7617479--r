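#' Zeros of the derivative of the first-order Bessel function
#'
#' The van Gelderen cylinder series runs over the positive roots of
#' \eqn{J_1'(\mu) = 0}. Roots are located by sign change of
#' \eqn{J_1'(x) = J_0(x) - J_1(x)/x} on a fine grid and polished with
#' [stats::uniroot()] to ~1e-13; the table is cached and extended on demand,
#' so truncation orders well beyond the default 18 are available for
#' convergence checks.
#'
#' @param n number of roots
#' @return numeric vector, the first `n` roots (1.8412, 5.3314, ...)
#' @export
besselJ1prime_zeros <- function(n) {
  n <- as.integer(n)
  if (n < 1) stop_domain("n must be >= 1")
  cached <- .poremri$j1p_zeros
  if (!is.null(cached) && length(cached) >= n) return(cached[seq_len(n)])
  j1p <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  upper <- (n + 2) * pi
  grid <- seq(0.5, upper, by = 0.05)
  v <- j1p(grid)
  idx <- which(v[-1] * v[-length(v)] < 0)
  if (length(idx) < n) stop("failed to bracket enough Bessel roots")
  roots <- vapply(idx[seq_len(n)], function(i)
    stats::uniroot(j1p, c(grid[i], grid[i + 1]), tol = 1e-13)$root, 0)
  .poremri$j1p_zeros <- roots
  roots
}

## shared validation for the radial-diffusivity front ends
check_radii <- function(r) {
  if (length(r) == 0 || any(!is.finite(r)) || any(r <= 0))
    stop_domain("radius must be finite and > 0")
}

## gamma^2 G^2 in 1/(ms^2 um^2), G in mT/m
gamma2G2 <- function(G) .GAMMA_PROTON^2 * (G * 1e-3)^2 * 1e-18

#' Radial diffusivity of a cylinder: van Gelderen model
#'
#' Apparent diffusivity perpendicular to an impermeable cylinder of radius
#' `r` under a rectangular PGSE sequence, from the Gaussian phase
#' distribution treatment. The perpendicular log-attenuation is
#' \deqn{-\ln S_\perp = 2\gamma^2G^2 \sum_m
#'   \frac{2 D\alpha_m^2\delta - 2 + 2e^{-D\alpha_m^2\delta}
#'         + 2e^{-D\alpha_m^2\Delta} - e^{-D\alpha_m^2(\Delta-\delta)}
#'         - e^{-D\alpha_m^2(\Delta+\delta)}}
#'        {D^2\alpha_m^6(\alpha_m^2 r^2 - 1)}}
#' with \eqn{\alpha_m = \mu_m/r} and \eqn{\mu_m} the roots of
#' \eqn{J_1'}; the apparent radial diffusivity is then
#' \eqn{D_\perp = -\ln S_\perp / b}. D is the intrinsic diffusivity
#' `diff$D_par`. The series is truncated at `diff$m_terms` (default 18).
#'
#' When the protocol carries several shells (vector G/b) a matrix with one
#' column per shell is returned.
#'
#' @param r cylinder radius/radii, um
#' @param protocol an [acquisition_protocol()]
#' @param diff [diffusion_params()]
#' @return D_perp in um^2/ms; vector over `r`, or `length(r) x n_shell`
#'   matrix for multi-shell protocols
#' @export
radial_diffusivity_vg <- function(r, protocol, diff = diffusion_params()) {
  check_radii(r)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  mu <- besselJ1prime_zeros(diff$m_terms)
  D0 <- diff$D_par
  delta <- protocol$delta; Delta <- protocol$Delta
  one_shell <- function(G, b) {
    if (b == 0) return(rep(0, length(r)))
    ## (m x r) outer products, summed over m
    am2 <- outer(mu^2, 1 / r^2)            # alpha_m^2
    ad <- D0 * am2
    num <- 2 * ad * delta - 2 +
      2 * exp(-ad * delta) + 2 * exp(-ad * Delta) -
      exp(-ad * (Delta - delta)) - exp(-ad * (Delta + delta))
    den <- D0^2 * am2^3 * (outer(mu^2, rep(1, length(r))) - 1)
    lnS <- 2 * gamma2G2(G) * colSums(num / den)
    pmin(pmax(lnS / (b * 1e-3), 0), D0)    # clamp to [0, D_par]
  }
  res <- vapply(seq_along(protocol$G),
                function(k) one_shell(protocol$G[k], protocol$b[k]),
                numeric(length(r)))
  if (length(protocol$G) == 1) as.vector(res) else res
}

#' Radial diffusivity: Neuman wide-pulse approximation
#'
#' Closed-form small-radius limit of the van Gelderen model, valid for
#' \eqn{\Delta \gg \delta \gg r^2/D}:
#' \deqn{D_\perp = \frac{7 r^4}{48\, D\, \delta\, (\Delta - \delta/3)}.}
#' Scales exactly as r^4. Only accurate for radii small compared to the
#' diffusion length during the pulse (within ~5% below ~1 um at
#' delta/Delta = 9/35 ms, but off by >20% at 5 um); provided for comparison
#' with the full series, which should be preferred for large pores.
#'
#' @inheritParams radial_diffusivity_vg
#' @return D_perp, um^2/ms (vector over `r`; matrix for multi-shell)
#' @export
radial_diffusivity_neuman <- function(r, protocol, diff = diffusion_params()) {
  check_radii(r)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  d <- 7 * r^4 / (48 * diff$D_par * protocol$delta *
                    (protocol$Delta - protocol$delta / 3))
  if (length(protocol$G) == 1) d else
    matrix(d, length(r), length(protocol$G))
}

#' Radial diffusivity: medium-pulse approximation (unavailable)
#'
#' Placeholder for a medium-pulse-regime closed form
#' (\eqn{\Delta \gg \delta \gtrsim r^2/D}) intermediate in accuracy between
#' the Neuman limit and the full series. The closed form has not been
#' transcribed into this package; calling this function signals a
#' `poremri_not_implemented` condition. Use [radial_diffusivity_vg()], which
#' covers all regimes.
#'
#' @inheritParams radial_diffusivity_vg
#' @export
radial_diffusivity_medium_pulse <- function(r, protocol, diff = diffusion_params()) {
  check_radii(r)
  stop(structure(class = c("poremri_not_implemented", "error", "condition"),
                 list(message = paste("medium-pulse approximation not available;",
                                      "use radial_diffusivity_vg()"),
                      call = sys.call(-1))))
}
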