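test_that("b_value reproduces the PGSE relation and its scalings", {
  ## paper-style protocol: G = 166.8 mT/m, delta/Delta = 9/35 ms
  b <- b_value(166.8, 9, 35)
  expect_lt(abs(b / 5000 - 1), 0.05)          # within 5% of the nominal value
  expect_equal(b, 5161.153, tolerance = 1e-6)
  expect_identical(b_value(0, 9, 35), 0)
  expect_equal(b_value(2 * 166.8, 9, 35), 4 * b)   # quadratic in G
  expect_error(b_value(100, -1, 35), class = "poremri_invalid_protocol")
  expect_error(b_value(100, 9, 9), class = "poremri_invalid_protocol")
})

test_that("acquisition_protocol validates and cross-checks G against b", {
  p <- acquisition_protocol(delta = 9, Delta = 35, G = 166.8, b = 5000, TE = 51)
  expect_s3_class(p, "acquisition_protocol")
  expect_error(acquisition_protocol(9, 35, G = 166.8, b = 3000, TE = 51),
               class = "poremri_invalid_protocol")
  expect_error(acquisition_protocol(9, 8, G = 166.8, TE = 51),
               class = "poremri_invalid_protocol")
  ## b-only protocols derive a consistent G
  p2 <- acquisition_protocol(9, 35, b = 5161.153, TE = 51)
  expect_equal(p2$G, 166.8, tolerance = 1e-5)
})

test_that("van Gelderen radial diffusivity: limits, truncation, monotonicity", {
  dpars <- diffusion_params(D_par = 2, m_terms = 18)
  ## motional narrowing: D_perp -> 0 as r -> 0
  expect_lt(radial_diffusivity_vg(0.01, prot_t2, dpars), 1e-6)
  ## m = 18 matches an m = 200 series to 1e-6 relative
  r <- seq(0.1, 10, length.out = 60)
  v18 <- radial_diffusivity_vg(r, prot_t2, dpars)
  v200 <- radial_diffusivity_vg(r, prot_t2, diffusion_params(2, 200))
  expect_lt(max(abs(v18 / v200 - 1)), 1e-6)
  ## non-decreasing in r, and clamped below D_par
  dense <- radial_diffusivity_vg(seq(0.05, 10, by = 0.05), prot_t2, dpars)
  expect_true(all(diff(dense) >= 0))
  expect_true(all(dense < 2))
  expect_error(radial_diffusivity_vg(-1, prot_t2), class = "poremri_domain_error")
})

test_that("Bessel derivative root table is accurate and extensible", {
  mu <- besselJ1prime_zeros(64)
  expect_equal(mu[1:3], c(1.8411837813, 5.3314427735, 8.5363163663),
               tolerance = 1e-9)
  j1p <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  expect_true(all(abs(j1p(mu)) < 1e-10))
  expect_true(all(diff(mu) > 3))   # one root per branch, no duplicates
})

test_that("Neuman wide-pulse form: r^4 scaling and validity regimes", {
  dpars <- diffusion_params()
  ## exact quartic scaling
  expect_equal(radial_diffusivity_neuman(2, prot_t2, dpars),
               16 * radial_diffusivity_neuman(1, prot_t2, dpars))
  ## agrees with the full series below 1 um, diverges by 5 um
  r_small <- seq(0.1, 1, by = 0.1)
  vg <- radial_diffusivity_vg(r_small, prot_t2, dpars)
  ne <- radial_diffusivity_neuman(r_small, prot_t2, dpars)
  expect_lt(max(abs(ne / vg - 1)), 0.05)
  rel5 <- abs(radial_diffusivity_neuman(5, prot_t2, dpars) /
                radial_diffusivity_vg(5, prot_t2, dpars) - 1)
  expect_gt(rel5, 0.20)
  ## the discrepancy grows with radius
  rel05 <- abs(radial_diffusivity_neuman(0.5, prot_t2, dpars) /
                 radial_diffusivity_vg(0.5, prot_t2, dpars) - 1)
  expect_gt(rel5, rel05)
})

test_that("medium-pulse approximation is explicitly unavailable", {
  expect_error(radial_diffusivity_medium_pulse(1, prot_t2),
               class = "poremri_not_implemented")
})

test_that("spherical-mean diffusion signal matches closed form and limits", {
  expect_identical(smt_diffusion(0, 2, 0.5), 1)
  ## isotropic limit: exp(-b D) exactly
  expect_equal(smt_diffusion(5000, 2, 2), exp(-5 * 2), tolerance = 1e-12)
  ## stick limit at the paper's b
  expect_equal(smt_diffusion(5000, 2, 0), 0.2802474, tolerance = 1e-6)
  expect_error(smt_diffusion(5000, 1, 2), class = "poremri_domain_error")
})

test_that("spherical-mean signal agrees with quadrature oracle over a grid", {
  set.seed(7)
  for (i in 1:40) {
    b <- runif(1, 0, 10000)
    dpar <- runif(1, 0.5, 3)
    dperp <- runif(1, 0, dpar)
    expect_equal(smt_diffusion(b, dpar, dperp),
                 powder_average_quadrature(b, dpar, dperp),
                 tolerance = 1e-4)
  }
  ## continuity across the guarded isotropic expansion
  d <- 2 - 10^seq(-14, -4)
  expect_true(all(abs(smt_diffusion(5000, 2, d) - exp(-10)) < 1e-6))
})

test_that("intra-pore T2 follows the surface-relaxation law", {
  expect_equal(t2_intra(1, relax_ref), 129.3103, tolerance = 1e-4)
  expect_equal(t2_intra(0.7, relax_ref), 91.70306, tolerance = 1e-4)
  ## no surface relaxation: bulk value for any radius
  expect_equal(t2_intra(c(0.1, 1, 10), relaxation_params(3000, 0)),
               rep(3000, 3))
  ## strictly increasing, asymptote at T2b
  r <- 10^seq(-2, 2, length.out = 50)
  expect_true(all(diff(t2_intra(r, relax_ref)) > 0))
  expect_equal(t2_intra(1e6, relax_ref) / 3000, 1, tolerance = 1e-3)
})

test_that("joint signal factorises, weights by volume, and decays", {
  relax <- relax_ref; dpars <- diffusion_params()
  one <- radius_sample(1.5)
  s <- joint_signal(5000, 100, one, relax, dpars, prot_t2)
  dp <- radial_diffusivity_vg(1.5, prot_t2, dpars)
  expect_equal(s, exp(-100 / t2_intra(1.5, relax)) *
                 smt_diffusion(5000, 2, dp), tolerance = 1e-12)
  ## volume weights for equal-count {1, 2} um are {0.2, 0.8}
  expect_equal(volume_weights(radius_sample(c(1, 2))), c(0.2, 0.8))
  ## b = 0, TE -> 0 returns the scale
  expect_equal(joint_signal(0, 1e-9, radius_sample(c(1, 2)), relax, dpars,
                            prot_t2, k = 2.5), 2.5, tolerance = 1e-9)
  ## non-increasing in b and TE
  smp <- radius_sample(c(0.5, 1, 2, 4))
  along_b <- joint_signal(seq(0, 10000, by = 2000), 75, smp, relax, dpars, prot_t2)
  along_te <- joint_signal(5000, c(51, 75, 100, 150), smp, relax, dpars, prot_t2)
  expect_true(all(diff(along_b) < 0))
  expect_true(all(diff(along_te) < 0))
})

test_that("radius sample validation and binned-count weighting", {
  expect_error(radius_sample(numeric(0)), class = "poremri_domain_error")
  expect_error(radius_sample(c(1, -2)), class = "poremri_domain_error")
  expect_error(radius_sample(c(1, Inf)), class = "poremri_domain_error")
  ## histogram bins: count * r^2 weighting
  w <- volume_weights(radius_sample(c(1, 2), counts = c(4, 1)))
  expect_equal(w, c(0.5, 0.5))
})
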