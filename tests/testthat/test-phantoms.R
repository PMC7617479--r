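test_that("radius sampling is reproducible, truncated, and mean-matched", {
  spec <- phantom_preset("phantom1")
  s1 <- sample_radii(spec, seed = 7)
  s2 <- sample_radii(spec, seed = 7)
  expect_identical(s1$radii, s2$radii)
  expect_true(all(s1$radii > 0 & s1$radii <= spec$max_radius))
  ## full-size draw reproduces the catalogued mean within sampling error
  expect_equal(length(s1$radii), 11618L)
  expect_lt(abs(mean(s1$radii) / 1.07 - 1), 0.02)
  ## the other presets hit their target means too (population means are
  ## solved analytically; one modest draw per preset suffices)
  for (lab in c("phantom3", "phantom4", "phantom5")) {
    sp <- phantom_preset(lab)
    sm <- sample_radii(sp, seed = 11)
    target <- c(phantom3 = 0.70, phantom4 = 1.18, phantom5 = 1.21)[[lab]]
    expect_lt(abs(mean(sm$radii) / target - 1), 0.03)
    expect_gt(max(sm$radii), 4)       # heavy right tail present
  }
})

test_that("phantom_spec validates mixtures and orientations", {
  comps <- data.frame(weight = c(0.9, 0.1), log_mean = c(0, 1.5),
                      log_sd = c(0.4, 0.3))
  expect_s3_class(phantom_spec(comps, 100), "phantom_spec")
  bad <- comps; bad$weight <- c(0.5, 0.2)
  expect_error(phantom_spec(bad, 100), class = "poremri_domain_error")
  expect_error(phantom_spec(comps, 100, orientations = matrix(c(0, 0, 2), 1)),
               class = "poremri_domain_error")
})

test_that("Rician corruption has the right moments and determinism", {
  expect_identical(add_rician(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(8)
  s <- 1.3; sg <- 0.4
  draws <- add_rician(rep(s, 1e5), sg)
  ## second-moment identity E[X^2] = S^2 + 2 sigma^2
  expect_equal(mean(draws^2), s^2 + 2 * sg^2, tolerance = 0.01)
  expect_true(all(draws >= 0))
  expect_identical(add_rician(1:5, 0.3, seed = 4), add_rician(1:5, 0.3, seed = 4))
  expect_error(add_rician(1, -0.1), class = "poremri_domain_error")
})

test_that("simulated directional data reduce to the analytic forward model", {
  spec <- phantom_preset("phantom1", n_fibers = 1500)
  smp <- sample_radii(spec, seed = 3)
  ds <- simulate_dwi(smp, spec, prot_t2, snr = Inf)
  ## b = 0 volumes carry no direction dependence and equal the relaxation sum
  b0 <- ds$clean[ds$volumes$dir == 0]
  relax <- relaxation_params(3000, spec$rho2)
  expect_equal(b0, vapply(prot_t2$TE, function(te)
    sum(volume_weights(smp) * exp(-te / t2_intra(smp$radii, relax))), 0),
    tolerance = 1e-12)
  ## noiseless spherical means match the unified model within quadrature error
  ser <- dataset_series(ds)$series
  expected <- joint_signal(prot_t2$b, prot_t2$TE, smp, relax,
                           diffusion_params(), prot_t2)
  expect_equal(ser$mean_signal / expected, rep(1, 6), tolerance = 0.01)
})

test_that("the powder average is invariant to fiber orientation layout", {
  ## same radii, parallel vs 90-degree crossing populations
  spec1 <- phantom_preset("phantom1", n_fibers = 1200)
  spec2 <- phantom_preset("phantom2", n_fibers = 1200)
  smp <- sample_radii(spec1, seed = 5)
  s_par <- dataset_series(simulate_dwi(smp, spec1, prot_t2, snr = Inf,
                                       relax = relax_ref))$series
  s_crx <- dataset_series(simulate_dwi(smp, spec2, prot_t2, snr = Inf,
                                       relax = relax_ref))$series
  expect_equal(s_crx$mean_signal / s_par$mean_signal, rep(1, 6),
               tolerance = 0.01)
  ## and to a global rotation of the fiber frame
  th <- 0.83
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  spec_rot <- spec1; spec_rot$orientations <- spec1$orientations %*% t(R)
  s_rot <- dataset_series(simulate_dwi(smp, spec_rot, prot_t2, snr = Inf,
                                       relax = relax_ref))$series
  expect_equal(s_rot$mean_signal / s_par$mean_signal, rep(1, 6),
               tolerance = 0.01)
})

test_that("volume weighting: doubling a fiber radius quadruples its weight", {
  spec <- phantom_spec(data.frame(weight = 1, log_mean = 0, log_sd = 0.3), 2)
  relax <- relaxation_params(3000, spec$rho2)
  smp_a <- radius_sample(c(1, 1))
  smp_b <- radius_sample(c(1, 2))
  ds_a <- simulate_dwi(smp_a, spec, prot_t2, snr = Inf)
  ds_b <- simulate_dwi(smp_b, spec, prot_t2, snr = Inf)
  ## weight of the enlarged fiber in the b0 signal: 4/(1+4)
  te <- prot_t2$TE[1]
  b0_b <- ds_b$clean[ds_b$volumes$dir == 0][1]
  expect_equal(b0_b,
               0.2 * exp(-te / t2_intra(1, relax)) +
                 0.8 * exp(-te / t2_intra(2, relax)),
               tolerance = 1e-12)
  expect_equal(ds_a$clean[1], exp(-te / t2_intra(1, relax)), tolerance = 1e-12)
})

test_that("requested SNR is realised in the simulated b0 repeats", {
  spec <- phantom_preset("phantom1", n_fibers = 400)
  smp <- sample_radii(spec, seed = 2)
  ## multi-shell block: five b0 repeats at the same TE
  ds <- simulate_dwi(smp, spec, prot_d, snr = 34, n_voxels = 1e4, seed = 21)
  stack <- dataset_series(ds)$b0_stack
  expect_equal(ncol(stack), 5)
  expect_equal(estimate_snr(stack), 34, tolerance = 0.05 * 34)
  ## determinism of the whole simulated dataset
  ds2 <- simulate_dwi(smp, spec, prot_d, snr = 34, n_voxels = 3, seed = 21)
  ds3 <- simulate_dwi(smp, spec, prot_d, snr = 34, n_voxels = 3, seed = 21)
  expect_identical(ds2$signal, ds3$signal)
  expect_error(simulate_dwi(smp, spec, prot_d, directions = diag(3) * 2),
               class = "poremri_domain_error")
})

test_that("simulator plus estimators close the loop on the synthetic truth", {
  ## noiseless end-to-end consistency, each branch under its own model
  ## assumptions (the calibrated-rho2 convention for the T2 branch; no
  ## surface relaxation for the diffusion branch)
  spec <- phantom_preset("phantom4", n_fibers = 1500)
  smp <- sample_radii(spec, seed = 9)
  ## T2 branch: calibrate rho2 on the measured series, then use it on both
  ## sides -- the estimated and distribution-derived radii coincide
  ser_te <- dataset_series(simulate_dwi(smp, spec, prot_t2, snr = Inf))$series
  cal <- calibrate_rho2(ser_te, smp)
  relax_hat <- relaxation_params(3000, cal$rho2)
  r_mri_r <- radius_from_t2(fit_monoexp_t2(ser_te)$T2i, relax_hat)
  r_sem_r <- fit_single_cylinder_relaxation(
    synth_relaxation_series(smp, prot_t2$TE, relax_hat), relax_hat)$r_eff
  expect_equal(r_mri_r / r_sem_r, 1, tolerance = 0.01)
  ## diffusion branch without surface relaxation: pure-diffusion physics,
  ## so the powder-averaged acquisition inverts to the reference fit; a
  ## dense direction set isolates the estimator from quadrature error
  no_srf <- relaxation_params(3000, 0)
  dirs_dense <- poremri:::fibonacci_sphere(240)
  ser_b <- dataset_series(simulate_dwi(smp, spec, prot_d, snr = Inf,
                                       directions = dirs_dense,
                                       relax = no_srf))$series
  r_mri_d <- fit_diffusion_radius(ser_b, prot_d)$r_eff
  r_sem_d <- fit_single_cylinder_diffusion(
    synth_diffusion_series(smp, prot_d), prot_d)$r_eff
  expect_equal(r_mri_d / r_sem_d, 1, tolerance = 0.01)
  ## the 48-direction study set carries an intrinsic powder-average
  ## quadrature error of a few tenths of a percent in the signal, i.e.
  ## up to a few percent in the fitted radius
  ser_b48 <- dataset_series(simulate_dwi(smp, spec, prot_d, snr = Inf,
                                         relax = no_srf))$series
  expect_equal(fit_diffusion_radius(ser_b48, prot_d)$r_eff / r_sem_d, 1,
               tolerance = 0.03)
  ## with surface relaxation active at TE = 51 ms, the radius-dependent T2
  ## weighting the pure-diffusion model neglects inflates its estimate
  ser_b2 <- dataset_series(simulate_dwi(smp, spec, prot_d, snr = Inf))$series
  expect_gt(fit_diffusion_radius(ser_b2, prot_d)$r_eff, r_sem_d)
})
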