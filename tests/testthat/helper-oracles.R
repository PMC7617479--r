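## Independent oracles used across the test files.

## Powder-average of an axisymmetric mono-exponential signal by midpoint
## quadrature over cos(theta) in [0, 1] -- independent of the closed-form
## spherical-mean expression under test.
powder_average_quadrature <- function(b_s_mm2, D_par, D_perp, n = 1e4) {
  bm <- b_s_mm2 * 1e-3
  ct2 <- ((seq_len(n) - 0.5) / n)^2
  mean(exp(-bm * (D_perp + (D_par - D_perp) * ct2)))
}

## default paper-style protocols shared by many tests
prot_t2 <- protocol_preset("t2_block")
prot_d <- protocol_preset("dmri_block")
relax_ref <- relaxation_params(T2b = 3000, rho2 = 3.7)

## a modest heavy-tailed sample used in ordering / tracking tests
heavy_tail_sample <- function(n = 3000, seed = 42) {
  sample_radii(phantom_preset("phantom1", n_fibers = n), seed = seed)
}
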