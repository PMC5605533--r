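# Forward spectral model shared by the synthetic generator and the fitter.
#
# I(Q, E) = amp * [ x * R(E) + (1 - x) * (p L(G1) + (1 - p) L(G2)) (x) R(E) ]
#           + C1 * E + C2
#
# where R is the unit-area resolution line shape, L(G) a unit-area Lorentzian
# of half-width G, and (x) denotes convolution. The elastic term uses R
# directly (delta convolved with R is R), which keeps the elastic fraction
# exact on a discrete grid. The quasielastic term is evaluated on a padded
# grid before convolution so that Lorentzian tails are not clipped at the
# window edge.

qens_model_curve <- function(e_grid, x, p, g1, g2, c1, c2, amp, resolution,
                             pad_ueV = 60) {
  h <- stopifnot_uniform_grid(e_grid, "energy grid")
  n_pad <- ceiling(pad_ueV / h)
  e_pad <- seq(e_grid[1] - n_pad * h, by = h,
               length.out = length(e_grid) + 2L * n_pad)
  s_pad <- p * lorentzian_area1(e_pad, g1) + (1 - p) * lorentzian_area1(e_pad, g2)
  s_conv <- convolve_with_resolution(s_pad, e_pad, resolution)
  s_conv <- s_conv[(n_pad + 1L):(n_pad + length(e_grid))]
  r_curve <- resolution_line_shape(e_grid, resolution)
  amp * (x * r_curve + (1 - x) * s_conv) + c1 * e_grid + c2
}

# Unit-area resolution line shape evaluated on the analysis grid.
resolution_line_shape <- function(e_grid, resolution) {
  h <- stopifnot_uniform_grid(e_grid, "energy grid")
  if (resolution$shape == "gaussian") {
    r <- gaussian_area1(e_grid, resolution$fwhm)
  } else {
    r <- stats::approx(resolution$curve$E, resolution$curve$I, xout = e_grid,
                       yleft = 0, yright = 0)$y
    r <- pmax(r, 0)
  }
  s <- sum(r) * h
  if (abs(s - 1) > 1e-6) r <- r / s
  r
}
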