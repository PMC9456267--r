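# Independent oracles and small fixture builders shared across the suite.

# Closed-form survival probability for 1D diffusion on (0, L) with an
# absorbing boundary at 0, a reflecting boundary at L and a uniform initial
# condition: eigenfunction expansion with lambda_n = (n - 1/2) * pi / L,
#   S(t) = sum_n 8 / ((2n - 1)^2 pi^2) * exp(-D lambda_n^2 t).
# This is the analytic counterpart of the settling walk for a monodisperse
# population; it is derived independently of the simulator.
survival_series <- function(D, L, t, n_terms = 500) {
  n <- seq_len(n_terms)
  lam2 <- ((n - 0.5) * pi / L)^2
  vapply(t, function(tt) {
    sum(8 / ((2 * n - 1)^2 * pi^2) * exp(-D * lam2 * tt))
  }, numeric(1))
}

# Render one centred spherical cap on a square noiseless image, choosing a
# pixel pitch fine enough to resolve the cap (>= ~12 px per cap radius,
# capped at the instrument-typical 3.9 nm).
render_single_cap <- function(Rc, H, pixel_size = NULL, image_size = 2000) {
  if (is.null(pixel_size)) pixel_size <- max(1.5, min(3.9, Rc / 12))
  v <- data.frame(center_x = image_size / 2, center_y = image_size / 2,
                  Rc_true = Rc, H_true = H)
  gen_height_map(v, image_size = image_size, pixel_size = pixel_size,
                 noise_sd = 0)
}

# Count local maxima of a kernel density estimate, ignoring shoulders below
# `rel_min` of the tallest mode. Oracle for bimodality checks.
kde_mode_count <- function(values, rel_min = 0.1) {
  d <- density(values)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  sum(y[peaks] > rel_min * max(y))
}
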