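test_that("log-normal generator recovers its parameters and handles the zero-spread limit", {
  # zero spread: every draw is exactly the median
  s0 <- gen_lognormal_sample(100, 1.0, n = 5, seed = 1)
  expect_equal(as.numeric(s0), rep(100, 5))

  # parameter recovery at n = 1e5, within 1%
  s <- gen_lognormal_sample(149.2, 1.461, n = 1e5, seed = 42)
  fit <- fit_lognormal(s, n_boot = 0)
  expect_lt(abs(fit$mu_star - 149.2) / 149.2, 0.01)
  expect_lt(abs(fit$sigma_star - 1.461) / 1.461, 0.01)

  # sample median tracks the scale parameter for the AFM-like population
  g <- gen_lognormal_sample(71.1, 1.431, n = 1e5, seed = 43,
                            label = "geometric")
  expect_lt(abs(median(as.numeric(g)) - 71.1) / 71.1, 0.01)
  expect_identical(attr(g, "label"), "geometric")
})

test_that("log-normal generator is seed-deterministic and validates inputs", {
  a <- gen_lognormal_sample(100, 1.4, 50, seed = 7)
  b <- gen_lognormal_sample(100, 1.4, 50, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_false(identical(as.numeric(a),
                         as.numeric(gen_lognormal_sample(100, 1.4, 50,
                                                         seed = 8))))
  expect_error(gen_lognormal_sample(-5, 1.4, 10), "positive")
  expect_error(gen_lognormal_sample(100, 0.9, 10), "sigma_star")
  expect_error(diameter_sample(numeric(0)), "at least one")
  expect_error(diameter_sample(c(10, -1, 20)), "offending")
})

test_that("bimodal generator produces the requested mixture structure", {
  # degenerate weight: everything comes from mode 2
  s0 <- gen_bimodal_sample(mix = 0, n = 500, seed = 1)
  expect_true(all(attr(s0, "component") == 2L))
  expect_lt(abs(median(as.numeric(s0)) - 250) / 250, 0.1)

  # well-separated modes give a bimodal density
  s <- gen_bimodal_sample(mix = 0.5,
                          mode1 = list(mu_star = 70, sigma_star = 1.3),
                          mode2 = list(mu_star = 250, sigma_star = 1.3),
                          n = 1e4, seed = 2)
  expect_identical(kde_mode_count(as.numeric(s)), 2L)
  expect_setequal(unique(attr(s, "component")), c(1L, 2L))

  # identical modes collapse to one
  u <- gen_bimodal_sample(mix = 0.5,
                          mode1 = list(mu_star = 120, sigma_star = 1.3),
                          mode2 = list(mu_star = 120, sigma_star = 1.3),
                          n = 1e4, seed = 3)
  expect_identical(kde_mode_count(as.numeric(u)), 1L)

  expect_error(gen_bimodal_sample(mix = 1.2, n = 10), "mix")
})

test_that("histogram binning is half-open, zero-anchored and conserving", {
  h <- sample_to_histogram(c(10, 10, 10), bin_width = 5)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(sum(h$counts), 3)
  # 10 sits in [10, 15), 9.9 in [5, 10)
  h2 <- sample_to_histogram(c(9.9, 10.0), bin_width = 5)
  expect_equal(h2$counts[h2$bin_centers == 7.5], 1)
  expect_equal(h2$counts[h2$bin_centers == 12.5], 1)

  for (seed in 1:5) {
    s <- gen_lognormal_sample(120, 1.5, n = 1000, seed = seed)
    expect_equal(sum(sample_to_histogram(s, 8)$counts), 1000)
  }
  expect_error(sample_to_histogram(c(10, 20), bin_width = -1), "positive")
})

test_that("height-map renderer reproduces exact cap geometry", {
  # full sphere: apex equals H within one pixel's discretisation
  r <- render_single_cap(Rc = 50, H = 100, pixel_size = 2000 / 512)
  expect_lt(abs(max(r$map$heights) - 100), 0.5)
  expect_equal(r$vesicles$dgeom_true, 100)

  # empty list renders a zero map
  r0 <- gen_height_map(NULL, image_size = 500, pixel_size = 5, noise_sd = 0)
  expect_true(all(r0$map$heights == 0))

  # seeded determinism, bit for bit
  v <- place_vesicles(c(60, 90), seed = 5, image_size = 2000)
  a <- gen_height_map(v, image_size = 2000, noise_sd = 1, seed = 9)
  b <- gen_height_map(v, image_size = 2000, noise_sd = 1, seed = 9)
  expect_identical(a$map$heights, b$map$heights)
})

test_that("renderer flags overlapping vesicles and rejects impossible caps", {
  v <- data.frame(center_x = c(1000, 1040), center_y = c(1000, 1000),
                  Rc_true = c(50, 50), H_true = c(80, 80))
  expect_warning(r <- gen_height_map(v, image_size = 2000), "overlap")
  expect_true(all(r$vesicles$overlap))

  bad <- data.frame(center_x = 500, center_y = 500,
                    Rc_true = 20, H_true = 50) # H > 2 Rc
  expect_error(gen_height_map(bad, image_size = 1000), "H_true")
  edge <- data.frame(center_x = 10, center_y = 500,
                     Rc_true = 50, H_true = 80)
  expect_error(gen_height_map(edge, image_size = 1000), "inside")
})

test_that("cap parameterisation inverts the surface-area relation", {
  for (ratio in c(0.3, 0.7, 1.0)) {
    cap <- cap_from_diameter(137, ratio)
    expect_equal(sqrt(4 * cap$Rc_true * cap$H_true - cap$H_true^2), 137)
  }
  expect_error(cap_from_diameter(100, 1.2), "height_ratio")
})
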