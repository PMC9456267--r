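test_that("diffusion constant follows the Einstein-Stokes relation", {
  # direct evaluation: kB*T / (3 pi eta d)
  expect_equal(diffusion_constant(150, 295, 0.95e-3), 3.0326e-12,
               tolerance = 1e-4)
  # exact inverse proportionality in the diameter
  expect_equal(diffusion_constant(75), 2 * diffusion_constant(150))
  expect_equal(diffusion_constant(300), diffusion_constant(150) / 2)
  expect_error(diffusion_constant(-10), "> 0")
  expect_error(diffusion_constant(150, viscosity = 0), "positive")
})

test_that("effective drop height interpolates between cap and flat limits", {
  expect_equal(effective_drop_height(1, 5), 0.5 + 1 / 150)
  # flat-cap limit: base radius >> height
  expect_equal(effective_drop_height(1, 1e4), 0.5, tolerance = 1e-8)
  h <- effective_drop_height(2, 5)
  expect_true(h > 1 && h < 2)
  expect_error(effective_drop_height(6, 5), "exceed")
  expect_error(effective_drop_height(0, 5), "positive")
})

test_that("settling runs are seed-reproducible and conserve vesicles", {
  cfg <- settling_config(n_vesicles = 5000, duration = 1800, seed = 11)
  a <- simulate_settling(cfg)
  b <- simulate_settling(cfg)
  expect_identical(a$attach_time, b$attach_time)
  expect_identical(a$diameters, b$diameters)
  expect_length(a$attach_time, 5000)
  # attached + suspended always partitions the population
  att <- sum(!is.na(a$attach_time))
  expect_equal(att + sum(is.na(a$attach_time)), 5000)
  # fraction is non-decreasing and bounded
  fr <- attached_fraction(a, seq(0, 1800, by = 60))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[1], 0)
  expect_true(all(fr <= 100))
})

test_that("effectively immobile vesicles never attach", {
  cfg <- settling_config(n_vesicles = 500, duration = 3600, seed = 12)
  res <- simulate_settling(cfg, diameters = rep(1e12, 500))
  expect_equal(attached_fraction(res, 3600), 0)
})

test_that("monodisperse attachment matches the analytic survival series", {
  cfg <- settling_config(n_vesicles = 2e4, duration = 2 * 3600, seed = 13)
  res <- simulate_settling(cfg, diameters = rep(150, 2e4))
  L <- res$h_cylinder * 1e-3
  D <- diffusion_constant(150)
  for (t in c(1800, 3600, 7200)) {
    frac_sim <- attached_fraction(res, t) / 100
    frac_ana <- 1 - survival_series(D, L, t)
    expect_lt(abs(frac_sim - frac_ana), 0.02)
  }
})

test_that("larger vesicles attach later on average", {
  cfg <- settling_config(n_vesicles = 2e4, duration = 2 * 3600, seed = 14)
  d <- rep(c(100, 300), each = 1e4)
  res <- simulate_settling(cfg, diameters = d)
  att <- !is.na(res$attach_time)
  t_small <- mean(res$attach_time[att & res$diameters == 100])
  t_big <- mean(res$attach_time[att & res$diameters == 300])
  expect_lt(t_small, t_big)
  # and the attached mean diameter grows with waiting time
  m <- attached_mean_diameter(res, c(1800, 7200))
  expect_lt(m[1], m[2])
})

test_that("attached-population accessors validate and sample reproducibly", {
  cfg <- settling_config(n_vesicles = 5000, duration = 3600, seed = 15)
  res <- simulate_settling(cfg)
  expect_error(attached_fraction(res, 7200), "duration")
  expect_warning(attached_mean_diameter(res, 0), "NA")

  s1 <- sample_attached(res, 3600, n = 100, seed = 3)
  s2 <- sample_attached(res, 3600, n = 100, seed = 3)
  expect_identical(as.numeric(s1), as.numeric(s2))
  att <- sum(!is.na(res$attach_time))
  full <- sample_attached(res, 3600, n = att, seed = 4)
  expect_setequal(as.numeric(full),
                  res$diameters[!is.na(res$attach_time)])
  expect_error(sample_attached(res, 3600, n = att + 1), "cannot sample")
})

test_that("membrane stretch scales diameters exactly", {
  s <- diameter_sample(c(100, 200))
  expect_equal(as.numeric(apply_stretch(s, 1.08)), c(108, 216))
  expect_equal(as.numeric(apply_stretch(s, 1)), c(100, 200))
  expect_equal(mean(apply_stretch(s, 1.05)), 1.05 * mean(s))
  expect_error(apply_stretch(s, 0.9), ">= 1")
})

test_that("thinner drops reach any attachment level sooner", {
  cfg <- settling_config(duration = 2 * 3600, seed = 16)
  sweep <- thickness_sweep(drop_heights = c(0.5, 1, 2), n_per_mm = 2e4,
                           config = cfg)
  expect_named(sweep, c("0.5 mm", "1 mm", "2 mm"))
  fr <- vapply(sweep, attached_fraction, numeric(1), t = 2 * 3600)
  expect_true(all(diff(fr) < 0))
  # vesicle counts scale with the drop height (equal concentration)
  expect_equal(vapply(sweep, function(r) length(r$diameters), numeric(1)),
               c("0.5 mm" = 1e4, "1 mm" = 2e4, "2 mm" = 4e4))
})

test_that("config validation catches unphysical setups", {
  expect_error(settling_config(duration = 95, dt = 10), "multiple")
  expect_error(settling_config(stretch_factor = 0.5), ">= 1")
  expect_error(settling_config(n_vesicles = 0), "positive")
  # a time step too coarse for the column triggers the discretisation warning
  cfg <- settling_config(dt = 10, duration = 100, n_vesicles = 10, seed = 1)
  expect_warning(simulate_settling(cfg, diameters = rep(0.5, 10)), "hcyl/5")
})
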