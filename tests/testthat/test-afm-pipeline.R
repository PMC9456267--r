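test_that("flattening removes tilt and line offsets without touching vesicles", {
  px <- 2000 / 512
  # pure plane tilt comes back as a zero map
  tilted <- gen_height_map(NULL, 2000, px,
                           artifacts = scan_artifacts(tilt = c(0.01, -0.02)))
  f <- flatten(tilted$map)
  expect_lt(max(abs(f$heights)), 1e-6)
  expect_true(f$flattened)

  # pure per-line offsets likewise
  lined <- gen_height_map(NULL, 2000, px,
                          artifacts = scan_artifacts(line_offset_sd = 3),
                          seed = 4)
  expect_lt(max(abs(flatten(lined$map)$heights)), 1e-6)

  # with sparse vesicles plus tilt, apex heights survive within 1 nm
  v <- place_vesicles(c(60, 80, 100), seed = 6, image_size = 2000)
  clean <- gen_height_map(v, 2000, px)
  arted <- gen_height_map(v, 2000, px,
                          artifacts = scan_artifacts(tilt = c(0.005, 0.003),
                                                     line_offset_sd = 2),
                          seed = 7)
  expect_lt(abs(max(flatten(arted$map)$heights) - max(clean$map$heights)), 1)
  expect_lt(abs(mean(flatten(arted$map)$heights)), 1e-9)
})

test_that("blob detection finds caps above the height filter and nothing else", {
  px <- 2000 / 512
  r <- render_single_cap(Rc = 55, H = 50, pixel_size = px)
  blobs <- detect_blobs(flatten(r$map))
  expect_equal(nrow(blobs), 1)
  expect_lt(abs(blobs$x_nm - 1000), px)
  expect_lt(abs(blobs$y_nm - 1000), px)

  # an 8 nm cap is below the membrane-thickness height filter
  low <- render_single_cap(Rc = 40, H = 8, pixel_size = px)
  expect_equal(nrow(detect_blobs(flatten(low$map))), 0)

  # an all-zero map yields an empty list
  zero <- height_map(matrix(0, 128, 128), px, flattened = TRUE)
  expect_equal(nrow(detect_blobs(zero)), 0)

  # unflattened input is refused
  expect_error(detect_blobs(r$map), "flatten")
})

test_that("profiles through a symmetric cap agree in all four directions", {
  r <- render_single_cap(Rc = 50, H = 80, pixel_size = 2)
  m <- flatten(r$map)
  profs <- extract_profiles(m, c(1000, 1000), half_length = 150)
  expect_length(profs, 4)
  maxima <- vapply(profs, function(p) max(p$heights), numeric(1))
  expect_true(all(abs(maxima - 80) < 1))
  fw <- vapply(profs, function(p) profile_fwhm_height(p)$fwhm, numeric(1))
  expect_lt((max(fw) - min(fw)) / mean(fw), 0.02)

  expect_error(extract_profiles(m, c(30, 30), half_length = 150),
               class = "vesicledrop_border_error")
})

test_that("FWHM extraction matches closed forms", {
  # triangle peaking at 10, reaching 0 at +/-10: half-max crossings at +/-5
  pos <- seq(-12, 12, by = 0.5)
  tri <- list(positions = pos, heights = pmax(10 - abs(pos), 0), angle = 0)
  expect_equal(profile_fwhm_height(tri)$fwhm, 10, tolerance = 1e-10)
  expect_equal(profile_fwhm_height(tri)$height, 10)

  # Gaussian of sd s has FWHM 2 sqrt(2 log 2) s
  s <- 18
  gauss <- list(positions = pos * 10,
                heights = 40 * exp(-(pos * 10)^2 / (2 * s^2)), angle = 45)
  expect_equal(profile_fwhm_height(gauss)$fwhm, 2 * sqrt(2 * log(2)) * s,
               tolerance = 0.01)

  flat <- list(positions = pos, heights = rep(0, length(pos)), angle = 90)
  expect_error(profile_fwhm_height(flat), "no positive peak")

  # no crossing on one side -> truncated error
  trunc <- list(positions = pos, heights = pmax(10 - abs(pos - 11), 0),
                angle = 0)
  expect_error(profile_fwhm_height(trunc),
               class = "vesicledrop_truncated_error")
})

test_that("asymmetry parameter follows its definition", {
  expect_equal(asymmetry(c(100, 100, 100, 100)), 0)
  expect_equal(asymmetry(c(100, 100, 100, 200)), 0.8)
  expect_equal(asymmetry(c(95, 100, 105, 100)), 0.1)
  expect_error(asymmetry(c(0, 0, 0, 0)), "zero")
})

test_that("circle fit recovers exact circles and rejects degenerate input", {
  th <- seq(0.3, pi - 0.3, length.out = 25)
  x <- 40 * cos(th); z <- -20 + 40 * sin(th)
  fit <- fit_circle(x, z)
  expect_equal(fit$radius, 40, tolerance = 1e-6)
  expect_equal(fit$center, c(0, -20), tolerance = 1e-5)

  # three points: the circumscribed circle passes through all of them
  x3 <- c(0, 2, 4); z3 <- c(0, 2, 0) # circumcircle radius 2, centre (2, 0)
  f3 <- fit_circle(x3, z3)
  expect_equal(f3$radius, 2, tolerance = 1e-6)
  expect_equal(f3$center, c(2, 0), tolerance = 1e-6)

  # the upper half of a noiseless cap profile is the cap circle itself
  r <- render_single_cap(Rc = 50, H = 100, pixel_size = 2)
  p <- extract_profiles(flatten(r$map), c(1000, 1000))[[1]]
  keep <- p$heights > 50
  expect_equal(fit_circle(p$positions[keep], p$heights[keep])$radius, 50,
               tolerance = 0.01)

  expect_error(fit_circle(c(0, 1), c(0, 1)), "3 points")
  expect_error(fit_circle(c(0, 1, 2), c(0, 1, 2)), "collinear")
})

test_that("geometric diameter obeys the spherical-cap relation and its domain", {
  expect_equal(geometric_diameter(50, 100), 100)
  expect_equal(geometric_diameter(40, 20), sqrt(2800))
  expect_lt(geometric_diameter(40, 0.001), 0.5)
  expect_warning(d <- geometric_diameter(10, 60), "domain")
  expect_true(is.nan(d))
  expect_error(geometric_diameter(-5, 10), "> 0")
})

test_that("pipeline recovers ground truth within 2% on noiseless caps", {
  grid <- expand.grid(Rc = c(20, 40, 70, 95), ratio = c(0.3, 0.6, 1.0))
  for (i in seq_len(nrow(grid))) {
    Rc <- grid$Rc[i]; H <- 2 * Rc * grid$ratio[i]
    dg_true <- sqrt(4 * Rc * H - H^2)
    tab <- analyze_image(render_single_cap(Rc, H)$map)
    acc <- tab[tab$accepted, ]
    expect_equal(nrow(acc), 1, info = sprintf("Rc=%g ratio=%g", Rc,
                                              grid$ratio[i]))
    expect_lt(abs(acc$dgeom_nm - dg_true) / dg_true, 0.02)
    expect_lt(abs(acc$H_nm - H) / H, 0.02)
    expect_lt(abs(acc$Rc_nm - Rc) / Rc, 0.05)
  }
})

test_that("asymmetry filter rejects smears and is monotone in its cutoff", {
  smear_only <- gen_height_map(NULL, 3000, 3000 / 512,
                               artifacts = scan_artifacts(n_smears = 3),
                               seed = 21)
  tab <- analyze_image(smear_only$map)
  expect_equal(sum(tab$accepted), 0)
  expect_true(all(tab$reject_reason %in% c("asymmetry", "border",
                                           "truncated_profile")))
  expect_gt(sum(tab$reject_reason == "asymmetry", na.rm = TRUE), 0)

  # mixed image: accepted count never increases as the cutoff drops
  v <- place_vesicles(c(70, 90), seed = 22, image_size = 3000)
  mixed <- gen_height_map(v, 3000, 3000 / 512,
                          artifacts = scan_artifacts(n_smears = 2),
                          seed = 23)
  counts <- vapply(c(0.8, 0.6, 0.3, 0.05), function(cut) {
    sum(analyze_image(mixed$map, asymmetry_max = cut)$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("accepted diameters are invariant under a 90-degree image rotation", {
  v <- place_vesicles(c(60, 85, 110), seed = 31, image_size = 2500)
  r <- gen_height_map(v, 2500, 2500 / 512, noise_sd = 0.3, seed = 32)
  rot <- height_map(t(r$map$heights)[ncol(r$map$heights):1, ],
                    r$map$pixel_size)
  d1 <- sort(analyze_image(r$map)$dgeom_nm)
  d2 <- sort(analyze_image(rot)$dgeom_nm)
  expect_length(d2, length(d1))
  expect_true(all(abs(d1 - d2) / d1 < 0.01))
})
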