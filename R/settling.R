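#' Einstein-Stokes diffusion constant
#'
#' `D = kB * T / (3 * pi * eta * d)` for a particle of hydrodynamic diameter
#' `d`. Inputs are in practical units (nm, K, Pa s); the result is in SI
#' m^2/s.
#'
#' @param d_hydr hydrodynamic diameter(s), nm.
#' @param temperature absolute temperature, K.
#' @param viscosity dynamic viscosity of the medium, Pa s.
#' @return Diffusion constant(s) in m^2/s (vectorised over `d_hydr`).
#' @export
#' @examples
#' diffusion_constant(150) # ~3e-12 m^2/s in water at room temperature
diffusion_constant <- function(d_hydr, temperature = 295,
                               viscosity = 0.95e-3) {
  check_positive(temperature, "temperature")
  check_positive(viscosity, "viscosity")
  if (any(d_hydr <= 0)) stop("`d_hydr` must be > 0", call. = FALSE)
  .kB * temperature / (3 * pi * viscosity * d_hydr * 1e-9)
}

#' Effective cylinder height of a sessile drop
#'
#' The spherical-cap drop of height `hdrop` on a circular base of radius
#' `rbase` is replaced by a cylinder whose height is the average height of
#' the cap surface over the base:
#' `hcyl = hdrop / 2 + hdrop^3 / (6 * rbase^2)`.
#'
#' @param drop_height cap height of the drop, mm.
#' @param base_radius base (substrate) radius, mm.
#' @return Effective cylinder height in mm, between `drop_height / 2`
#'   (flat-cap limit) and `drop_height`.
#' @export
#' @examples
#' effective_drop_height(1, 5) # 0.50667 mm
effective_drop_height <- function(drop_height, base_radius) {
  check_positive(drop_height, "drop_height")
  check_positive(base_radius, "base_radius")
  if (drop_height > base_radius) {
    stop("`drop_height` must not exceed `base_radius`", call. = FALSE)
  }
  drop_height / 2 + drop_height^3 / (6 * base_radius^2)
}

#' Settling simulation configuration
#'
#' Physics and geometry of the drop-settling Monte Carlo. Defaults describe a
#' 1 mm drop on a 5 mm mica disc at room temperature imaged over 20 h with a
#' 10 s step; `n_vesicles = 2e5` is a desk-scale population whose attachment
#' fractions and means are unbiased in N (raise it for tighter Monte Carlo
#' error).
#'
#' @param drop_height drop (cap) height, mm.
#' @param base_radius substrate radius, mm.
#' @param dt time step, s.
#' @param duration total simulated time, s; must be a multiple of `dt`.
#' @param n_vesicles number of simulated vesicles.
#' @param temperature temperature, K.
#' @param viscosity medium viscosity, Pa s.
#' @param stretch_factor multiplicative membrane-stretch factor (>= 1)
#'   applied post hoc to late-timepoint samples via [apply_stretch()];
#'   recorded here so reports carry it.
#' @param seed optional integer seed governing every random draw of the run.
#' @return A list of class `settling_config`.
#' @export
settling_config <- function(drop_height = 1, base_radius = 5, dt = 10,
                            duration = 20 * 3600, n_vesicles = 2e5,
                            temperature = 295, viscosity = 0.95e-3,
                            stretch_factor = 1, seed = NULL) {
  for (nm in c("drop_height", "base_radius", "dt", "duration", "n_vesicles",
               "temperature", "viscosity")) {
    check_positive(get(nm), nm)
  }
  if (abs(duration / dt - round(duration / dt)) > 1e-9) {
    stop("`duration` must be a multiple of `dt`", call. = FALSE)
  }
  if (stretch_factor < 1) {
    stop("`stretch_factor` must be >= 1", call. = FALSE)
  }
  structure(list(drop_height = drop_height, base_radius = base_radius,
                 dt = dt, duration = duration,
                 n_vesicles = as.integer(n_vesicles),
                 temperature = temperature, viscosity = viscosity,
                 stretch_factor = stretch_factor, seed = seed),
            class = "settling_config")
}

#' Simulate Brownian settling of vesicles in a sample drop
#'
#' Each vesicle performs an independent 1D random walk along the drop height:
#' initial positions are uniform in `(0, hcyl)` where `hcyl` is the effective
#' cylinder height ([effective_drop_height()]); every step adds a Gaussian
#' displacement of sd `sqrt(2 * D * dt)` with `D` from
#' [diffusion_constant()]; a vesicle at or below the substrate at a step end
#' attaches permanently and leaves the simulation; one crossing the drop top
#' is reflected. Absorption is only checked at step ends, so first-passage
#' times carry the usual O(sqrt(dt)) discretisation bias; a warning is issued
#' if the median step exceeds a fifth of the column height.
#'
#' @param config a [settling_config()].
#' @param diameters hydrodynamic diameters: a [diameter_sample()] or numeric
#'   vector (nm), one per vesicle (overrides `config$n_vesicles`), or `NULL`
#'   to draw `config$n_vesicles` diameters from the default NTA-fit
#'   log-normal population (median 149.2 nm, shape 1.461).
#' @return A list of class `settling_result` with `diameters` (nm),
#'   `attach_time` (s; `NA` for vesicles still suspended at the end),
#'   `h_cylinder` (mm) and the `config`.
#' @export
simulate_settling <- function(config = settling_config(), diameters = NULL) {
  stopifnot(inherits(config, "settling_config"))
  h_mm <- effective_drop_height(config$drop_height, config$base_radius)
  h_m <- h_mm * 1e-3
  n_steps <- as.integer(round(config$duration / config$dt))
  res <- with_seed(config$seed, {
    d <- if (is.null(diameters)) {
      unclass(gen_lognormal_sample(149.2, 1.461, config$n_vesicles))
    } else {
      as_diameter_values(diameters)
    }
    sigma <- sqrt(2 * diffusion_constant(d, config$temperature,
                                         config$viscosity) * config$dt)
    if (median(sigma) > h_m / 5) {
      warning("median step sd exceeds hcyl/5; the discrete absorption rule ",
              "is unsafe at this dt", call. = FALSE)
    }
    z0 <- runif(length(d), 0, h_m)
    steps <- settle_walk(z0, sigma, h_m, n_steps)
    list(d = d, steps = steps)
  })
  structure(list(diameters = res$d,
                 attach_time = res$steps * config$dt,
                 h_cylinder = h_mm,
                 config = config),
            class = "settling_result")
}

#' @export
print.settling_result <- function(x, ...) {
  n <- length(x$diameters)
  att <- sum(!is.na(x$attach_time))
  cat(sprintf("<settling_result> %d vesicles, %.2f mm effective column\n",
              n, x$h_cylinder))
  cat(sprintf("  %.1f%% attached within %.1f h (T = %g K, eta = %g Pa s)\n",
              100 * att / n, x$config$duration / 3600,
              x$config$temperature, x$config$viscosity))
  invisible(x)
}

check_time <- function(result, t) {
  stopifnot(inherits(result, "settling_result"))
  if (any(t < 0) || any(t > result$config$duration)) {
    stop("`t` must lie in [0, duration]", call. = FALSE)
  }
  invisible(t)
}

#' Percentage of vesicles attached by time t
#'
#' @param result a [simulate_settling()] result.
#' @param t time(s) since drop placement, s.
#' @return Attached percentage(s), 0-100; non-decreasing in `t`.
#' @export
attached_fraction <- function(result, t) {
  check_time(result, t)
  at <- result$attach_time
  vapply(t, function(tt) 100 * sum(!is.na(at) & at <= tt) /
           length(at), numeric(1L))
}

#' Mean hydrodynamic diameter of the vesicles attached by time t
#'
#' @inheritParams attached_fraction
#' @return Mean diameter(s) in nm; `NA` (with a warning) where nothing has
#'   attached yet.
#' @export
attached_mean_diameter <- function(result, t) {
  check_time(result, t)
  at <- result$attach_time
  out <- vapply(t, function(tt) {
    sel <- !is.na(at) & at <= tt
    if (!any(sel)) NA_real_ else mean(result$diameters[sel])
  }, numeric(1L))
  if (anyNA(out)) {
    warning("no vesicles attached at some requested times; returning NA",
            call. = FALSE)
  }
  out
}

#' Randomly sample attached vesicles at time t
#'
#' Draws `n` vesicles uniformly without replacement from those attached to
#' the substrate by time `t`, emulating the analyst picking a fixed number of
#' imaged vesicles.
#'
#' @inheritParams attached_fraction
#' @param n sample size.
#' @param seed optional integer seed.
#' @return A [diameter_sample()] of the drawn hydrodynamic diameters.
#' @export
sample_attached <- function(result, t, n = 200, seed = NULL) {
  check_time(result, t)
  sel <- which(!is.na(result$attach_time) & result$attach_time <= t)
  if (length(sel) < n) {
    stop(sprintf("only %d vesicles attached by t = %g s; cannot sample %d",
                 length(sel), t, n), call. = FALSE)
  }
  idx <- with_seed(seed, sample(sel, n))
  diameter_sample(result$diameters[idx], label = "hydrodynamic",
                  source = sprintf("attached by %g s", t))
}

#' Apply a linear membrane-stretch factor to a diameter sample
#'
#' Models slow osmotic/adhesive stretching of the lipid bilayer as a
#' multiplicative increase of every diameter; applied post hoc to
#' late-timepoint samples, it does not alter diffusion during a run.
#'
#' @param sample a [diameter_sample()] or numeric vector, nm.
#' @param factor stretch factor >= 1 (1.08 models an 8% linear stretch).
#' @return A [diameter_sample()] with every diameter multiplied by `factor`.
#' @export
apply_stretch <- function(sample, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1) {
    stop("`factor` must be a single number >= 1", call. = FALSE)
  }
  values <- as_diameter_values(sample) * factor
  lab <- attr(sample, "label") %||% "hydrodynamic"
  diameter_sample(values, label = lab,
                  source = sprintf("stretched by factor %g", factor))
}

#' Settling runs across drop thicknesses at constant concentration
#'
#' Repeats the settling simulation for several drop heights, scaling the
#' vesicle count proportionally to the height (`n_per_mm` vesicles per mm) so
#' every drop holds the same concentration. Each run draws its own diameters
#' from the same population.
#'
#' @param drop_heights drop heights to simulate, mm.
#' @param n_per_mm vesicles per mm of drop height.
#' @param config template [settling_config()]; its `drop_height` and
#'   `n_vesicles` are overridden per run, and per-run seeds are derived from
#'   `config$seed`.
#' @param mu_star,sigma_star log-normal population the diameters are drawn
#'   from.
#' @return A named list of `settling_result`s, one per drop height.
#' @export
thickness_sweep <- function(drop_heights = c(0.5, 1, 2), n_per_mm = 2e5,
                            config = settling_config(),
                            mu_star = 149.2, sigma_star = 1.461) {
  seeds <- derive_seeds(config$seed, 2L * length(drop_heights))
  out <- lapply(seq_along(drop_heights), function(i) {
    cfg <- config
    cfg$drop_height <- drop_heights[i]
    cfg$n_vesicles <- as.integer(round(n_per_mm * drop_heights[i]))
    # distinct seeds for the diameter draw and the walk, so the initial
    # heights are independent of the diameters
    cfg$seed <- seeds[[2L * i]]
    d <- gen_lognormal_sample(mu_star, sigma_star, cfg$n_vesicles,
                              seed = seeds[[2L * i - 1L]])
    simulate_settling(cfg, diameters = d)
  })
  names(out) <- sprintf("%g mm", drop_heights)
  out
}
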