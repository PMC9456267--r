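#' Study configuration
#'
#' Bundles a scenario name, its parameters, a root seed and an output
#' directory. All randomness in [run_scenario()] flows from the root seed
#' through deterministic per-stage child seeds, so a configuration fully
#' determines every artifact written.
#'
#' @param scenario one of `"sim_settling"`, `"sim_stretch"`, `"bimodal"`,
#'   `"thickness_sweep"`, `"ratio"`, `"afm_timepoints"`.
#' @param params named list of scenario parameters (defaults are filled in
#'   per scenario by [run_scenario()]).
#' @param seed root integer seed.
#' @param out_dir output directory; created if missing.
#' @return A list of class `study_config`.
#' @export
study_config <- function(scenario, params = list(), seed = 1,
                         out_dir = tempfile("vesicledrop-")) {
  scenario <- match.arg(scenario,
                        c("sim_settling", "sim_stretch", "bimodal",
                          "thickness_sweep", "ratio", "afm_timepoints"))
  if (!is.list(params)) stop("`params` must be a list", call. = FALSE)
  structure(list(scenario = scenario, params = params, seed = seed,
                 out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' The file needs a top-level `scenario` key plus optional `seed`, `out_dir`
#' and a `params` mapping; unknown top-level keys are an error so typos are
#' caught early.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$scenario)) {
    stop(path, ": missing required field `scenario`", call. = FALSE)
  }
  extra <- setdiff(names(y), c("scenario", "params", "seed", "out_dir"))
  if (length(extra)) {
    stop(path, ": unknown top-level fields: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  study_config(y$scenario, params = y$params %||% list(),
               seed = y$seed %||% 1,
               out_dir = y$out_dir %||% dirname(path))
}

fill_defaults <- function(params, defaults) {
  for (nm in names(defaults)) {
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  }
  params
}

default_sim_params <- function() {
  list(drop_height = 1, base_radius = 5, dt = 10, hours = 20,
       n_vesicles = 2e5, temperature = 295, viscosity = 0.95e-3,
       mu_star = 149.2, sigma_star = 1.461, stretch_factor = 1.08,
       sample_size = 200, n_boot = 10000)
}

config_from_params <- function(p, seed) {
  settling_config(drop_height = p$drop_height, base_radius = p$base_radius,
                  dt = p$dt, duration = p$hours * 3600,
                  n_vesicles = p$n_vesicles, temperature = p$temperature,
                  viscosity = p$viscosity,
                  stretch_factor = p$stretch_factor, seed = seed)
}

write_manifest <- function(config, params, extra = list()) {
  manifest <- c(list(package = "vesicledrop",
                     version = as.character(utils::packageVersion("vesicledrop")),
                     scenario = config$scenario, seed = config$seed,
                     boltzmann_J_per_K = .kB),
                params, extra)
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

mean_ci_report <- function(m) {
  list(mean_nm = m$mean, ci_lo_nm = m$ci[1L], ci_hi_nm = m$ci[2L], n = m$n)
}

#' Run a reproducible study scenario
#'
#' Executes one of the canned experiments and writes its tables and JSON
#' reports (plus a `manifest.json` echoing every parameter, the defaulted
#' physical constants and the seed) into `config$out_dir`. Identical
#' configurations produce byte-identical artifacts.
#'
#' Scenarios:
#' * `sim_settling` — one settling run; writes the per-vesicle table
#'   (`vesicles.csv`) and an hourly time series of attached percentage and
#'   mean attached diameter (`summary.json`).
#' * `sim_stretch` — the timepoint comparison: samples of
#'   `sample_size` attached vesicles at 1 h and 20 h, the 20 h sample also
#'   with the membrane-stretch factor applied; bootstrap CIs and CI-overlap
#'   verdicts (`stretch_report.json`).
#' * `bimodal` — settling of a two-mode population; writes attached-size
#'   histograms at 1 h and 20 h.
#' * `thickness_sweep` — settling at several drop heights with
#'   concentration-matched vesicle counts; writes a long-format time series.
#' * `ratio` — log-normal fits of two diameter CSVs (`nta_csv`,
#'   `afm_csv`) and their median-ratio statistic (`ratio.json`).
#' * `afm_timepoints` — renders synthetic AFM images of two geometric
#'   populations, runs the image pipeline, fits both timepoints and writes
#'   blob reports and fits.
#'
#' @param config a [study_config()], or the path to a YAML file for
#'   [read_study_config()].
#' @return Invisibly, a list with the in-memory results and written paths.
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(config$scenario,
         sim_settling = scenario_sim_settling(config),
         sim_stretch = scenario_sim_stretch(config),
         bimodal = scenario_bimodal(config),
         thickness_sweep = scenario_thickness_sweep(config),
         ratio = scenario_ratio(config),
         afm_timepoints = scenario_afm_timepoints(config))
}

scenario_sim_settling <- function(config) {
  p <- fill_defaults(config$params, default_sim_params())
  seeds <- derive_seeds(config$seed, 2L)
  d <- gen_lognormal_sample(p$mu_star, p$sigma_star, p$n_vesicles,
                            seed = seeds[[1L]])
  res <- simulate_settling(config_from_params(p, seeds[[2L]]), diameters = d)
  vpath <- file.path(config$out_dir, "vesicles.csv")
  write.csv(data.frame(vesicle_id = seq_along(res$diameters),
                       diameter_nm = res$diameters,
                       attach_time_s = res$attach_time),
            vpath, row.names = FALSE)
  hours <- seq(0, p$hours)
  summary <- list(
    h_cylinder_mm = res$h_cylinder,
    time_h = hours,
    attached_percent = attached_fraction(res, hours * 3600),
    mean_attached_diameter_nm = suppressWarnings(
      attached_mean_diameter(res, hours * 3600)))
  spath <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  mpath <- write_manifest(config, p)
  invisible(list(result = res, paths = c(vpath, spath, mpath)))
}

scenario_sim_stretch <- function(config) {
  p <- fill_defaults(config$params, default_sim_params())
  seeds <- derive_seeds(config$seed, 5L)
  d <- gen_lognormal_sample(p$mu_star, p$sigma_star, p$n_vesicles,
                            seed = seeds[[1L]])
  res <- simulate_settling(config_from_params(p, seeds[[2L]]), diameters = d)
  t_early <- 3600
  t_late <- p$hours * 3600
  s_early <- sample_attached(res, t_early, p$sample_size, seed = seeds[[3L]])
  s_late <- sample_attached(res, t_late, p$sample_size, seed = seeds[[4L]])
  s_late_str <- apply_stretch(s_late, p$stretch_factor)
  boot_seeds <- derive_seeds(seeds[[5L]], 3L)
  m_early <- mean_with_ci(s_early, n_boot = p$n_boot, seed = boot_seeds[[1L]])
  m_late <- mean_with_ci(s_late, n_boot = p$n_boot, seed = boot_seeds[[2L]])
  m_late_str <- mean_with_ci(s_late_str, n_boot = p$n_boot,
                             seed = boot_seeds[[3L]])
  report <- list(
    early = c(list(time_h = t_early / 3600), mean_ci_report(m_early)),
    late = c(list(time_h = p$hours), mean_ci_report(m_late)),
    late_stretched = c(list(time_h = p$hours,
                            stretch_factor = p$stretch_factor),
                       mean_ci_report(m_late_str)),
    significant_without_stretch = ci_overlap_significant(m_early, m_late),
    significant_with_stretch = ci_overlap_significant(m_early, m_late_str))
  rpath <- file.path(config$out_dir, "stretch_report.json")
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = NA)
  mpath <- write_manifest(config, p)
  invisible(list(result = res, report = report, paths = c(rpath, mpath)))
}

scenario_bimodal <- function(config) {
  p <- fill_defaults(config$params, c(default_sim_params(),
                                      list(mix = 0.5,
                                           mode1 = list(mu_star = 70,
                                                        sigma_star = 1.3),
                                           mode2 = list(mu_star = 250,
                                                        sigma_star = 1.3),
                                           bin_width = 10)))
  seeds <- derive_seeds(config$seed, 2L)
  d <- gen_bimodal_sample(p$mix, p$mode1, p$mode2, n = p$n_vesicles,
                          seed = seeds[[1L]])
  res <- simulate_settling(config_from_params(p, seeds[[2L]]), diameters = d)
  paths <- character(0)
  for (h in c(1, p$hours)) {
    sel <- !is.na(res$attach_time) & res$attach_time <= h * 3600
    hist <- sample_to_histogram(res$diameters[sel], p$bin_width)
    path <- file.path(config$out_dir, sprintf("attached_%dh.csv", h))
    write_histogram(hist, path)
    paths <- c(paths, path)
  }
  mpath <- write_manifest(config, p[setdiff(names(p), c("mode1", "mode2"))],
                          extra = list(mode1 = p$mode1, mode2 = p$mode2))
  invisible(list(result = res, paths = c(paths, mpath)))
}

scenario_thickness_sweep <- function(config) {
  p <- fill_defaults(config$params,
                     c(default_sim_params(),
                       list(drop_heights = c(0.5, 1, 2), n_per_mm = 2e5)))
  sweep <- thickness_sweep(p$drop_heights, p$n_per_mm,
                           config_from_params(p, config$seed),
                           mu_star = p$mu_star, sigma_star = p$sigma_star)
  hours <- seq(0, p$hours)
  rows <- do.call(rbind, lapply(names(sweep), function(nm) {
    data.frame(drop_height_mm = sweep[[nm]]$config$drop_height,
               time_h = hours,
               attached_percent = attached_fraction(sweep[[nm]], hours * 3600),
               mean_attached_diameter_nm = suppressWarnings(
                 attached_mean_diameter(sweep[[nm]], hours * 3600)))
  }))
  tpath <- file.path(config$out_dir, "thickness_sweep.csv")
  write.csv(rows, tpath, row.names = FALSE)
  mpath <- write_manifest(config, p)
  invisible(list(sweep = sweep, series = rows, paths = c(tpath, mpath)))
}

scenario_ratio <- function(config) {
  p <- config$params
  for (field in c("nta_csv", "afm_csv")) {
    if (is.null(p[[field]])) {
      stop("ratio scenario requires parameter `", field,
           "` (path to a diameter CSV)", call. = FALSE)
    }
  }
  p <- fill_defaults(p, list(n_boot = 10000))
  seeds <- derive_seeds(config$seed, 2L)
  fit_nta <- fit_lognormal(read_diameters(p$nta_csv, label = "hydrodynamic"),
                           n_boot = p$n_boot, seed = seeds[[1L]])
  fit_afm <- fit_lognormal(read_diameters(p$afm_csv, label = "geometric"),
                           n_boot = p$n_boot, seed = seeds[[2L]])
  rat <- withCallingHandlers(
    nta_afm_ratio(fit_nta, fit_afm),
    warning = function(w) invokeRestart("muffleWarning"))
  report <- list(nta = list(mu_star = fit_nta$mu_star,
                            sigma_star = fit_nta$sigma_star),
                 afm = list(mu_star = fit_afm$mu_star,
                            sigma_star = fit_afm$sigma_star),
                 ratio = rat$ratio, shapes_compatible = rat$shapes_compatible)
  rpath <- file.path(config$out_dir, "ratio.json")
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = NA)
  mpath <- write_manifest(config, p)
  invisible(list(fit_nta = fit_nta, fit_afm = fit_afm, ratio = rat,
                 paths = c(rpath, mpath)))
}

scenario_afm_timepoints <- function(config) {
  p <- fill_defaults(config$params, list(
    early = list(mu_star = 71.1, sigma_star = 1.431),
    late = list(mu_star = 79.8, sigma_star = 1.436),
    n_images = 2, vesicles_per_image = 12, height_ratio = 0.8,
    image_size = 3000, pixel_size = 3000 / 512, noise_sd = 0.5,
    n_boot = 10000))
  seeds <- derive_seeds(config$seed, 3L)
  analyze_tp <- function(pop, seed) {
    img_seeds <- derive_seeds(seed, 2L * p$n_images)
    dg <- numeric(0)
    blobs_all <- list()
    for (i in seq_len(p$n_images)) {
      d <- gen_lognormal_sample(pop$mu_star, pop$sigma_star,
                                p$vesicles_per_image,
                                seed = img_seeds[[2L * i - 1L]],
                                label = "geometric")
      truth <- place_vesicles(unclass(d), p$height_ratio, p$image_size,
                              seed = img_seeds[[2L * i]])
      render <- gen_height_map(truth, p$image_size, p$pixel_size,
                               noise_sd = p$noise_sd,
                               seed = img_seeds[[2L * i]])
      blobs <- analyze_image(render$map)
      blobs$image <- i
      blobs_all[[i]] <- blobs
      dg <- c(dg, blobs$dgeom_nm[blobs$accepted])
    }
    list(dgeom = dg, blobs = do.call(rbind, blobs_all))
  }
  early <- analyze_tp(p$early, seeds[[1L]])
  late <- analyze_tp(p$late, seeds[[2L]])
  boot_seeds <- derive_seeds(seeds[[3L]], 2L)
  fit_early <- fit_lognormal(diameter_sample(early$dgeom, "geometric"),
                             n_boot = p$n_boot, seed = boot_seeds[[1L]])
  fit_late <- fit_lognormal(diameter_sample(late$dgeom, "geometric"),
                            n_boot = p$n_boot, seed = boot_seeds[[2L]])
  paths <- c(
    write_blob_report(early$blobs,
                      file.path(config$out_dir, "blobs_early.csv")),
    write_blob_report(late$blobs,
                      file.path(config$out_dir, "blobs_late.csv")),
    write_fit_json(fit_early, file.path(config$out_dir, "fit_early.json")),
    write_fit_json(fit_late, file.path(config$out_dir, "fit_late.json")))
  mpath <- write_manifest(config,
                          p[setdiff(names(p), c("early", "late"))],
                          extra = list(early = p$early, late = p$late))
  invisible(list(fit_early = fit_early, fit_late = fit_late,
                 blobs_early = early$blobs, blobs_late = late$blobs,
                 paths = c(paths, mpath)))
}
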