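#' AFM-style height maps
#'
#' A `height_map` is a rectangular grid of surface heights in nanometres with
#' a physical pixel pitch. Rows are scan lines (y), columns are the fast-scan
#' axis (x); the centre of pixel `[i, j]` sits at physical coordinates
#' `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)`.
#'
#' @param heights numeric matrix of heights in nm.
#' @param pixel_size pixel pitch in nm (> 0).
#' @param flattened logical; `TRUE` once scan artifacts have been removed and
#'   the zero level set (see [flatten()]).
#' @return A list of class `height_map`.
#' @export
height_map <- function(heights, pixel_size, flattened = FALSE) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    stop("`heights` must be a numeric matrix", call. = FALSE)
  }
  check_positive(pixel_size, "pixel_size")
  structure(list(heights = heights, pixel_size = pixel_size,
                 flattened = isTRUE(flattened)),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, %.3g nm/px (%.2f x %.2f um), %s\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              ncol(x$heights) * x$pixel_size / 1000,
              nrow(x$heights) * x$pixel_size / 1000,
              if (x$flattened) "flattened" else "raw"))
  cat(sprintf("  height range [%.2f, %.2f] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

# In-plane footprint radius of a spherical cap (sphere radius Rc, cap height H)
# as seen from above: the cap meets the substrate at sqrt(2*Rc*H - H^2) when
# H <= Rc; beyond the hemisphere the widest visible extent is the equator, Rc.
cap_footprint_radius <- function(Rc, H) {
  ifelse(H <= Rc, sqrt(pmax(2 * Rc * H - H^2, 0)), Rc)
}

#' Spherical-cap parameters from a free-floating diameter
#'
#' Inverts the equal-surface-area cap relation `dgeom = sqrt(4*Rc*H - H^2)`:
#' given the free-floating diameter and a deformation ratio
#' `height_ratio = H / dgeom` in `(0, 1]`, returns the cap height
#' `H = height_ratio * dgeom` and sphere radius
#' `Rc = dgeom * (1 + height_ratio^2) / (4 * height_ratio)`.
#' `height_ratio = 1` is the undeformed sphere (`H = dgeom`, `Rc = dgeom / 2`).
#'
#' @param dgeom free-floating geometric diameter(s), nm.
#' @param height_ratio cap height as a fraction of `dgeom`, in `(0, 1]`.
#' @return A data.frame with columns `Rc_true`, `H_true`, `dgeom_true`.
#' @export
cap_from_diameter <- function(dgeom, height_ratio = 0.8) {
  if (any(dgeom <= 0)) stop("`dgeom` must be > 0", call. = FALSE)
  if (any(height_ratio <= 0 | height_ratio > 1)) {
    stop("`height_ratio` must be in (0, 1]", call. = FALSE)
  }
  H <- height_ratio * dgeom
  Rc <- dgeom * (1 + height_ratio^2) / (4 * height_ratio)
  data.frame(Rc_true = Rc, H_true = H, dgeom_true = dgeom)
}

#' Lay out ground-truth vesicles inside an image
#'
#' Places spherical-cap vesicles with the given free-floating diameters at
#' random, non-overlapping positions with a border margin, by rejection
#' sampling.
#'
#' @inheritParams cap_from_diameter
#' @param image_size image side length in nm (square image).
#' @param margin minimum distance of a centre from any image border, nm.
#' @param min_gap minimum clearance between cap footprints, nm.
#' @param seed optional integer seed.
#' @param max_tries placement attempts per vesicle before giving up.
#' @return Ground-truth data.frame with columns `center_x`, `center_y`,
#'   `Rc_true`, `H_true`, `dgeom_true` (all nm).
#' @export
place_vesicles <- function(dgeom, height_ratio = 0.8, image_size = 3000,
                           margin = 250, min_gap = 20, seed = NULL,
                           max_tries = 2000) {
  caps <- cap_from_diameter(dgeom, height_ratio)
  foot <- cap_footprint_radius(caps$Rc_true, caps$H_true)
  n <- nrow(caps)
  with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, margin, image_size - margin)
        y <- runif(1, margin, image_size - margin)
        if (i == 1L) { ok <- TRUE } else {
          j <- seq_len(i - 1L)
          ok <- all(sqrt((xs[j] - x)^2 + (ys[j] - y)^2) >
                      foot[j] + foot[i] + min_gap)
        }
        if (ok) { xs[i] <- x; ys[i] <- y; placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not place vesicle ", i, " without overlap; ",
             "reduce the number or size of vesicles", call. = FALSE)
      }
    }
    cbind(data.frame(center_x = xs, center_y = ys), caps)
  })
}

#' Scan-artifact configuration for the height-map generator
#'
#' All artifacts are opt-in so the flattening stage can be exercised in
#' isolation. `tilt` is a linear background plane in nm per nm of x and y.
#' Smears are elongated Gaussian ridges standing in for probe-dragged
#' objects; they exercise the asymmetry filter, not tip physics.
#'
#' @param line_offset_sd sd of per-scanline height offsets, nm.
#' @param tilt length-2 gradient `c(gx, gy)` of a background plane, nm/nm.
#' @param n_smears number of smear objects to add.
#' @param smear_height smear peak height, nm.
#' @param smear_sd length-2 `c(sd_long, sd_short)` Gaussian sds of the smear
#'   along its long and short axes, nm.
#' @return A list of class `scan_artifacts`.
#' @export
scan_artifacts <- function(line_offset_sd = 0, tilt = c(0, 0), n_smears = 0,
                           smear_height = 30, smear_sd = c(70, 17.5)) {
  stopifnot(length(tilt) == 2L, length(smear_sd) == 2L,
            line_offset_sd >= 0, n_smears >= 0)
  structure(list(line_offset_sd = line_offset_sd, tilt = as.numeric(tilt),
                 n_smears = as.integer(n_smears),
                 smear_height = smear_height,
                 smear_sd = as.numeric(smear_sd)),
            class = "scan_artifacts")
}

#' Render a synthetic AFM height map of spherical-cap vesicles
#'
#' Each vesicle is rendered as an exact spherical cap evaluated at pixel
#' centres: `z(r) = sqrt(Rc^2 - r^2) - (Rc - H)`, clipped at zero, on a zero
#' baseline. Optional Gaussian pixel noise, per-scanline offsets, a background
#' tilt plane, and elongated smear objects emulate common AFM artifacts.
#' Overlapping surfaces combine by taking the pointwise maximum.
#'
#' @param vesicles ground-truth data.frame as produced by [place_vesicles()]
#'   (columns `center_x`, `center_y`, `Rc_true`, `H_true`); may have 0 rows.
#' @param image_size image side length in nm.
#' @param pixel_size pixel pitch in nm.
#' @param noise_sd sd of i.i.d. Gaussian height noise, nm.
#' @param artifacts a [scan_artifacts()] configuration.
#' @param seed optional integer seed.
#' @return A list with elements `map` (a raw [height_map()]) and `vesicles`
#'   (the ground truth, with `dgeom_true` and an `overlap` flag column).
#' @export
gen_height_map <- function(vesicles, image_size = 3000,
                           pixel_size = 3000 / 512, noise_sd = 0,
                           artifacts = scan_artifacts(), seed = NULL) {
  check_positive(pixel_size, "pixel_size")
  stopifnot(inherits(artifacts, "scan_artifacts"), noise_sd >= 0)
  if (is.null(vesicles) || nrow(vesicles) == 0L) {
    vesicles <- data.frame(center_x = numeric(0), center_y = numeric(0),
                           Rc_true = numeric(0), H_true = numeric(0))
  }
  need <- c("center_x", "center_y", "Rc_true", "H_true")
  if (!all(need %in% names(vesicles))) {
    stop("`vesicles` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(vesicles) &&
      (any(vesicles$H_true <= 0) ||
       any(vesicles$H_true > 2 * vesicles$Rc_true))) {
    stop("each vesicle needs 0 < H_true <= 2 * Rc_true", call. = FALSE)
  }
  npx <- max(2L, round(image_size / pixel_size))
  xc <- (seq_len(npx) - 0.5) * pixel_size # column centres
  yc <- (seq_len(npx) - 0.5) * pixel_size # row centres
  z <- matrix(0, nrow = npx, ncol = npx)

  foot <- cap_footprint_radius(vesicles$Rc_true, vesicles$H_true)
  if (nrow(vesicles) &&
      any(vesicles$center_x - foot < 0 | vesicles$center_x + foot > image_size |
          vesicles$center_y - foot < 0 | vesicles$center_y + foot > image_size)) {
    stop("vesicles must fit inside the image", call. = FALSE)
  }

  overlap <- rep(FALSE, nrow(vesicles))
  if (nrow(vesicles) > 1L) {
    for (i in seq_len(nrow(vesicles) - 1L)) {
      for (j in seq(i + 1L, nrow(vesicles))) {
        d <- sqrt((vesicles$center_x[i] - vesicles$center_x[j])^2 +
                  (vesicles$center_y[i] - vesicles$center_y[j])^2)
        if (d < foot[i] + foot[j]) overlap[i] <- overlap[j] <- TRUE
      }
    }
    if (any(overlap)) {
      warning("overlapping vesicle footprints; surfaces combined by maximum",
              call. = FALSE)
    }
  }

  for (i in seq_len(nrow(vesicles))) {
    Rc <- vesicles$Rc_true[i]; H <- vesicles$H_true[i]
    cx <- vesicles$center_x[i]; cy <- vesicles$center_y[i]
    cols <- which(abs(xc - cx) <= foot[i] + pixel_size)
    rows <- which(abs(yc - cy) <= foot[i] + pixel_size)
    if (!length(cols) || !length(rows)) next
    r2 <- outer((yc[rows] - cy)^2, (xc[cols] - cx)^2, `+`)
    cap <- matrix(0, nrow = length(rows), ncol = length(cols))
    inside <- r2 <= Rc^2
    cap[inside] <- sqrt(Rc^2 - r2[inside]) - (Rc - H)
    cap <- pmax(cap, 0)
    z[rows, cols] <- pmax(z[rows, cols], cap)
  }

  z <- with_seed(seed, {
    if (artifacts$n_smears > 0L) {
      for (s in seq_len(artifacts$n_smears)) {
        scx <- runif(1, 0.15 * image_size, 0.85 * image_size)
        scy <- runif(1, 0.15 * image_size, 0.85 * image_size)
        theta <- runif(1, 0, pi)
        sl <- artifacts$smear_sd[1]; ss <- artifacts$smear_sd[2]
        du <- outer(rep(1, npx), xc - scx) * cos(theta) +
              outer(yc - scy, rep(1, npx)) * sin(theta)
        dv <- -outer(rep(1, npx), xc - scx) * sin(theta) +
              outer(yc - scy, rep(1, npx)) * cos(theta)
        smear <- artifacts$smear_height *
          exp(-(du^2 / (2 * sl^2) + dv^2 / (2 * ss^2)))
        z <- pmax(z, smear)
      }
    }
    if (any(artifacts$tilt != 0)) {
      z <- z + outer(rep(1, npx), xc) * artifacts$tilt[1] +
               outer(yc, rep(1, npx)) * artifacts$tilt[2]
    }
    if (artifacts$line_offset_sd > 0) {
      z <- z + rnorm(npx, sd = artifacts$line_offset_sd)
    }
    if (noise_sd > 0) {
      z <- z + matrix(rnorm(npx * npx, sd = noise_sd), nrow = npx)
    }
    z
  })

  vesicles$dgeom_true <- if (nrow(vesicles)) {
    sqrt(4 * vesicles$Rc_true * vesicles$H_true - vesicles$H_true^2)
  } else numeric(0)
  vesicles$overlap <- overlap
  list(map = height_map(z, pixel_size, flattened = FALSE),
       vesicles = vesicles)
}
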