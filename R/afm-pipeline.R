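#' Flatten a height map
#'
#' Standard AFM pre-processing: (i) subtract the median height of every scan
#' line (robust to sparse tall vesicles), (ii) remove a global least-squares
#' background plane, (iii) set the zero level to the image mean. Sets the
#' `flattened` flag consumed by [detect_blobs()].
#'
#' @param map a [height_map()].
#' @return A flattened [height_map()].
#' @export
flatten <- function(map) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  h <- h - apply(h, 1L, median)
  nr <- nrow(h); nc <- ncol(h)
  px <- map$pixel_size
  x <- rep((seq_len(nc) - 0.5) * px, each = nr)
  y <- rep((seq_len(nr) - 0.5) * px, times = nc)
  fit <- stats::lm.fit(cbind(1, x, y), as.vector(h))
  h <- h - matrix(fit$fitted.values, nrow = nr)
  h <- h - mean(h)
  height_map(h, map$pixel_size, flattened = TRUE)
}

# Separable Gaussian blur with edge replication; sd in pixels.
blur_gauss <- function(m, sd_px) {
  if (sd_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sd_px))
  k <- dnorm(seq(-r, r), sd = sd_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1L], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2L))[(r + 1L):(r + length(v))]
  }
  m <- apply(m, 2L, conv1)          # along columns
  t(apply(m, 1L, conv1))            # along rows
}

# Strict local maxima of `m` above `threshold` over the 8-neighbourhood.
# Ties on plateaus are broken towards the lowest (row, col) index.
local_maxima <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  is_max <- m > threshold
  # strictly greater than "earlier" neighbours, >= "later" ones
  for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))) {
    is_max <- is_max & m > shift(d[1], d[2])
  }
  for (d in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    is_max <- is_max & m >= shift(d[1], d[2])
  }
  which(is_max, arr.ind = TRUE)
}

# Quick FWHM estimate (in pixels) around a seed on a smoothed map, used only
# to size the Gaussian-fit window.
est_fwhm_px <- function(m, r0, c0) {
  half <- m[r0, c0] / 2
  run <- function(vals) {
    i <- which(vals < half)
    if (length(i)) i[1L] - 1L else length(vals)
  }
  wx <- run(m[r0, seq(c0, ncol(m))]) + run(m[r0, seq(c0, 1L)])
  wy <- run(m[seq(r0, nrow(m)), c0]) + run(m[seq(r0, 1L), c0])
  max(2L, (wx + wy) / 2)
}

#' Detect vesicle-like blobs in a flattened height map
#'
#' Local maxima above `height_min` (after light Gaussian smoothing) seed
#' windowed 2D elliptical Gaussian fits that refine each candidate's centre to
#' sub-pixel precision. Candidates are kept only if the fitted height exceeds
#' `height_min` (rejects features thinner than a deflated double lipid
#' membrane) and the fitted FWHM is below `fwhm_max`.
#'
#' @param map a flattened [height_map()].
#' @param fwhm_max maximum fitted full width at half maximum, nm.
#' @param height_min minimum fitted blob height, nm.
#' @param smooth_sd_px sd of the detection pre-smoothing, in pixels.
#' @return A data.frame with one row per candidate blob: `x_nm`, `y_nm`
#'   (sub-pixel centre), `height_fit_nm`, `fwhm_fit_nm`.
#' @export
detect_blobs <- function(map, fwhm_max = 200, height_min = 10,
                         smooth_sd_px = 1) {
  stopifnot(inherits(map, "height_map"))
  if (!map$flattened) {
    stop("`map` must be flattened first; see flatten()", call. = FALSE)
  }
  h <- map$heights; px <- map$pixel_size
  sm <- blur_gauss(h, smooth_sd_px)
  seeds <- local_maxima(sm, height_min)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      height_fit_nm = numeric(0), fwhm_fit_nm = numeric(0))
  if (nrow(seeds) == 0L) return(empty)
  seeds <- seeds[order(sm[seeds], decreasing = TRUE), , drop = FALSE]

  acc <- list()
  for (s in seq_len(nrow(seeds))) {
    r0 <- seeds[s, 1L]; c0 <- seeds[s, 2L]
    w_px <- est_fwhm_px(sm, r0, c0)
    half <- max(4L, ceiling(1.5 * w_px))
    rows <- max(1L, r0 - half):min(nrow(h), r0 + half)
    cols <- max(1L, c0 - half):min(ncol(h), c0 + half)
    dat <- data.frame(
      x = rep((cols - 0.5) * px, each = length(rows)),
      y = rep((rows - 0.5) * px, times = length(cols)),
      z = as.vector(h[rows, cols])
    )
    start <- list(A = h[r0, c0], x0 = (c0 - 0.5) * px, y0 = (r0 - 0.5) * px,
                  sx = w_px * px / 2.3548, sy = w_px * px / 2.3548)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))),
        data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- as.list(coef(fit))
    fwhm <- 2.3548 * (abs(p$sx) + abs(p$sy)) / 2
    # fitted centre must stay inside its window, else the fit diverged
    if (p$x0 < min(dat$x) || p$x0 > max(dat$x) ||
        p$y0 < min(dat$y) || p$y0 > max(dat$y)) next
    if (!(p$A > height_min) || !(fwhm < fwhm_max)) next
    dup <- FALSE
    for (a in acc) {
      if (sqrt((a$x_nm - p$x0)^2 + (a$y_nm - p$y0)^2) <
          max(fwhm, a$fwhm_fit_nm) / 2) { dup <- TRUE; break }
    }
    if (dup) next
    acc[[length(acc) + 1L]] <- data.frame(
      x_nm = p$x0, y_nm = p$y0, height_fit_nm = p$A, fwhm_fit_nm = fwhm)
  }
  if (!length(acc)) return(empty)
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

# Bilinear interpolation of map heights at physical coordinates (nm).
# Returns NA outside the grid of pixel centres.
bilinear <- function(map, xs, ys) {
  h <- map$heights; px <- map$pixel_size
  nr <- nrow(h); nc <- ncol(h)
  cf <- xs / px - 0.5 # 0-based fractional column index
  rf <- ys / px - 0.5
  ok <- cf >= 0 & cf <= nc - 1 & rf >= 0 & rf <= nr - 1
  c0 <- pmin(floor(cf), nc - 2L); r0 <- pmin(floor(rf), nr - 2L)
  tc <- cf - c0; tr <- rf - r0
  z <- rep(NA_real_, length(xs))
  i <- which(ok)
  if (length(i)) {
    r1 <- r0[i] + 1L; c1 <- c0[i] + 1L
    z[i] <- (1 - tr[i]) * ((1 - tc[i]) * h[cbind(r1, c1)] +
                           tc[i] * h[cbind(r1, c1 + 1L)]) +
            tr[i] * ((1 - tc[i]) * h[cbind(r1 + 1L, c1)] +
                     tc[i] * h[cbind(r1 + 1L, c1 + 1L)])
  }
  z
}

# Catmull-Rom cubic kernel on a unit-spaced stencil p0..p3, evaluated at
# fractional offset t in [0,1] from p1.
cr_kernel <- function(p0, p1, p2, p3, t) {
  0.5 * (2 * p1 + (p2 - p0) * t +
         (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
         (3 * (p1 - p2) + p3 - p0) * t^3)
}

# Bicubic (Catmull-Rom) interpolation; less chord bias than bilinear on
# curved surfaces, so profile-derived circle fits are nearly unbiased even
# when a cap spans only ~10 pixels. Falls back to NA within 2 px of the
# border (where the 4x4 stencil does not fit).
bicubic <- function(map, xs, ys) {
  h <- map$heights; px <- map$pixel_size
  nr <- nrow(h); nc <- ncol(h)
  cf <- xs / px - 0.5
  rf <- ys / px - 0.5
  ok <- cf >= 1 & cf <= nc - 2 & rf >= 1 & rf <= nr - 2
  z <- rep(NA_real_, length(xs))
  i <- which(ok)
  if (!length(i)) return(z)
  c1 <- pmin(floor(cf[i]), nc - 3L); r1 <- pmin(floor(rf[i]), nr - 3L)
  tc <- cf[i] - c1; tr <- rf[i] - r1
  rows <- lapply(0:3, function(k) {
    rk <- r1 + k # R (1-based) row index of stencil row k: 0-based r1 - 1 + k
    cr_kernel(h[cbind(rk, c1 + 0L)], h[cbind(rk, c1 + 1L)],
              h[cbind(rk, c1 + 2L)], h[cbind(rk, c1 + 3L)], tc)
  })
  zi <- cr_kernel(rows[[1L]], rows[[2L]], rows[[3L]], rows[[4L]], tr)
  # clamp to the enclosing 2x2 neighbourhood to suppress cubic ringing at
  # steep cap edges, keeping the smooth-region accuracy
  q11 <- h[cbind(r1 + 1L, c1 + 1L)]; q12 <- h[cbind(r1 + 1L, c1 + 2L)]
  q21 <- h[cbind(r1 + 2L, c1 + 1L)]; q22 <- h[cbind(r1 + 2L, c1 + 2L)]
  z[i] <- pmin(pmax(zi, pmin(q11, q12, q21, q22)),
               pmax(q11, q12, q21, q22))
  z
}

#' Extract four line profiles through a blob centre
#'
#' Samples heights by bicubic interpolation along lines through `center` at
#' 0, 45, 90 and 135 degrees. Axis-aligned profiles step by one pixel pitch;
#' diagonal profiles step by `pixel_size * sqrt(2)` (the grid diagonal).
#'
#' @param map a (typically flattened) [height_map()].
#' @param center length-2 centre `c(x, y)` in nm.
#' @param half_length profile half-length in nm; total length is twice this.
#' @param angles profile directions in degrees.
#' @return A list of profiles, each a list with `positions` (nm, centred on
#'   the blob), `heights` (nm) and `angle`.
#' @export
extract_profiles <- function(map, center, half_length = 200,
                             angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(map, "height_map"), length(center) == 2L)
  px <- map$pixel_size
  out <- lapply(angles, function(a) {
    step <- if (a %% 90 == 0) px else px * sqrt(2)
    nhalf <- ceiling(half_length / step)
    tpos <- seq(-nhalf, nhalf) * step
    th <- a * pi / 180
    z <- bicubic(map, center[1L] + tpos * cos(th),
                 center[2L] + tpos * sin(th))
    if (anyNA(z)) return(NULL)
    list(positions = tpos, heights = z, angle = a)
  })
  if (any(vapply(out, is.null, logical(1L)))) {
    stop(errorCondition("blob centre too close to the image border",
                        class = c("vesicledrop_border_error", "error",
                                  "condition")))
  }
  out
}

#' Profile height and full width at half maximum
#'
#' `Hp` is the profile maximum; the FWHM is the distance between the two
#' half-maximum crossings nearest the peak, each linearly interpolated
#' between samples. A profile whose half-maximum level is never crossed on
#' one side (truncated blob) raises an error of class
#' `vesicledrop_truncated_error`.
#'
#' @param profile one profile as returned by [extract_profiles()].
#' @return A list with `fwhm` and `height`, both in nm.
#' @export
profile_fwhm_height <- function(profile) {
  z <- profile$heights; pos <- profile$positions
  if (max(z) <= 0) stop("profile has no positive peak", call. = FALSE)
  ipk <- which.max(z)
  Hp <- z[ipk]
  half <- Hp / 2
  cross <- function(idx) { # idx walks away from the peak
    below <- which(z[idx] < half)
    if (!length(below)) {
      stop(errorCondition("profile truncated: no half-maximum crossing",
                          class = c("vesicledrop_truncated_error", "error",
                                    "condition")))
    }
    j <- idx[below[1L]]         # first sample below half
    k <- idx[below[1L] - 1L]    # its neighbour towards the peak
    pos[k] + (half - z[k]) * (pos[j] - pos[k]) / (z[j] - z[k])
  }
  xr <- cross(seq(ipk, length(z)))
  xl <- cross(seq(ipk, 1L))
  list(fwhm = xr - xl, height = Hp)
}

#' Profile asymmetry parameter
#'
#' `(max - min) / mean` of the four directional FWHMs. Near-circular blobs
#' score close to 0; elongated scan artifacts score high and are rejected
#' above the cutoff (0.6 by default in [analyze_image()]).
#'
#' @param fwhms numeric vector of per-profile FWHMs, nm.
#' @return The dimensionless asymmetry.
#' @export
asymmetry <- function(fwhms) {
  if (any(!is.finite(fwhms))) stop("FWHMs must be finite", call. = FALSE)
  m <- mean(fwhms)
  if (m == 0) stop("mean FWHM is zero", call. = FALSE)
  (max(fwhms) - min(fwhms)) / m
}

#' Least-squares circle fit
#'
#' Algebraic (Kasa) initialisation by linear least squares, followed by
#' geometric refinement minimising the sum of squared radial residuals with
#' BFGS. Used to fit the cross-section of a spherical cap to the upper part
#' of a blob profile.
#'
#' @param x,z point coordinates (nm). At least 3 non-collinear points.
#' @return A list with `radius` and `center = c(x, z)`.
#' @export
fit_circle <- function(x, z) {
  if (length(x) != length(z)) stop("x and z lengths differ", call. = FALSE)
  if (length(x) < 3L) {
    stop("circle fit needs at least 3 points", call. = FALSE)
  }
  if (qr(cbind(x, z, 1))$rank < 3L) {
    stop("circle fit needs non-collinear points", call. = FALSE)
  }
  # Kasa: x^2 + z^2 = 2 a x + 2 b z + (r^2 - a^2 - b^2)
  sol <- stats::lm.fit(cbind(2 * x, 2 * z, 1), x^2 + z^2)$coefficients
  a <- sol[1L]; b <- sol[2L]
  r <- sqrt(max(sol[3L] + a^2 + b^2, .Machine$double.eps))
  obj <- function(p) sum((sqrt((x - p[1L])^2 + (z - p[2L])^2) - p[3L])^2)
  ref <- optim(c(a, b, r), obj, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))
  list(radius = unname(ref$par[3L]), center = unname(ref$par[1:2]))
}

#' Geometric diameter of a free-floating vesicle from its adsorbed cap
#'
#' A vesicle adsorbed as a spherical cap with sphere radius `Rc` and height
#' `H` has the same membrane surface area as a free-floating sphere of
#' diameter `dgeom = sqrt(4 * Rc * H - H^2)` (inextensible-bilayer
#' assumption). The expression is real only on the cap domain
#' `4 * Rc * H >= H^2`, i.e. `H <= 4 * Rc`; outside it `NaN` is returned with
#' a warning, never a clamped value.
#'
#' @param Rc fitted sphere (cap) radius, nm.
#' @param H cap height, nm.
#' @return `dgeom` in nm (vectorised); `NaN` where the cap domain is violated.
#' @export
#' @examples
#' geometric_diameter(50, 100) # undeformed sphere: 100
geometric_diameter <- function(Rc, H) {
  if (any(Rc <= 0) || any(H <= 0)) {
    stop("`Rc` and `H` must be > 0", call. = FALSE)
  }
  rad <- 4 * Rc * H - H^2
  bad <- rad < 0
  if (any(bad)) {
    warning(sum(bad), " blob(s) outside the spherical-cap domain ",
            "(4*Rc*H < H^2); returning NaN", call. = FALSE)
    rad[bad] <- NaN
  }
  sqrt(rad)
}

#' Analyse an AFM height image into accepted vesicle diameters
#'
#' Full pipeline: flatten, detect blobs, extract four directional profiles
#' per blob, compute per-profile FWHM and height, reject asymmetric blobs
#' (`asymmetry > asymmetry_max`), fit a circle to each profile's points above
#' half its height, average the circle radii into the cap radius `Rc` and the
#' profile heights into `H`, and convert to the free-floating geometric
#' diameter. Per-blob failures are recorded in `reject_reason`, never abort
#' the image.
#'
#' @param map a [height_map()]; flattened automatically unless already so.
#' @param fwhm_max,height_min detection filters, see [detect_blobs()].
#' @param asymmetry_max asymmetry rejection cutoff (dimensionless).
#' @param profile_half_length profile half-length, nm (defaults to
#'   `fwhm_max`, giving total profile length `2 * fwhm_max`).
#' @return A data.frame with columns `blob_id`, `x_nm`, `y_nm`, `H_nm`,
#'   `Rc_nm`, `height_fit_nm`, `asymmetry`, `dgeom_nm`, `accepted`,
#'   `reject_reason`. The number of spherical-cap domain violations is
#'   attached as attribute `"cap_domain_violations"`.
#' @export
analyze_image <- function(map, fwhm_max = 200, height_min = 10,
                          asymmetry_max = 0.6,
                          profile_half_length = fwhm_max) {
  stopifnot(inherits(map, "height_map"))
  if (!map$flattened) map <- flatten(map)
  blobs <- detect_blobs(map, fwhm_max = fwhm_max, height_min = height_min)
  cols <- c("blob_id", "x_nm", "y_nm", "H_nm", "Rc_nm", "height_fit_nm",
            "asymmetry", "dgeom_nm", "accepted", "reject_reason")
  if (nrow(blobs) == 0L) {
    out <- data.frame(blob_id = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), H_nm = numeric(0),
                      Rc_nm = numeric(0), height_fit_nm = numeric(0),
                      asymmetry = numeric(0), dgeom_nm = numeric(0),
                      accepted = logical(0), reject_reason = character(0))
    attr(out, "cap_domain_violations") <- 0L
    return(out)
  }
  n_domain <- 0L
  rows <- lapply(seq_len(nrow(blobs)), function(i) {
    res <- list(blob_id = i, x_nm = blobs$x_nm[i], y_nm = blobs$y_nm[i],
                H_nm = NA_real_, Rc_nm = NA_real_,
                height_fit_nm = blobs$height_fit_nm[i],
                asymmetry = NA_real_, dgeom_nm = NA_real_,
                accepted = FALSE, reject_reason = NA_character_)
    profs <- tryCatch(
      extract_profiles(map, c(blobs$x_nm[i], blobs$y_nm[i]),
                       half_length = profile_half_length),
      vesicledrop_border_error = function(e) NULL)
    if (is.null(profs)) {
      res$reject_reason <- "border"
      return(res)
    }
    fh <- lapply(profs, function(p) {
      tryCatch(profile_fwhm_height(p), error = function(e) NULL)
    })
    if (any(vapply(fh, is.null, logical(1L)))) {
      res$reject_reason <- "truncated_profile"
      return(res)
    }
    fwhms <- vapply(fh, `[[`, numeric(1L), "fwhm")
    hps <- vapply(fh, `[[`, numeric(1L), "height")
    res$asymmetry <- asymmetry(fwhms)
    res$H_nm <- mean(hps)
    if (res$asymmetry > asymmetry_max) {
      res$reject_reason <- "asymmetry"
      return(res)
    }
    if (res$H_nm <= height_min) {
      res$reject_reason <- "height"
      return(res)
    }
    radii <- vapply(seq_along(profs), function(j) {
      p <- profs[[j]]
      keep <- p$heights > hps[j] / 2
      tryCatch(fit_circle(p$positions[keep], p$heights[keep])$radius,
               error = function(e) NA_real_)
    }, numeric(1L))
    if (all(is.na(radii))) {
      res$reject_reason <- "circle_fit"
      return(res)
    }
    res$Rc_nm <- mean(radii, na.rm = TRUE)
    rad <- 4 * res$Rc_nm * res$H_nm - res$H_nm^2
    if (rad < 0) {
      res$reject_reason <- "cap_domain"
      return(res)
    }
    res$dgeom_nm <- sqrt(rad)
    res$accepted <- TRUE
    res
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out <- out[, cols]
  attr(out, "cap_domain_violations") <-
    sum(out$reject_reason == "cap_domain", na.rm = TRUE)
  out
}
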