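#' Read and write diameter samples as CSV
#'
#' The on-disk format is a headered CSV with the single column
#' `diameter_nm`. Reading validates the schema strictly and rejects
#' non-positive diameters, naming the offending rows.
#'
#' @param path file path.
#' @param label,source passed to [diameter_sample()] when reading.
#' @return `read_diameters()` returns a [diameter_sample()];
#'   `write_diameters()` returns `path` invisibly.
#' @export
read_diameters <- function(path, label = "hydrodynamic", source = path) {
  df <- read.csv(path, check.names = FALSE)
  check_schema(df, "diameter_nm", path)
  bad <- which(!is.finite(df$diameter_nm) | df$diameter_nm <= 0)
  if (length(bad)) {
    stop(sprintf("%s: diameters must be > 0; offending data rows: %s",
                 path, paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  diameter_sample(df$diameter_nm, label = label, source = source)
}

#' @rdname read_diameters
#' @param sample a [diameter_sample()] or numeric vector, nm.
#' @export
write_diameters <- function(sample, path) {
  values <- as_diameter_values(sample)
  write.csv(data.frame(diameter_nm = values), path, row.names = FALSE)
  invisible(path)
}

#' Read and write size histograms as CSV
#'
#' Columns `bin_center_nm,count`; bins must be strictly increasing and
#' equally spaced, counts non-negative with a positive total.
#'
#' @param path file path.
#' @return `read_histogram()` returns a [size_histogram()];
#'   `write_histogram()` returns `path` invisibly.
#' @export
read_histogram <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  check_schema(df, c("bin_center_nm", "count"), path)
  centers <- df$bin_center_nm
  if (length(centers) < 2L) {
    stop(path, ": a histogram needs at least 2 bins", call. = FALSE)
  }
  widths <- diff(centers)
  if (any(widths <= 0) ||
      max(abs(widths - widths[1L])) > 1e-6 * abs(widths[1L])) {
    stop(path, ": bin centres must be strictly increasing and equally spaced",
         call. = FALSE)
  }
  size_histogram(centers, df$count, bin_width = widths[1L])
}

#' @rdname read_histogram
#' @param histogram a [size_histogram()].
#' @export
write_histogram <- function(histogram, path) {
  stopifnot(inherits(histogram, "size_histogram"))
  write.csv(data.frame(bin_center_nm = histogram$bin_centers,
                       count = histogram$counts),
            path, row.names = FALSE)
  invisible(path)
}

check_schema <- function(df, expected, path) {
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) || length(extra)) {
    stop(sprintf("%s: column schema mismatch; missing: %s; unexpected: %s",
                 path,
                 if (length(missing)) paste(missing, collapse = ", ")
                 else "none",
                 if (length(extra)) paste(extra, collapse = ", ")
                 else "none"),
         call. = FALSE)
  }
  invisible(df)
}

#' Read and write height maps
#'
#' Height maps travel as a whitespace-delimited text matrix (or a 16-bit
#' grayscale TIFF when the `tiff` package is available) plus a JSON sidecar
#' holding `pixel_size_nm` and `height_scale`; stored values times
#' `height_scale` are heights in nm. The sidecar defaults to
#' `<path>.json`.
#'
#' @param map a [height_map()].
#' @param path data file path; format chosen by extension (`.tif`/`.tiff`
#'   for TIFF, anything else is text).
#' @param sidecar sidecar JSON path.
#' @return `write_height_map()` returns `path` invisibly;
#'   `read_height_map()` returns a [height_map()].
#' @export
write_height_map <- function(map, path,
                             sidecar = paste0(path, ".json")) {
  stopifnot(inherits(map, "height_map"))
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing TIFF requires the `tiff` package; use a .txt path",
           call. = FALSE)
    }
    lo <- min(map$heights)
    hi <- max(map$heights)
    scale <- if (hi > lo) (hi - lo) / 65535 else 1
    pix <- (map$heights - lo) / ifelse(scale > 0, scale, 1)
    tiff::writeTIFF(pix / 65535, path, bits.per.sample = 16L)
    meta <- list(pixel_size_nm = map$pixel_size, height_scale = scale,
                 height_offset_nm = lo, format = "tiff16")
  } else {
    write.table(format(map$heights, digits = 10, trim = TRUE), path,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    meta <- list(pixel_size_nm = map$pixel_size, height_scale = 1,
                 height_offset_nm = 0, format = "text")
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) {
    stop("sidecar metadata not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("pixel_size_nm", "height_scale")) {
    if (is.null(meta[[field]])) {
      stop(sidecar, ": missing required field `", field, "`", call. = FALSE)
    }
  }
  offset <- meta$height_offset_nm %||% 0
  if (identical(meta$format, "tiff16")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the `tiff` package", call. = FALSE)
    }
    pix <- tiff::readTIFF(path)
    h <- pix * 65535 * meta$height_scale + offset
  } else {
    h <- as.matrix(read.table(path))
    dimnames(h) <- NULL
    h <- h * meta$height_scale + offset
  }
  height_map(h, meta$pixel_size_nm, flattened = FALSE)
}

#' Write a blob report CSV
#'
#' Writes the per-blob table produced by [analyze_image()] with the stable
#' column set `blob_id,x_nm,y_nm,H_nm,Rc_nm,asymmetry,dgeom_nm,accepted,
#' reject_reason`.
#'
#' @param blobs data.frame from [analyze_image()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_blob_report <- function(blobs, path) {
  cols <- c("blob_id", "x_nm", "y_nm", "H_nm", "Rc_nm", "asymmetry",
            "dgeom_nm", "accepted", "reject_reason")
  write.csv(blobs[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a log-normal fit as JSON
#'
#' @param fit a [lognormal_fit()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lognormal_fit"))
  jsonlite::write_json(
    list(mu_star = fit$mu_star, mu_ci = fit$ci_mu,
         sigma_star = fit$sigma_star, sigma_ci = fit$ci_sigma,
         n = fit$n, n_boot = fit$n_boot),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lognormal_fit(j$mu_star, j$sigma_star,
                ci_mu = j$mu_ci, ci_sigma = j$sigma_ci,
                n = j$n %||% NA_integer_, n_boot = j$n_boot %||% NA_integer_)
}
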