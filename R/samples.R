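#' Diameter samples
#'
#' A `diameter_sample` is a numeric vector of particle diameters in nanometres
#' with a `label` attribute saying whether the values are geometric (AFM-style)
#' or hydrodynamic (NTA-style) diameters, and a free-text `source`.
#'
#' @param values numeric vector of diameters in nm; must be finite and > 0.
#' @param label `"hydrodynamic"` or `"geometric"`.
#' @param source free-text provenance string.
#' @return A numeric vector of class `diameter_sample`.
#' @export
#' @examples
#' diameter_sample(c(80, 120, 150), label = "hydrodynamic")
diameter_sample <- function(values,
                            label = c("hydrodynamic", "geometric"),
                            source = "") {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("a diameter sample must contain at least one value", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("diameters must be finite and > 0; offending entries: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  label <- match.arg(label)
  structure(values, label = label, source = source, class = "diameter_sample")
}

#' @export
print.diameter_sample <- function(x, ...) {
  cat(sprintf("<diameter_sample> %d %s diameters (nm)\n",
              length(x), attr(x, "label")))
  cat(sprintf("  median %.1f nm, range [%.1f, %.1f] nm\n",
              median(unclass(x)), min(x), max(x)))
  if (nzchar(attr(x, "source") %||% "")) {
    cat("  source:", attr(x, "source"), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_diameter_values <- function(x) {
  if (inherits(x, "diameter_sample")) return(as.numeric(unclass(x)))
  if (is.numeric(x)) {
    if (any(!is.finite(x) | x <= 0)) {
      stop("diameters must be finite and > 0", call. = FALSE)
    }
    return(as.numeric(x))
  }
  stop("expected a numeric vector or a diameter_sample", call. = FALSE)
}

#' Draw a log-normal diameter population
#'
#' Diameters are drawn i.i.d. from a log-normal distribution parameterised by
#' its median (scale) `mu_star` and multiplicative shape `sigma_star`; 68.3%
#' of the distribution's mass lies between `mu_star / sigma_star` and
#' `mu_star * sigma_star`. This is the canonical parameterisation for particle
#' size distributions and the one used for NTA/AFM population fits.
#'
#' @param mu_star median diameter in nm (> 0).
#' @param sigma_star multiplicative shape (>= 1); `1` gives a point mass.
#' @param n number of diameters to draw.
#' @param seed optional integer seed; identical seeds give identical samples.
#' @inheritParams diameter_sample
#' @return A [diameter_sample()].
#' @export
#' @examples
#' s <- gen_lognormal_sample(149.2, 1.461, n = 1000, seed = 1)
#' median(s)
gen_lognormal_sample <- function(mu_star, sigma_star, n, seed = NULL,
                                 label = "hydrodynamic",
                                 source = sprintf("lognormal(%g, %g)",
                                                  mu_star, sigma_star)) {
  check_positive(mu_star, "mu_star")
  if (!is.numeric(sigma_star) || length(sigma_star) != 1L || sigma_star < 1) {
    stop("`sigma_star` must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  values <- with_seed(seed, rlnorm(n, meanlog = log(mu_star),
                                   sdlog = log(sigma_star)))
  diameter_sample(values, label = label, source = source)
}

#' Draw a bimodal (two-component log-normal mixture) diameter population
#'
#' Emulates a hypothetical vesicle population with two size modes. Each value
#' is drawn from mode 1 with probability `mix`, else from mode 2; the
#' component assignment is kept in the `"component"` attribute (1 or 2) so the
#' mixture can be tested.
#'
#' @param mix mixture weight of mode 1, in `[0, 1]`.
#' @param mode1,mode2 lists with elements `mu_star` and `sigma_star`.
#' @inheritParams gen_lognormal_sample
#' @return A [diameter_sample()] with a `"component"` attribute.
#' @export
gen_bimodal_sample <- function(mix = 0.5,
                               mode1 = list(mu_star = 70, sigma_star = 1.3),
                               mode2 = list(mu_star = 250, sigma_star = 1.3),
                               n = 1000, seed = NULL,
                               label = "hydrodynamic") {
  if (!is.numeric(mix) || length(mix) != 1L || mix < 0 || mix > 1) {
    stop("`mix` must be a single weight in [0, 1]", call. = FALSE)
  }
  for (m in list(mode1, mode2)) {
    check_positive(m$mu_star, "mu_star")
    if (m$sigma_star < 1) stop("`sigma_star` must be >= 1", call. = FALSE)
  }
  out <- with_seed(seed, {
    comp <- 2L - rbinom(n, 1L, mix) # 1 w.p. mix, else 2
    v <- numeric(n)
    i1 <- comp == 1L
    v[i1] <- rlnorm(sum(i1), log(mode1$mu_star), log(mode1$sigma_star))
    v[!i1] <- rlnorm(sum(!i1), log(mode2$mu_star), log(mode2$sigma_star))
    list(values = v, comp = comp)
  })
  s <- diameter_sample(out$values, label = label,
                       source = sprintf("bimodal mix=%g", mix))
  attr(s, "component") <- out$comp
  s
}

#' Size histograms
#'
#' A binned size distribution in the format instruments export: equally spaced
#' bin centres (nm) with non-negative counts. Bins are half-open `[lo, hi)`
#' and anchored at zero.
#'
#' @param bin_centers strictly increasing, equally spaced bin centres in nm.
#' @param counts non-negative counts, same length as `bin_centers`.
#' @param bin_width bin width in nm.
#' @return A list of class `size_histogram`.
#' @export
size_histogram <- function(bin_centers, counts, bin_width) {
  check_positive(bin_width, "bin_width")
  if (length(bin_centers) != length(counts)) {
    stop("`bin_centers` and `counts` must have the same length", call. = FALSE)
  }
  if (length(bin_centers) > 1L) {
    d <- diff(bin_centers)
    if (any(d <= 0) || max(abs(d - bin_width)) > 1e-6 * bin_width) {
      stop("bin centres must be strictly increasing and spaced by `bin_width`",
           call. = FALSE)
    }
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) <= 0) stop("total count must be > 0", call. = FALSE)
  structure(list(bin_centers = as.numeric(bin_centers),
                 counts = as.numeric(counts),
                 bin_width = bin_width),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("<size_histogram> %d bins of %.3g nm, total count %g\n",
              length(x$bin_centers), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Bin a diameter sample into a size histogram
#'
#' Values are assigned to half-open bins `[k*w, (k+1)*w)` anchored at zero, so
#' every value lands in exactly one bin and the counts sum to the sample size.
#'
#' @param sample a [diameter_sample()] or numeric vector (nm).
#' @param bin_width bin width in nm.
#' @return A [size_histogram()] covering bins from zero to the largest value.
#' @export
sample_to_histogram <- function(sample, bin_width) {
  values <- as_diameter_values(sample)
  check_positive(bin_width, "bin_width")
  idx <- floor(values / bin_width) # 0-based bin index
  nbin <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbin)
  size_histogram(bin_centers = (seq_len(nbin) - 0.5) * bin_width,
                 counts = counts, bin_width = bin_width)
}
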