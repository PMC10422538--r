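# MicroDoppler (power Doppler) image formation and noise-bias removal.
# "Coherent integration" of the filtered ensemble is implemented as the
# per-pixel mean of squared magnitudes: integrating the complex samples
# before taking the modulus would cancel the Doppler phases and destroy the
# blood signal the filter just isolated. The mean (rather than the sum) over
# frames makes images comparable across ensemble lengths.

#' MicroDoppler image
#'
#' @param power Nonnegative 2-D array (linear power units).
#' @param timestamp Session time, seconds.
#' @param ensemble_index Index of the source ensemble.
#' @return Object of class `md_image`.
#' @export
md_image <- function(power, timestamp = 0, ensemble_index = NA_integer_) {
  stopifnot(is.matrix(power))
  if (any(!is.finite(power))) stop("power must be finite", call. = FALSE)
  structure(list(power = power, timestamp = timestamp,
                 ensemble_index = as.integer(ensemble_index)),
            class = "md_image")
}

#' Form a microDoppler image from a (filtered) ensemble
#'
#' Pixel power is `mean_n |s(x, z, n)|^2` over the slow-time ensemble.
#'
#' @param filtered An [iq_ensemble()] or an `svd_filter_result` (its
#'   `filtered` component is used).
#' @param ensemble_index Optional provenance index.
#' @return An [md_image()].
#' @export
power_doppler <- function(filtered, ensemble_index = NA_integer_) {
  if (inherits(filtered, "svd_filter_result")) filtered <- filtered$filtered
  stopifnot(is.array(filtered), length(dim(filtered)) == 3L)
  if (any(is.na(filtered)))
    stop("NaN in ensemble", if (!is.na(ensemble_index))
      paste0(" (ensemble ", ensemble_index, ")"), call. = FALSE)
  d <- dim(filtered)
  m <- Mod(unclass(filtered))^2
  dim(m) <- c(d[1] * d[2], d[3])
  md_image(matrix(rowMeans(m), d[1], d[2]),
           timestamp = attr(filtered, "timestamp") %||% 0,
           ensemble_index = ensemble_index)
}

#' MicroDoppler series
#'
#' One image per ensemble, strictly increasing timestamps.
#'
#' @param images List of [md_image()] objects.
#' @return Object of class `md_series`: 3-D `power` array
#'   (depth x lateral x time) plus `timestamps`.
#' @export
md_series <- function(images) {
  stopifnot(length(images) >= 1,
            all(vapply(images, inherits, logical(1), "md_image")))
  ts <- vapply(images, `[[`, numeric(1), "timestamp")
  if (any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  d <- dim(images[[1]]$power)
  power <- array(NA_real_, c(d, length(images)))
  for (k in seq_along(images)) power[, , k] <- images[[k]]$power
  structure(list(power = power, timestamps = ts), class = "md_series")
}

#' @export
print.md_series <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<md_series> %d x %d px, %d frames, t = [%g, %g] s\n",
              d[1], d[2], d[3], min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Estimate the additive noise-power profile
#'
#' Two transparent estimators of the noise bias carried by a microDoppler
#' image:
#' \describe{
#'   \item{`vessel_free_region`}{per-depth median of pixel power inside a
#'     declared vessel-free mask, broadcast laterally. Depth rows without
#'     masked pixels inherit the overall masked median.}
#'   \item{`high_order_residual`}{per-pixel mean power of the above-`high_cut`
#'     residual retained by [svd_filter()], rescaled to the noise power
#'     expected inside the target band. Because the SVD sorts directions by
#'     energy, the bottom singular orders carry systematically *less* than
#'     their dimension share of white-noise energy; the rescaling therefore
#'     uses the Marchenko-Pastur energy fraction of the bottom tail rather
#'     than the naive dimension ratio, which would under-estimate the noise
#'     by tens of percent.}
#' }
#'
#' @param x An [md_image()] (for `vessel_free_region`) or an
#'   `svd_filter_result` with a non-`NULL` residual
#'   (for `high_order_residual`).
#' @param method Estimator name.
#' @param mask Logical matrix declaring vessel-free pixels
#'   (`vessel_free_region` only).
#' @param target_dim Dimension of the singular-order band whose noise
#'   content is being estimated (`high_order_residual` only); defaults to
#'   the kept band `high_cut - low_cut`. Use `n - low_cut` when the residual
#'   band itself remains part of the image.
#' @return Noise power profile: a matrix matching the image
#'   (`high_order_residual`) or a per-depth vector (`vessel_free_region`).
#' @export
estimate_noise_profile <- function(x,
                                   method = c("high_order_residual",
                                              "vessel_free_region"),
                                   mask = NULL, target_dim = NULL) {
  method <- match.arg(method)
  if (method == "vessel_free_region") {
    stopifnot(inherits(x, "md_image"))
    if (is.null(mask) || !any(mask)) stop("empty mask", call. = FALSE)
    stopifnot(all(dim(mask) == dim(x$power)))
    p <- x$power
    prof <- vapply(seq_len(nrow(p)), function(i) {
      v <- p[i, mask[i, ]]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
    prof[is.na(prof)] <- stats::median(p[mask])
    prof
  } else {
    stopifnot(inherits(x, "svd_filter_result"))
    if (is.null(x$residual))
      stop("high_order_residual needs a filter result with a high_cut ",
           "residual", call. = FALSE)
    n <- length(x$singular_values)
    tail_dim <- n - x$high_cut
    if (is.null(target_dim)) target_dim <- x$high_cut - x$low_cut
    npix <- prod(dim(x$residual)[1:2])
    r <- min(npix, n)
    frac <- .mp_energy_fraction(tail_dim / r, r / max(npix, n))
    power_doppler(x$residual)$power * (target_dim / n) / frac
  }
}

# Fraction of white-noise energy carried by the bottom q-fraction of the
# singular spectrum of an m x n complex Gaussian matrix (aspect ratio
# c = min/max dims). The squared singular values follow the
# Marchenko-Pastur law on [(1-sqrt(c))^2, (1+sqrt(c))^2] (unit mean);
# integrating x * density up to the q-quantile gives the energy share of
# the weakest directions, which is well below q itself.
.mp_energy_fraction <- function(q, c) {
  if (q <= 0) return(0)
  if (q >= 1) return(1)
  a <- (1 - sqrt(c))^2
  b <- (1 + sqrt(c))^2
  x <- seq(a, b, length.out = 20001)[-c(1, 20001)]
  dens <- sqrt(pmax(0, (b - x) * (x - a))) / (2 * pi * c * x)
  dx <- x[2] - x[1]
  cdf <- cumsum(dens) * dx
  cdf <- cdf / cdf[length(cdf)]
  i_q <- which(cdf >= q)[1]
  energy <- cumsum(dens * x) * dx
  energy[i_q] / energy[length(energy)]
}

#' Subtract the noise bias from a microDoppler image
#'
#' `power' = max(power - profile, 0)`. The subtracted map and the fraction
#' of clamped (negative-going) pixels are retained as attributes
#' `subtracted` and `clamp_frac` for diagnostics.
#'
#' @param img An [md_image()].
#' @param noise_profile Matrix of the image's shape, or a per-depth vector
#'   broadcast laterally.
#' @return The bias-corrected [md_image()].
#' @export
remove_noise_bias <- function(img, noise_profile) {
  stopifnot(inherits(img, "md_image"))
  if (any(noise_profile < 0))
    stop("noise profile must be nonnegative", call. = FALSE)
  prof <- if (is.matrix(noise_profile)) {
    stopifnot(all(dim(noise_profile) == dim(img$power)))
    noise_profile
  } else {
    stopifnot(length(noise_profile) == nrow(img$power))
    matrix(noise_profile, nrow(img$power), ncol(img$power))
  }
  diffm <- img$power - prof
  out <- md_image(pmax(diffm, 0), timestamp = img$timestamp,
                  ensemble_index = img$ensemble_index)
  attr(out, "subtracted") <- prof
  attr(out, "clamp_frac") <- mean(diffm < 0)
  out
}
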