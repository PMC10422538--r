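# Plane-wave channel-data simulation and delay-and-sum reconstruction.
# This is a validation harness for the acquisition geometry the rest of the
# pipeline assumes: the main analysis path consumes generator IQ directly.

#' Simulate single-angle plane-wave channel data for point scatterers
#'
#' Each element trace is a sum of band-limited pulses (Gaussian-windowed
#' tone at the transmit frequency) centred at the two-way delay
#' `tau = (x sin(theta) + z cos(theta))/c + sqrt(z^2 + (x - x_e)^2)/c`.
#'
#' @param scatterers Data frame with columns `x`, `z` (metres; `z > 0` below
#'   the array face) and `amplitude`.
#' @param acq An [acquisition_config()].
#' @param angle Plane-wave steering angle, degrees.
#' @param fs Fast-time sampling rate, Hz (must be at least 4x the transmit
#'   frequency).
#' @param t_max Trace duration, seconds; default covers 20 mm depth.
#' @param n_cycles Pulse length in carrier cycles (FWHM of the envelope).
#' @return Real matrix `num_elements x n_samples` of class `channel_data`
#'   with attributes `fs`, `angle`, `t0 = 0`.
#' @export
simulate_channel_data <- function(scatterers, acq, angle = 0,
                                  fs = 4 * acq$center_frequency,
                                  t_max = 2 * 0.020 / acq$speed_of_sound,
                                  n_cycles = 2.5) {
  stopifnot(inherits(acq, "acquisition_config"),
            is.data.frame(scatterers),
            all(c("x", "z", "amplitude") %in% names(scatterers)))
  if (any(scatterers$z <= 0))
    stop("scatterers must lie in front of the array (z > 0)", call. = FALSE)
  if (fs < 4 * acq$center_frequency)
    stop("fast-time sampling must be >= 4x the transmit frequency",
         call. = FALSE)
  xe <- element_positions(acq)
  nt <- ceiling(t_max * fs)
  t <- (0:(nt - 1)) / fs
  th <- angle * pi / 180
  c0 <- acq$speed_of_sound
  sigma <- n_cycles / (2.355 * acq$center_frequency)  # FWHM = n_cycles periods
  traces <- matrix(0, acq$num_elements, nt)
  for (s in seq_len(nrow(scatterers))) {
    a <- scatterers$amplitude[s]
    if (a == 0) next
    x <- scatterers$x[s]; z <- scatterers$z[s]
    tau <- (x * sin(th) + z * cos(th)) / c0 + sqrt(z^2 + (x - xe)^2) / c0
    for (e in seq_len(acq$num_elements)) {
      idx <- which(abs(t - tau[e]) < 4 * sigma)
      if (!length(idx)) next
      u <- t[idx] - tau[e]
      traces[e, idx] <- traces[e, idx] +
        a * cos(2 * pi * acq$center_frequency * u) * exp(-u^2 / (2 * sigma^2))
    }
  }
  structure(traces, fs = fs, angle = angle, t0 = 0,
            class = c("channel_data", "matrix", "array"))
}

#' Rectangular beamforming grid
#'
#' Lateral origin at the array centre, depth 0 at the array face; uniform
#' spacing per axis.
#'
#' @param depth_range,lateral_range Extent in metres, `c(min, max)`.
#' @param spacing Grid spacing in metres (both axes).
#' @return Object of class `image_grid` with `depth_coords`, `lateral_coords`.
#' @export
image_grid <- function(depth_range, lateral_range, spacing) {
  stopifnot(spacing > 0, depth_range[1] > 0, depth_range[2] > depth_range[1],
            lateral_range[2] > lateral_range[1])
  structure(list(depth_coords = seq(depth_range[1], depth_range[2],
                                    by = spacing),
                 lateral_coords = seq(lateral_range[1], lateral_range[2],
                                      by = spacing),
                 spacing = spacing),
            class = "image_grid")
}

# Analytic signal of each row of a real matrix (FFT method).
.analytic <- function(x) {
  nt <- ncol(x)
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[c(1, nt / 2 + 1)] <- 1; h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nt + 1) / 2)] <- 2
  }
  t(apply(x, 1, function(r) stats::fft(stats::fft(r) * h, inverse = TRUE) / nt))
}

#' Delay-and-sum reconstruction of a single plane-wave transmit
#'
#' Converts each element trace to its analytic signal, interpolates it at
#' the two-way delay of every grid point, applies an f-number-limited Hann
#' receive apodization, and sums across elements. Grid points whose delay
#' falls outside the recorded trace contribute zero; their count is reported
#' in the `n_clipped` attribute.
#'
#' @param channels A [simulate_channel_data()] result (or any real matrix
#'   with `fs` and `t0` attributes).
#' @param angle Transmit steering angle, degrees.
#' @param grid An [image_grid()].
#' @param acq An [acquisition_config()].
#' @param f_number Receive f-number limiting the accepted aperture.
#' @return Complex matrix `depth x lateral` of class `beamformed_image`.
#' @export
das_single_angle <- function(channels, angle, grid, acq, f_number = 1) {
  stopifnot(inherits(grid, "image_grid"),
            inherits(acq, "acquisition_config"), f_number > 0)
  fs <- attr(channels, "fs")
  t0 <- attr(channels, "t0") %||% 0
  stopifnot(!is.null(fs))
  xe <- element_positions(acq)
  c0 <- acq$speed_of_sound
  th <- angle * pi / 180
  zd <- grid$depth_coords; xl <- grid$lateral_coords
  nz <- length(zd); nx <- length(xl)
  ana <- .analytic(unclass(channels))
  nt <- ncol(ana)
  img <- matrix(0 + 0i, nz, nx)
  n_clipped <- 0L
  # pixel grid as vectors (depth-major)
  Z <- rep(zd, times = nx)
  X <- rep(xl, each = nz)
  tau_tx <- (X * sin(th) + Z * cos(th)) / c0
  acc <- numeric(length(Z))           # apodization normalisation
  val <- complex(length(Z))
  half_ap <- Z / (2 * f_number)
  for (e in seq_len(acq$num_elements)) {
    u <- (X - xe[e]) / half_ap        # in [-1, 1] inside accepted aperture
    w <- ifelse(abs(u) <= 1, 0.5 + 0.5 * cos(pi * u), 0)
    sel <- which(w > 0)
    if (!length(sel)) next
    tau <- tau_tx[sel] + sqrt(Z[sel]^2 + (X[sel] - xe[e])^2) / c0
    pos <- (tau - t0) * fs + 1
    i0 <- floor(pos)
    frac <- pos - i0
    ok <- i0 >= 1 & i0 < nt
    n_clipped <- n_clipped + sum(!ok)
    if (any(ok)) {
      so <- sel[ok]
      tr <- ana[e, ]
      val[so] <- val[so] + w[so] *
        ((1 - frac[ok]) * tr[i0[ok]] + frac[ok] * tr[i0[ok] + 1])
      acc[so] <- acc[so] + w[so]
    }
  }
  img[] <- val
  structure(img, grid = grid, angle = angle, n_clipped = n_clipped,
            class = c("beamformed_image", "matrix", "array"))
}

#' Coherently compound beamformed angle images
#'
#' Complex mean across angles; all images must share the same grid.
#'
#' @param angle_images List of [das_single_angle()] results.
#' @return Complex `beamformed_image` on the common grid.
#' @export
compound <- function(angle_images) {
  stopifnot(is.list(angle_images), length(angle_images) >= 1)
  dims <- lapply(angle_images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("angle images are on mismatched grids", call. = FALSE)
  out <- Reduce(`+`, lapply(angle_images, unclass)) / length(angle_images)
  structure(out, grid = attr(angle_images[[1]], "grid"),
            angle = NA_real_,
            class = c("beamformed_image", "matrix", "array"))
}

#' Lateral -6 dB mainlobe width of a point-spread function
#'
#' Measured on the magnitude image along the lateral profile through the
#' peak, with linear interpolation of the half-amplitude crossings.
#'
#' @param img A `beamformed_image`.
#' @return Width in metres.
#' @export
mainlobe_width <- function(img) {
  grid <- attr(img, "grid")
  a <- Mod(unclass(img))
  pk <- which(a == max(a), arr.ind = TRUE)[1, ]
  prof <- a[pk[1], ]
  x <- grid$lateral_coords
  half <- prof[pk[2]] / 2
  above <- prof >= half
  # walk outwards from the peak to the first crossings
  li <- pk[2]; while (li > 1 && above[li - 1]) li <- li - 1
  ri <- pk[2]; while (ri < length(prof) && above[ri + 1]) ri <- ri + 1
  xl <- if (li == 1) x[1] else
    x[li] - (x[li] - x[li - 1]) * (prof[li] - half) / (prof[li] - prof[li - 1])
  xr <- if (ri == length(prof)) x[ri] else
    x[ri] + (x[ri + 1] - x[ri]) * (prof[ri] - half) / (prof[ri] - prof[ri + 1])
  xr - xl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
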