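# Functional activation mapping: percent CBV change of each microDoppler
# image relative to a time-averaged baseline window, plus ROI time courses.

#' Baseline window specification
#'
#' @param t_start,t_end Session-time bounds of the pre-injection baseline
#'   window, seconds (inclusive).
#' @return Object of class `baseline_spec`.
#' @export
baseline_spec <- function(t_start = 0, t_end) {
  stopifnot(t_end > t_start, t_start >= 0)
  structure(list(t_start = t_start, t_end = t_end), class = "baseline_spec")
}

#' Time-averaged baseline image
#'
#' Pixel-wise mean microDoppler power over the baseline window. At least
#' three images must fall inside the window.
#'
#' @param series An [md_series()].
#' @param spec A [baseline_spec()].
#' @return Matrix of baseline power.
#' @export
baseline_image <- function(series, spec) {
  stopifnot(inherits(series, "md_series"), inherits(spec, "baseline_spec"))
  idx <- which(series$timestamps >= spec$t_start &
                 series$timestamps <= spec$t_end)
  if (!length(idx)) stop("baseline window contains no images", call. = FALSE)
  if (length(idx) < 3)
    stop("baseline window must contain at least 3 images (has ",
         length(idx), ")", call. = FALSE)
  apply(series$power[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Functional activation map series
#'
#' Percent CBV change relative to the baseline image,
#' `100 * (P_t - B) / B`, computed only where the baseline exceeds a power
#' floor; elsewhere the pixel is flagged invalid (`NA`) rather than allowed
#' to blow up. The raw difference maps are retained as well.
#'
#' The floor defaults to the `floor_quantile` (1st percentile) of the
#' baseline power over the vessel region, so that near-zero
#' background pixels — whose percent change would be pure noise — never
#' enter ROI statistics. When no `vessel_mask` is supplied the vessel
#' region is segmented from the baseline image itself as the pixels above
#' 5 percent of its 99.5th power percentile (after noise-bias removal the
#' background sits near zero, far below any perfused pixel).
#'
#' @param series An [md_series()].
#' @param baseline Baseline image from [baseline_image()].
#' @param vessel_mask Optional logical matrix of vessel-bearing pixels used
#'   to set the default floor.
#' @param floor Power floor; pixels with `baseline <= floor` are invalid.
#'   Must be positive.
#' @param floor_quantile Vessel-region baseline quantile used when `floor`
#'   is `NULL`.
#' @return Object of class `activation_series`: `percent` and `diff` 3-D
#'   arrays, logical `valid` map, `baseline_image`, `timestamps`.
#' @export
activation_map <- function(series, baseline, vessel_mask = NULL,
                           floor = NULL, floor_quantile = 0.01) {
  stopifnot(inherits(series, "md_series"),
            all(dim(baseline) == dim(series$power)[1:2]))
  if (is.null(floor)) {
    if (is.null(vessel_mask)) {
      top <- stats::quantile(baseline, 0.995, names = FALSE)
      vessel_mask <- baseline > 0.05 * top
    }
    stopifnot(all(dim(vessel_mask) == dim(baseline)))
    pos <- baseline[vessel_mask]
    pos <- pos[pos > 0]
    if (!length(pos)) stop("vessel region has no positive baseline pixels",
                           call. = FALSE)
    floor <- stats::quantile(pos, floor_quantile, names = FALSE)
  }
  if (floor <= 0) stop("baseline floor must be positive", call. = FALSE)
  valid <- baseline > floor
  nt <- dim(series$power)[3]
  percent <- diffm <- array(NA_real_, dim(series$power))
  for (k in seq_len(nt)) {
    dk <- series$power[, , k] - baseline
    diffm[, , k] <- dk
    pk <- matrix(NA_real_, nrow(baseline), ncol(baseline))
    pk[valid] <- 100 * dk[valid] / baseline[valid]
    percent[, , k] <- pk
  }
  structure(list(percent = percent, diff = diffm, valid = valid,
                 baseline_image = baseline, timestamps = series$timestamps),
            class = "activation_series")
}

#' @export
print.activation_series <- function(x, ...) {
  d <- dim(x$percent)
  cat(sprintf("<activation_series> %d x %d px, %d frames, %d valid px\n",
              d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}

#' ROI-mean percent-change time course
#'
#' Per-timestamp mean of the valid pixels inside the mask; the number of
#' contributing pixels is recorded per frame. Invalid pixels never
#' contribute, so the trace is unchanged by whatever values they carry.
#'
#' @param act An [activation_map()] result.
#' @param mask Logical ROI matrix.
#' @return Data frame with columns `time`, `percent`, `n_valid`.
#' @export
roi_trace <- function(act, mask) {
  stopifnot(inherits(act, "activation_series"),
            all(dim(mask) == dim(act$valid)))
  sel <- mask & act$valid
  if (!any(sel)) stop("mask contains no valid pixels", call. = FALSE)
  nt <- dim(act$percent)[3]
  val <- vapply(seq_len(nt), function(k) mean(act$percent[, , k][sel]),
                numeric(1))
  data.frame(time = act$timestamps, percent = val, n_valid = sum(sel))
}

#' Moving-average smoothing with shrinking edge windows
#'
#' Centred moving average over `kernel_len` samples; at the trace ends the
#' window shrinks to the available samples rather than reflecting or
#' padding, so no phantom values appear where injections are read off.
#' For even kernels the extra sample sits on the trailing side.
#'
#' @param trace Numeric vector, or a [roi_trace()] data frame (its
#'   `percent` column is smoothed and returned alongside).
#' @param kernel_len Window length in samples (>= 1).
#' @return Same type as the input (data frames gain a `smoothed` column).
#' @export
smooth_trace <- function(trace, kernel_len = 10) {
  if (is.data.frame(trace)) {
    trace$smoothed <- smooth_trace(trace$percent, kernel_len)
    return(trace)
  }
  n <- length(trace)
  stopifnot(kernel_len >= 1)
  if (kernel_len > n)
    stop("kernel_len (", kernel_len, ") exceeds series length (", n, ")",
         call. = FALSE)
  hl <- floor((kernel_len - 1) / 2)
  hr <- kernel_len - 1 - hl
  vapply(seq_len(n), function(i) {
    mean(trace[max(1, i - hl):min(n, i + hr)])
  }, numeric(1))
}
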