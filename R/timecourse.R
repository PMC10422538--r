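#' Hemodynamic drug-response time-course parameters
#'
#' Parameterises the piecewise cerebral-blood-volume (CBV) multiplier applied
#' to responding vessel pixels: unity during baseline, an exponential rise
#' toward `1 + peak_fractional_increase` after the tremorgen injection at
#' `t_baseline_end`, a slow exponential return toward baseline, and an
#' optional suppression dip (beta-blocker arm) that sets in at `t_suppressor`
#' and recovers with `rebound_tau`.
#'
#' The evoked elevation is
#' \deqn{m(t) = 1 + A \, c \,(1 - e^{-\Delta/\tau_r})\, e^{-\Delta/\tau_d},}
#' with \eqn{\Delta = t - t_0} and \eqn{c} chosen so the maximum equals
#' \eqn{1 + A}. The suppression dip multiplies the elevation \eqn{m(t)-1}
#' (not the multiplier itself) by \eqn{1 - d\,g(t - t_s)}, where \eqn{g}
#' rises from 0 over `suppression_onset_tau` and decays with `rebound_tau`
#' (normalised to peak 1), so `suppression_depth = 1` means full suppression
#' back to baseline and the multiplier stays continuous everywhere.
#'
#' @param t_baseline_end End of the drug-free baseline epoch, seconds
#'   (default 1800 s, i.e. 30 min).
#' @param peak_fractional_increase Peak evoked fractional CBV increase A
#'   (default 1.6, i.e. +160 percent).
#' @param rise_tau,decay_tau Rise and decay time constants, seconds.
#' @param suppression_enabled Logical; add the suppressor dip.
#' @param t_suppressor Suppressor injection time, seconds
#'   (default `t_baseline_end + 1200`, i.e. 20 min after the first drug).
#' @param suppression_depth Fraction of the evoked elevation removed at the
#'   bottom of the dip, in `[0, 1]`.
#' @param rebound_tau Recovery time constant of the dip, seconds.
#' @param suppression_onset_tau Short onset time constant of the dip, seconds.
#' @return An object of class `timecourse_params`.
#' @seealso [cbv_multiplier()]
#' @export
timecourse_params <- function(t_baseline_end = 1800,
                              peak_fractional_increase = 1.6,
                              rise_tau = 180,
                              decay_tau = 7200,
                              suppression_enabled = FALSE,
                              t_suppressor = t_baseline_end + 1200,
                              suppression_depth = 0.8,
                              rebound_tau = 600,
                              suppression_onset_tau = 60) {
  stopifnot(is.numeric(t_baseline_end), length(t_baseline_end) == 1L,
            t_baseline_end >= 0,
            is.numeric(peak_fractional_increase),
            peak_fractional_increase >= 0)
  if (rise_tau <= 0 || decay_tau <= 0)
    stop("rise_tau and decay_tau must be positive", call. = FALSE)
  if (suppression_enabled) {
    if (rebound_tau <= 0 || suppression_onset_tau <= 0)
      stop("rebound_tau and suppression_onset_tau must be positive",
           call. = FALSE)
    if (suppression_depth < 0 || suppression_depth > 1)
      stop("suppression_depth must lie in [0, 1]", call. = FALSE)
    if (t_suppressor < t_baseline_end)
      stop("t_suppressor must not precede t_baseline_end", call. = FALSE)
  }
  structure(
    list(t_baseline_end = t_baseline_end,
         peak_fractional_increase = peak_fractional_increase,
         rise_tau = rise_tau,
         decay_tau = decay_tau,
         suppression_enabled = isTRUE(suppression_enabled),
         t_suppressor = t_suppressor,
         suppression_depth = suppression_depth,
         rebound_tau = rebound_tau,
         suppression_onset_tau = suppression_onset_tau),
    class = "timecourse_params")
}

# Normalised rise-decay pulse (1-exp(-u/a))*exp(-u/b), scaled to peak 1.
# Peaks at u* = a*log(1 + b/a).
.rise_decay_pulse <- function(u, a, b) {
  peak_u <- a * log1p(b / a)
  peak <- (1 - exp(-peak_u / a)) * exp(-peak_u / b)
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- (1 - exp(-u[pos] / a)) * exp(-u[pos] / b) / peak
  out
}

#' Evaluate the CBV multiplier at given times
#'
#' Vectorised over `t`. Exactly 1 for `t < t_baseline_end`, continuous
#' everywhere, nonnegative, and tends back to 1 long after the response.
#'
#' @param t Time(s) since session start, seconds (nonnegative).
#' @param params A [timecourse_params()] object.
#' @return Numeric vector of multipliers, same length as `t`.
#' @examples
#' p <- timecourse_params()
#' cbv_multiplier(0, p)                      # baseline: exactly 1
#' max(cbv_multiplier(seq(0, 2e4, by = 1), p))  # ~ 1 + peak_fractional_increase
#' @export
cbv_multiplier <- function(t, params) {
  stopifnot(inherits(params, "timecourse_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  elev <- params$peak_fractional_increase *
    .rise_decay_pulse(t - params$t_baseline_end,
                      params$rise_tau, params$decay_tau)
  if (params$suppression_enabled) {
    dip <- params$suppression_depth *
      .rise_decay_pulse(t - params$t_suppressor,
                        params$suppression_onset_tau, params$rebound_tau)
    elev <- elev * (1 - dip)
  }
  1 + elev
}
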