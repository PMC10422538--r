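# Time-point contrasts on ROI activation traces: Wilcoxon-Mann-Whitney
# rank-sum comparison of the +/-5-frame sample windows at two session times.
# The test itself is implemented here (exact small-sample path and
# normal approximation with midranks, tie-corrected variance, and
# continuity correction) rather than delegated, so its behaviour under the
# pipeline's exact conditions is fully specified and testable.

#' Extract the sample window around a time point
#'
#' Returns the `2 * half_window + 1` trace values centred on the frame
#' nearest `t` (ties between two equally near frames resolve to the earlier
#' frame). A window clipped by the session boundary is an error, never
#' silently shortened.
#'
#' @param trace A [roi_trace()] data frame (columns `time`, `percent`), or a
#'   numeric vector with a `times` attribute.
#' @param t Centre time, seconds.
#' @param half_window Half-width in frames (default 5).
#' @return Numeric vector of `2 * half_window + 1` samples.
#' @export
window_samples <- function(trace, t, half_window = 5) {
  if (is.data.frame(trace)) {
    times <- trace$time; values <- trace$percent
  } else {
    times <- attr(trace, "times"); values <- as.numeric(trace)
    if (is.null(times)) stop("numeric trace needs a 'times' attribute",
                             call. = FALSE)
  }
  stopifnot(half_window >= 0)
  d <- abs(times - t)
  i <- which(d == min(d))[1]   # tie resolves to the earlier frame
  lo <- i - half_window; hi <- i + half_window
  if (lo < 1 || hi > length(values))
    stop(sprintf("window [%d, %d] around t = %g falls outside the session (1..%d)",
                 lo, hi, t, length(values)), call. = FALSE)
  values[lo:hi]
}

# Exact null distribution of the Mann-Whitney U statistic for tie-free
# ranks: N(m, n, u) = N(m-1, n, u-n) + N(m, n-1, u) with N(m, 0, 0) =
# N(0, n, 0) = 1; counts[u + 1] = number of the C(n1+n2, n1) rank
# configurations with U = u.
.mw_counts <- function(n1, n2) {
  tab <- vector("list", n2 + 1)
  for (n in 0:n2) tab[[n + 1]] <- 1            # m = 0 row
  for (m in seq_len(n1)) {
    new <- vector("list", n2 + 1)
    new[[1]] <- 1                              # n = 0
    for (n in seq_len(n2)) {
      a <- c(numeric(n), tab[[n + 1]])         # from N(m-1, n, u-n)
      b <- new[[n]]                            # from N(m, n-1, u)
      L <- max(length(a), length(b))
      new[[n + 1]] <- c(a, numeric(L - length(a))) +
        c(b, numeric(L - length(b)))
    }
    tab <- new
  }
  counts <- tab[[n2 + 1]]
  c(counts, numeric(n1 * n2 + 1 - length(counts)))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic with midranks for ties. For
#' `n1 + n2 <= 12` with no ties the two-sided p-value is exact (enumeration
#' of the null U distribution); otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used. If every value
#' in both samples is identical the result is degenerate with `p = 1`.
#'
#' @param x,y Numeric sample vectors (`n1, n2 >= 1`).
#' @return Object of class `rank_sum_result`: `u_statistic` (U of `x`),
#'   `p_value` (two-sided), `n1`, `n2`, `method` (`"exact"` or
#'   `"normal_approx"`), `degenerate`.
#' @export
rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1, is.numeric(x), is.numeric(y))
  comb <- c(x, y)
  # uninformative data: constant values, or identical sample multisets
  if (length(unique(comb)) == 1L ||
      (n1 == n2 && isTRUE(all(sort(x) == sort(y)))))
    return(structure(list(u_statistic = n1 * n2 / 2, p_value = 1,
                          n1 = n1, n2 = n2, method = "degenerate",
                          degenerate = TRUE), class = "rank_sum_result"))
  r <- rank(comb)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(comb))
  n <- n1 + n2
  if (!ties && n <= 12) {
    counts <- .mw_counts(n1, n2)
    total <- sum(counts)
    umin <- min(u, n1 * n2 - u)
    p <- 2 * sum(counts[seq_len(umin + 1)]) / total  # null dist is symmetric
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tt <- table(comb)
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0)
      return(structure(list(u_statistic = u, p_value = 1, n1 = n1, n2 = n2,
                            method = "degenerate", degenerate = TRUE),
                       class = "rank_sum_result"))
    z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, p_value = p, n1 = n1, n2 = n2,
                 method = method, degenerate = FALSE),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum> U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Time-point contrast specification
#'
#' @param t1,t2 Session times to compare, seconds.
#' @param half_window Half-width of each sample window, frames (default 5).
#' @param roi_label Name of the ROI the contrast applies to.
#' @return Object of class `timepoint_contrast`.
#' @export
timepoint_contrast <- function(t1, t2, half_window = 5,
                               roi_label = "active") {
  stopifnot(is.numeric(t1), is.numeric(t2), half_window >= 0)
  if (t1 == t2) stop("contrast time points must differ", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, half_window = as.integer(half_window),
                 roi_label = roi_label),
            class = "timepoint_contrast")
}

#' Run a time-point contrast on an ROI trace
#'
#' Draws the two `+/- half_window`-frame sample windows from the raw
#' (unsmoothed) ROI-mean percent-change trace, requires them to be
#' non-overlapping, and applies [rank_sum()].
#'
#' @param trace A [roi_trace()] data frame.
#' @param contrast A [timepoint_contrast()].
#' @return Object of class `contrast_result`: the `rank_sum_result` plus a
#'   one-row `summary` data frame (ROI, times, medians, direction, U, p,
#'   method).
#' @export
run_contrast <- function(trace, contrast) {
  stopifnot(is.data.frame(trace), inherits(contrast, "timepoint_contrast"))
  nearest <- function(t) which.min(abs(trace$time - t))
  i1 <- nearest(contrast$t1); i2 <- nearest(contrast$t2)
  h <- contrast$half_window
  if (abs(i1 - i2) <= 2 * h)
    stop("contrast windows overlap (centres ", i1, " and ", i2,
         " with half-window ", h, ")", call. = FALSE)
  s1 <- window_samples(trace, contrast$t1, h)
  s2 <- window_samples(trace, contrast$t2, h)
  rs <- rank_sum(s1, s2)
  structure(list(rank_sum = rs,
                 samples = list(t1 = s1, t2 = s2),
                 summary = data.frame(
                   roi = contrast$roi_label,
                   t1 = contrast$t1, t2 = contrast$t2,
                   median_t1 = stats::median(s1),
                   median_t2 = stats::median(s2),
                   direction = ifelse(stats::median(s1) > stats::median(s2),
                                      "t1 > t2", "t1 <= t2"),
                   u_statistic = rs$u_statistic,
                   p_value = rs$p_value,
                   n1 = rs$n1, n2 = rs$n2,
                   method = rs$method)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
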