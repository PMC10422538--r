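# SVD spatiotemporal clutter filtering: the Doppler ensemble is reshaped to
# a space x time Casorati matrix, decomposed, and the low singular orders
# (high-energy, spatiotemporally coherent tissue motion) are rejected.

#' Reshape an IQ ensemble to its Casorati matrix
#'
#' Column `k` is the vectorised `k`-th frame (column-major over
#' depth x lateral); the reshape is lossless and invertible with
#' [from_casorati()].
#'
#' @param ens An [iq_ensemble()] (complex 3-D array).
#' @return Complex matrix of class `casorati_matrix`
#'   (`depth*lateral` rows x `ensemble_len` columns) carrying the spatial
#'   dimensions and acquisition metadata as attributes.
#' @export
to_casorati <- function(ens) {
  if (!(is.array(ens) && length(dim(ens)) == 3L))
    stop("input must be a 3-D ensemble (depth x lateral x slow-time)",
         call. = FALSE)
  d <- dim(ens)
  m <- unclass(ens)
  dim(m) <- c(d[1] * d[2], d[3])
  structure(m, dim_spatial = d[1:2],
            frame_rate = attr(ens, "frame_rate"),
            timestamp = attr(ens, "timestamp"),
            class = c("casorati_matrix", "matrix", "array"))
}

#' Inverse of [to_casorati()]
#' @param cm A `casorati_matrix`.
#' @return The original [iq_ensemble()].
#' @export
from_casorati <- function(cm) {
  stopifnot(inherits(cm, "casorati_matrix"))
  sp <- attr(cm, "dim_spatial")
  iq_ensemble(array(unclass(cm), dim = c(sp, ncol(cm))),
              frame_rate = attr(cm, "frame_rate") %||% NA_real_,
              timestamp = attr(cm, "timestamp") %||% 0)
}

#' Filter an ensemble by global singular-order thresholding
#'
#' Computes the (economy, complex) SVD of the Casorati matrix and
#' reconstructs the ensemble from singular components with order in
#' `(low_cut, high_cut]`. The rejected low orders (tissue clutter) and the
#' residual above `high_cut` are returned alongside for diagnostics; by
#' default no high-order cut is applied (`high_cut = NULL`), leaving noise
#' handling to the noise-bias stage.
#'
#' With `low_cut = 0` and no `high_cut` the input is returned exactly.
#' When `low_cut` reaches the numerical rank the output is all-zero and a
#' warning is raised.
#'
#' When `low_cut = NULL` the rejection order is chosen from the computed
#' singular spectrum by [select_threshold()] (plus `low_cut_margin`), so the
#' decomposition is only performed once.
#'
#' @param x An [iq_ensemble()] or `casorati_matrix`.
#' @param low_cut Number of leading singular orders to reject (>= 0), or
#'   `NULL` to select automatically.
#' @param high_cut Highest singular order to keep, or `NULL` for all.
#' @param select_method,fixed_k Passed to [select_threshold()] when
#'   `low_cut = NULL`.
#' @param low_cut_margin Safety margin added to the selected order.
#' @return Object of class `svd_filter_result`: `filtered`, `clutter`,
#'   `residual` (ensembles; `residual` is `NULL` without a high cut),
#'   `singular_values`, `low_cut`, `high_cut`.
#' @export
svd_filter <- function(x, low_cut, high_cut = NULL,
                       select_method = "energy_knee", fixed_k = NULL,
                       low_cut_margin = 0) {
  cm <- if (inherits(x, "casorati_matrix")) x else to_casorati(x)
  n <- ncol(cm)
  rmax <- min(dim(cm))
  auto <- is.null(low_cut)
  if (!auto && low_cut < 0) stop("low_cut must be >= 0", call. = FALSE)
  if (!is.null(high_cut) && high_cut >= rmax) high_cut <- NULL
  X <- unclass(cm)
  attributes(X) <- list(dim = dim(cm))

  reshape <- function(M) {
    out <- cm
    out[] <- M
    from_casorati(out)
  }

  if (!auto && low_cut == 0 && is.null(high_cut)) {
    # identity path: exact, but still expose the singular spectrum
    sv <- La.svd(X, nu = 0, nv = 0)$d
    return(structure(list(filtered = reshape(X),
                          clutter = reshape(matrix(0 + 0i, nrow(X), n)),
                          residual = NULL,
                          singular_values = sv,
                          low_cut = 0L, high_cut = NULL),
                     class = "svd_filter_result"))
  }

  s <- La.svd(X, nu = 0, nv = rmax)   # rows of s$vt are conjugated right
                                      # singular vectors
  sv <- s$d
  if (auto) {
    if (is.null(fixed_k)) fixed_k <- ceiling(0.15 * n)
    low_cut <- select_threshold(sv, method = select_method,
                                fixed_k = fixed_k) + low_cut_margin
  }
  if (!is.null(high_cut) && high_cut <= low_cut)
    stop("high_cut must exceed low_cut", call. = FALSE)
  num_rank <- sum(sv > max(sv[1], .Machine$double.eps) *
                    max(dim(X)) * .Machine$double.eps)
  proj <- function(idx) {
    if (!length(idx)) return(matrix(0 + 0i, nrow(X), n))
    Vh <- s$vt[idx, , drop = FALSE]
    (X %*% Conj(t(Vh))) %*% Vh
  }
  if (low_cut >= num_rank)
    warning("low_cut (", low_cut, ") >= numerical rank (", num_rank,
            "): filtered output is all zero", call. = FALSE)
  low <- proj(seq_len(min(low_cut, rmax)))
  resid <- if (!is.null(high_cut)) proj(seq(high_cut + 1, rmax)) else NULL
  kept <- X - low - (if (is.null(resid)) 0 else resid)
  structure(list(filtered = reshape(kept),
                 clutter = reshape(low),
                 residual = if (is.null(resid)) NULL else reshape(resid),
                 singular_values = sv,
                 low_cut = as.integer(low_cut),
                 high_cut = if (is.null(high_cut)) NULL
                            else as.integer(high_cut)),
            class = "svd_filter_result")
}

#' @export
print.svd_filter_result <- function(x, ...) {
  cat(sprintf("<svd_filter_result> low_cut %d, high_cut %s, sigma1 = %.4g\n",
              x$low_cut,
              if (is.null(x$high_cut)) "none" else x$high_cut,
              x$singular_values[1]))
  invisible(x)
}

#' Select the clutter rejection order from a singular spectrum
#'
#' `method = "energy_knee"` returns the order at which the decay of the
#' log-spectrum flattens: the index maximising the discrete curvature
#' (second difference) of `log(sigma)`, minus one. For a spectrum with a
#' sharp clutter/blood break this is the number of clutter orders. When the
#' spectrum is degenerate (numerically flat) the method falls back to the
#' configured fixed order with a warning. `method = "fixed"` returns
#' `fixed_k` unconditionally.
#'
#' @param singular_values Nonnegative, descending singular values.
#' @param method `"energy_knee"` (default) or `"fixed"`.
#' @param fixed_k Fixed rejection order; default `ceiling(0.15 * length)`.
#' @return Integer `low_cut`.
#' @export
select_threshold <- function(singular_values,
                             method = c("energy_knee", "fixed"),
                             fixed_k = ceiling(0.15 * length(singular_values))) {
  method <- match.arg(method)
  sv <- singular_values
  if (!length(sv)) stop("empty singular spectrum", call. = FALSE)
  if (is.unsorted(rev(sv))) stop("singular values must be descending",
                                 call. = FALSE)
  if (method == "fixed") return(as.integer(fixed_k))
  keep <- sv > max(sv[1] * 1e-14, 0)
  l <- log(sv[keep])
  if (length(l) < 3 || diff(range(l)) < 1e-8) {
    warning("degenerate singular spectrum: falling back to fixed order ",
            fixed_k, call. = FALSE)
    return(as.integer(fixed_k))
  }
  curv <- l[3:length(l)] - 2 * l[2:(length(l) - 1)] + l[1:(length(l) - 2)]
  i <- which.max(curv) + 1L   # index (into l) of maximum curvature
  if (max(curv) < 1e-8) {
    warning("no knee in singular spectrum: falling back to fixed order ",
            fixed_k, call. = FALSE)
    return(as.integer(fixed_k))
  }
  as.integer(i - 1L)
}
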