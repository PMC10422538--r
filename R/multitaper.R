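# Discrete prolate spheroidal (Slepian) sequences via the symmetric
# tridiagonal formulation. The tridiagonal operator
#   T[t,t]   = ((N-1-2t)/2)^2 cos(2 pi W),  t = 0..N-1
#   T[t,t+1] = (t+1)(N-1-t)/2
# commutes with the band-concentration kernel, so its top eigenvectors are
# the DPSS in decreasing order of spectral concentration. The top
# eigenvalues of T are well separated, which makes bisection (Sturm counts)
# plus tridiagonal inverse iteration fast and robust at N in the tens of
# thousands, where a dense eigendecomposition is not an option.

# Number of eigenvalues of the symmetric tridiagonal (d, e) strictly below x.
.sturm_count <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1] - x
  if (q < 0) cnt <- 1L
  tiny <- .Machine$double.xmin
  for (i in 2:n) {
    if (abs(q) < tiny) q <- tiny
    q <- d[i] - x - e[i - 1]^2 / q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

# j-th largest eigenvalue of (d, e) by bisection.
.tridiag_eigval <- function(d, e, j) {
  n <- length(d)
  r <- c(0, abs(e))
  lo <- min(d - r[seq_len(n)] - c(abs(e), 0))
  hi <- max(d + r[seq_len(n)] + c(abs(e), 0))
  target <- n - j + 1L   # want count(< lambda_j + eps) >= target
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (.sturm_count(d, e, mid) >= target) hi <- mid else lo <- mid
    if (hi - lo <= 4 * .Machine$double.eps * max(abs(lo), abs(hi), 1)) break
  }
  (lo + hi) / 2
}

# Eigenvector of (d, e) for eigenvalue lam by inverse iteration.
.tridiag_eigvec <- function(d, e, lam, prev = NULL) {
  n <- length(d)
  shift <- lam * (1 + 1e-13) + 1e-300
  A <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(e, d - shift, e))
  v <- rep(1 / sqrt(n), n)
  for (it in 1:4) {
    v <- as.numeric(Matrix::solve(A, v))
    if (!is.null(prev))
      for (p in seq_len(ncol(prev))) v <- v - sum(v * prev[, p]) * prev[, p]
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv == 0) { v <- stats::rnorm(n); next }
    v <- v / nv
  }
  v
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` unit-energy DPSS of length `n` with
#' time-bandwidth product `nw`, ordered by decreasing spectral
#' concentration in the band `|f| <= nw/n` (cycles/sample). The
#' concentration of each taper is returned in the `"concentration"`
#' attribute.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (e.g. 3).
#' @param k Number of tapers (at most `2 nw - 1` for well-concentrated
#'   tapers).
#' @return `n x k` matrix, one taper per column, each with unit energy.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 8, nw > 0, k >= 1, k <= n)
  W <- nw / n
  if (W >= 0.5) stop("nw/n must be below 0.5", call. = FALSE)
  t0 <- 0:(n - 1)
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  e <- (t0[-1]) * (n - t0[-1]) / 2
  V <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lam <- .tridiag_eigval(d, e, j)
    V[, j] <- .tridiag_eigvec(d, e, lam,
                              prev = if (j > 1) V[, seq_len(j - 1),
                                                 drop = FALSE])
  }
  # sign convention: symmetric tapers positive mean, antisymmetric tapers
  # positive initial lobe
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8 * sqrt(n)) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[which.max(abs(V[1:ceiling(n / 2), j])), j] < 0) {
      V[, j] <- -V[, j]
    }
  }
  # band concentration via zero-padded FFT
  nfft <- 2^ceiling(log2(8 * n))
  conc <- vapply(seq_len(k), function(j) {
    sp <- Mod(stats::fft(c(V[, j], rep(0, nfft - n))))^2
    f <- (0:(nfft - 1)) / nfft
    inband <- f <= W | f >= 1 - W
    sum(sp[inband]) / sum(sp)
  }, numeric(1))
  structure(V, concentration = conc)
}
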