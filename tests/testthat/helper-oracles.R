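# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately take different computational
# routes than the implementation they check.

tiny_acq <- function(ensemble_len = 48, frame_rate = 1000) {
  acquisition_config(ensemble_len = ensemble_len,
                     frame_rate_in_ensemble = frame_rate,
                     prf = 5 * frame_rate)
}

tiny_scene <- function(seed = 1, ...) {
  hemodynamic_scene(grid_shape = c(16, 16), seed = seed, ...)
}

# Brute-force two-sided permutation p-value for the rank-sum test:
# enumerates every assignment of group labels with utils::combn and counts
# configurations at least as extreme (in |U - E[U]|) as observed.
# Independent of the implementation's count-distribution recurrence.
ranksum_brute <- function(x, y) {
  comb <- c(x, y)
  n1 <- length(x); n <- length(comb)
  r <- rank(comb)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  us <- apply(utils::combn(n, n1), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# SVD-filter oracle: reconstruct the kept band from an eigendecomposition
# of the Gram matrix X^H X (a different route than the LAPACK SVD used by
# svd_filter).
gram_filter <- function(X, low_cut, high_cut = NULL) {
  n <- ncol(X)
  e <- eigen(Conj(t(X)) %*% X, symmetric = TRUE)
  hi <- if (is.null(high_cut)) min(dim(X)) else high_cut
  idx <- seq_len(hi)
  idx <- idx[idx > low_cut]
  V <- e$vectors[, idx, drop = FALSE]
  X %*% V %*% Conj(t(V))
}

# Projection of an arbitrary matrix onto the kept band of X's right singular
# subspace, again via the Gram eigendecomposition (used to measure how much
# clutter survives the filter applied to the total data).
gram_project <- function(X, M, low_cut, high_cut = NULL) {
  n <- ncol(X)
  e <- eigen(Conj(t(X)) %*% X, symmetric = TRUE)
  hi <- if (is.null(high_cut)) min(dim(X)) else high_cut
  idx <- seq_len(hi)
  idx <- idx[idx > low_cut]
  V <- e$vectors[, idx, drop = FALSE]
  M %*% V %*% Conj(t(V))
}

frob2 <- function(M) sum(Mod(M)^2)

# Reduced-scale harmaline scenario shared by several slow tests: same
# physics and epochs as the default scenario, smaller grid and shorter
# ensembles. Memoised per test process.
reduced_cfg <- function(seed = 11, ...) {
  utils::modifyList(
    list(seed = seed,
         acquisition = list(ensemble_len = 200L),
         scene = list(grid_shape = c(32L, 32L)),
         session = list(n_ensembles = 60L)),
    list(...))
}

.shared_cache <- new.env(parent = emptyenv())

shared_reduced_run <- function() {
  if (is.null(.shared_cache$run)) {
    out <- file.path(tempdir(), "md-shared-run")
    .shared_cache$run <- run_pipeline(reduced_cfg(), out)
  }
  .shared_cache$run
}
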