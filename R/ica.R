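# Symmetric FastICA with tanh contrast on a PCA-whitened signal matrix.
# X: n_samples x n_signals, columns mean-removed. Returns the estimated
# source time courses (n_samples x n_comp). Deterministic given `seed`.
fast_ica <- function(X, n_comp, seed = 1L, max_iter = 200L, tol = 1e-6) {
  n <- nrow(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > 1e-10)
  n_comp <- min(n_comp, length(keep))
  if (n_comp < 1L) return(NULL)
  # whitened data: unit-variance principal scores
  Z <- sweep(pc$x[, keep[seq_len(n_comp)], drop = FALSE], 2L,
             pc$sdev[keep[seq_len(n_comp)]], "/")
  W <- with_seed(seed, matrix(rnorm(n_comp * n_comp), n_comp, n_comp))
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)            # n x k source estimates
    G <- tanh(WX)
    Gp <- 1 - G^2
    W_new <- crossprod(G, Z) / n - diag(colMeans(Gp), n_comp) %*% W
    W_new <- sym_orth(W_new)
    if (max(abs(abs(diag(W_new %*% t(W))) - 1)) < tol) {
      W <- W_new
      break
    }
    W <- W_new
  }
  Z %*% t(W)
}
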