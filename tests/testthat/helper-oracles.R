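# Independent oracles used to cross-check the kernel implementation.
# Kept deliberately separate from the package code paths: the oracle works in
# the primal (gene) space with classical NIPALS PLS2, never through the Gram
# matrix.

# Classical NIPALS PLS2 on (X, Y): score vectors normalized to unit length,
# X and Y deflated by the extracted score. With a linear kernel on centered
# data the kernel algorithm must reproduce these scores up to sign.
nipals_pls2_oracle <- function(X, labels, n_components,
                               tol = 1e-12, max_iter = 1000L) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Y <- encode_labels(labels)
  Y <- matrix(as.numeric(Y), nrow(Y), ncol(Y))
  Tmat <- NULL
  Wmat <- NULL
  for (h in seq_len(n_components)) {
    if (sqrt(sum(Y^2)) < 1e-12) break
    u <- Y[, which(colSums(Y^2) > 0)[1L]]
    u <- u / sqrt(sum(u^2))
    t_old <- rep(0, nrow(Xc))
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      t_vec <- drop(Xc %*% w)
      t_vec <- t_vec / sqrt(sum(t_vec^2))
      cvec <- drop(crossprod(Y, t_vec))
      u <- drop(Y %*% cvec)
      u <- u / sqrt(sum(u^2))
      if (sqrt(sum((t_vec - t_old)^2)) < tol) break
      t_old <- t_vec
    }
    cvec <- drop(crossprod(Y, t_vec))
    i <- which.max(abs(cvec))
    if (cvec[i] < 0) t_vec <- -t_vec
    Tmat <- cbind(Tmat, t_vec)
    w <- drop(crossprod(Xc, t_vec))
    Wmat <- cbind(Wmat, w / sqrt(sum(w^2)))
    Xc <- Xc - t_vec %*% crossprod(t_vec, Xc)
    Y <- Y - t_vec %*% crossprod(t_vec, Y)
  }
  list(scores = Tmat, weights = Wmat)
}

# Small random classification instance with balanced-ish classes.
rand_instance <- function(n, p, n_classes, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("g", seq_len(p))))
  labels <- rep(paste0("c", seq_len(n_classes)), length.out = n)
  # a touch of signal so instances are not pure noise
  X[, 1L] <- X[, 1L] + as.numeric(factor(labels))
  list(X = X, labels = labels)
}

max_abs_diff_up_to_sign <- function(a, b) {
  min(max(abs(a - b)), max(abs(a + b)))
}
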