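#' Encode class labels as a centered indicator matrix
#'
#' Builds the n-by-c one-hot class membership matrix and centers each column
#' to mean zero, so that classification can be treated as multivariate
#' regression of the indicator on the (feature-space) expression profiles.
#' Class order is first-appearance order in `labels`.
#'
#' @param labels Length-n vector (character or factor) of class labels with
#'   at least 2 classes and at least 2 samples per class.
#' @return An `indicator` object: the centered n-by-c matrix with attributes
#'   `classes` (ordered class labels) and `counts` (per-class sizes).
#' @export
#' @examples
#' encode_labels(c("A", "A", "B", "B"))
encode_labels <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("need at least 2 distinct classes", call. = FALSE)
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stop("every class needs at least 2 samples (class '",
         names(counts)[which.min(counts)],
         "' has fewer); within-class scatter is undefined otherwise",
         call. = FALSE)
  n <- length(labels)
  Y <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  Y[cbind(seq_len(n), match(labels, classes))] <- 1
  Y <- scale(Y, center = TRUE, scale = FALSE)
  attr(Y, "scaled:center") <- NULL
  structure(Y, classes = classes, counts = as.integer(counts),
            class = c("indicator", class(matrix())))
}

normalize_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-300) return(NULL)
  v / nv
}

#' Extract one kernel-PLS component by kernel NIPALS
#'
#' Alternates `t <- normalize(K u)`, `c <- Y't`, `u <- normalize(Y c)` until
#' the score vector `t` stabilises. The fixed point of this map is the
#' dominant eigenvector of `K Y Y'` (up to normalization), so for a rank-one
#' response (two classes) the loop closes in a single pass with
#' `t = normalize(K y)`. The sign of `t` is fixed so that the entry of `Y't`
#' largest in magnitude is positive.
#'
#' @param K Symmetric (residual) Gram matrix.
#' @param Y (Residual) centered response matrix with nonzero norm.
#' @param inner_tol Convergence tolerance on the change in `t`.
#' @param inner_max_iter Iteration cap; non-convergence returns the current
#'   iterate with a warning.
#' @return List with unit score vector `t`, dual direction `u` (coefficients
#'   over samples), number of iterations `iters`, and `converged` flag.
#'   `NULL` when `K` carries no remaining signal along `Y`.
#' @export
extract_component <- function(K, Y, inner_tol = 1e-10, inner_max_iter = 500L) {
  K <- unclass(K); Y <- unclass(Y)
  if (sqrt(sum(Y^2)) < 1e-12)
    stop("response matrix is numerically zero (signal exhausted)", call. = FALSE)
  nz <- which(colSums(Y^2) > 0)[1L]
  u <- normalize_vec(Y[, nz])
  t_old <- rep(0, nrow(K))
  iters <- 0L
  converged <- FALSE
  t_vec <- NULL
  while (iters < inner_max_iter) {
    iters <- iters + 1L
    t_vec <- normalize_vec(drop(K %*% u))
    if (is.null(t_vec)) return(NULL)  # K annihilates the response direction
    cvec <- drop(crossprod(Y, t_vec))
    u_new <- normalize_vec(drop(Y %*% cvec))
    if (is.null(u_new)) return(NULL)
    u <- u_new
    if (sqrt(sum((t_vec - t_old)^2)) < inner_tol) { converged <- TRUE; break }
    t_old <- t_vec
  }
  if (!converged)
    warning("kernel NIPALS inner loop did not converge within ",
            inner_max_iter, " iterations", call. = FALSE)
  cvec <- drop(crossprod(Y, t_vec))
  i <- which.max(abs(cvec))
  if (cvec[i] < 0) { t_vec <- -t_vec; u <- -u }
  list(t = t_vec, u = u, iters = iters, converged = converged)
}

#' Deflate the Gram and response matrices by an extracted component
#'
#' Removes the contribution of the unit score vector `t`:
#' `Y <- Y - t t' Y` and `K <- (I - t t') K (I - t t')`. After deflation
#' `t' Y = 0` and `K t = 0`, which is what makes successive score vectors
#' mutually orthogonal.
#'
#' @param K Residual Gram matrix.
#' @param Y Residual response matrix.
#' @param t Unit-norm score vector.
#' @return List with elements `K` and `Y`.
#' @export
deflate_kpls <- function(K, Y, t) {
  K <- unclass(K); Y <- unclass(Y)
  t <- drop(t)
  stopifnot(abs(sum(t^2) - 1) < 1e-8)
  Y_next <- Y - t %*% crossprod(t, Y)
  Kt <- drop(K %*% t)
  K_next <- K - tcrossprod(t, Kt) - tcrossprod(Kt, t) +
    drop(crossprod(t, Kt)) * tcrossprod(t)
  K_next <- (K_next + t(K_next)) / 2
  list(K = K_next, Y = Y_next)
}

#' Variation of the response explained by a component
#'
#' The Rd statistic: the mean squared Pearson correlation between the score
#' vector and the columns of the original centered indicator matrix. A
#' zero-variance response column contributes 0; a zero-variance score vector
#' yields 0 with a warning.
#'
#' @param t Score vector.
#' @param Y Original centered indicator matrix (not the deflated residual).
#' @return A number in `[0, 1]`.
#' @export
rd_contribution <- function(t, Y) {
  t <- drop(t); Y <- unclass(Y)
  if (sqrt(sum(t^2)) == 0) stop("score vector has zero norm", call. = FALSE)
  if (stats::sd(t) < 1e-300) {
    warning("score vector has zero variance; Rd = 0", call. = FALSE)
    return(0)
  }
  r2 <- apply(Y, 2L, function(y) {
    if (stats::sd(y) < 1e-300) return(0)
    stats::cor(y, t)^2
  })
  mean(r2)
}

#' Fisher discriminant ratio of component scores
#'
#' Between-class scatter over within-class scatter of the per-sample scores:
#' `J = sum_i n_i (m_i - m)^2 / sum_i sum_{j in class i} (t_j - m_i)^2`.
#' Perfect separation (zero within-class scatter with positive between-class
#' scatter) returns `Inf`. Larger values mean the component is more useful
#' for classification; the self-adaptive stopping rule in [kpls()] retains
#' components while their ratio stays above a fraction of the best one seen.
#'
#' @param t Score vector of length n.
#' @param labels Class labels (at least 2 classes).
#' @return Nonnegative number, possibly `Inf`.
#' @export
#' @examples
#' fisher_ratio(c(0, 1, 2, 3), c("a", "a", "b", "b"))  # 4
fisher_ratio <- function(t, labels) {
  t <- drop(t)
  labels <- as.character(labels)
  stopifnot(length(t) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  m <- mean(t)
  cm <- tapply(t, labels, mean)
  nc <- tapply(t, labels, length)
  between <- sum(nc * (cm - m)^2)
  within <- sum((t - cm[labels])^2)
  if (within < 1e-12) {
    if (between > 0) return(Inf)
    return(0)
  }
  between / within
}

#' Fit the kernel-PLS feature-selection model
#'
#' Builds the centered Gram matrix, encodes the class labels as a centered
#' indicator matrix and repeatedly extracts score vectors by kernel NIPALS,
#' deflating both working matrices after each extraction. For every component
#' it records the variation of the response explained (Rd, used later to
#' weight gene importance) and the Fisher discriminant ratio J of its scores.
#'
#' The number of components is chosen self-adaptively: the first component is
#' always retained, and component `h > 1` is retained while
#' `J_h >= lambda_rel * J*`, where `J*` is the largest finite ratio observed
#' so far. Infinite ratios (perfect separation) are always retained and never
#' trigger stopping. Extraction also stops at `max_components` or when the
#' response residual is numerically exhausted. Pass `n_components` to request
#' a fixed number of components and bypass the Fisher-ratio rule.
#'
#' @param X Numeric samples-by-genes matrix; column names are used as gene
#'   identifiers.
#' @param labels Class labels, one per row of `X`.
#' @param kernel A [kernel_spec()] or kernel name.
#' @param gamma,degree,coef0 Kernel parameters, see [kernel_spec()].
#' @param n_components Optional fixed number of components (disables the
#'   self-adaptive rule).
#' @param max_components Cap on the number of components (default 10; always
#'   further capped at n - 1).
#' @param lambda_rel Relative Fisher-ratio threshold (default 0.05).
#' @param inner_tol,inner_max_iter Inner NIPALS loop controls.
#' @return An object of class `kpls` with elements `scores` (n-by-kappa
#'   matrix of orthonormal score vectors), `dual` (matching dual directions),
#'   `rd`, `fisher_j`, `kappa`, `stopping_reason` (one of `"threshold"`,
#'   `"max_components"`, `"y_exhausted"`), `trace` (per-extracted-component
#'   diagnostics including any rejected component), `Y` (centered indicator),
#'   `classes`, `labels`, `kernel`, and the matched `call`.
#' @export
#' @examples
#' sim <- simulate_microarray(n_samples = 40, n_genes = 100, seed = 1)
#' fit <- kpls(sim$expression, sim$labels, kernel = "rbf")
#' fit
kpls <- function(X, labels,
                 kernel = c("rbf", "linear", "polynomial"),
                 gamma = NULL, degree = 3L, coef0 = 1,
                 n_components = NULL, max_components = 10L,
                 lambda_rel = 0.05,
                 inner_tol = 1e-10, inner_max_iter = 500L) {
  cl <- match.call()
  if (is.character(kernel))
    kernel <- kernel_spec(match.arg(kernel), gamma = gamma,
                          degree = degree, coef0 = coef0)
  X <- validate_expression_matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (length(labels) != n)
    stop("length(labels) must equal nrow(X)", call. = FALSE)
  stopifnot(lambda_rel > 0, max_components >= 1, inner_tol > 0,
            inner_max_iter >= 1)

  Y0 <- encode_labels(labels)
  K <- center_gram(compute_gram(X, kernel))
  kernel <- attr(K, "kernel")

  fixed <- !is.null(n_components)
  h_max <- if (fixed) min(n_components, n - 1L) else min(max_components, n - 1L)

  Kh <- unclass(K); Yh <- unclass(Y0)
  Tmat <- NULL; Umat <- NULL
  rd <- numeric(0); jj <- numeric(0)
  trace <- list()
  j_star <- NA_real_
  reason <- "max_components"

  for (h in seq_len(h_max)) {
    if (sqrt(sum(Yh^2)) < 1e-12) { reason <- "y_exhausted"; break }
    comp <- extract_component(Kh, Yh, inner_tol, inner_max_iter)
    if (is.null(comp)) { reason <- "y_exhausted"; break }
    j_h <- fisher_ratio(comp$t, labels)
    rd_h <- rd_contribution(comp$t, Y0)
    retain <- fixed || h == 1L || is.infinite(j_h) || is.na(j_star) ||
      j_h >= lambda_rel * j_star
    trace[[h]] <- data.frame(component = h, rd = rd_h, fisher_j = j_h,
                             iters = comp$iters, retained = retain)
    if (!retain) { reason <- "threshold"; break }
    Tmat <- cbind(Tmat, comp$t)
    Umat <- cbind(Umat, comp$u)
    rd <- c(rd, rd_h); jj <- c(jj, j_h)
    if (is.finite(j_h) && (is.na(j_star) || j_h > j_star)) j_star <- j_h
    defl <- deflate_kpls(Kh, Yh, comp$t)
    Kh <- defl$K; Yh <- defl$Y
  }

  if (is.null(Tmat))
    stop("no component could be extracted; the kernel matrix carries no signal",
         call. = FALSE)
  colnames(Tmat) <- paste0("comp", seq_len(ncol(Tmat)))
  colnames(Umat) <- colnames(Tmat)
  structure(list(scores = Tmat, dual = Umat, rd = rd, fisher_j = jj,
                 kappa = ncol(Tmat), stopping_reason = reason,
                 trace = do.call(rbind, trace),
                 Y = Y0, classes = attr(Y0, "classes"),
                 labels = as.character(labels),
                 kernel = kernel, lambda_rel = lambda_rel,
                 n = n, p = ncol(X), gene_ids = colnames(X),
                 call = cl),
            class = "kpls")
}

#' @export
print.kpls <- function(x, ...) {
  cat("Kernel PLS feature-selection fit\n")
  cat("  samples:", x$n, " genes:", x$p, " classes:",
      length(x$classes), "\n")
  cat("  kernel:", x$kernel$name)
  if (!is.null(x$kernel$gamma)) cat(" (gamma = ", format(x$kernel$gamma, digits = 4), ")", sep = "")
  cat("\n")
  cat("  components retained:", x$kappa,
      " (stopping:", x$stopping_reason, ")\n")
  cat("  per-component Rd:", paste(format(x$rd, digits = 3), collapse = ", "), "\n")
  cat("  per-component J: ", paste(format(x$fisher_j, digits = 3), collapse = ", "), "\n")
  invisible(x)
}
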