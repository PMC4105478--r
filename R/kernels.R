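#' Kernel specification
#'
#' Describes the kernel function used to build the Gram matrix. Three kernels
#' are supported: `linear` (the plain dot product), `rbf`
#' (`exp(-gamma * ||x - y||^2)`) and `polynomial`
#' (`(gamma * <x, y> + coef0)^degree`).
#'
#' When `gamma` is `NULL` it is resolved at Gram-computation time to
#' `1 / (p * var(X))`, where `p` is the number of genes and `var(X)` the
#' overall element variance of the expression matrix. This keeps the kernel
#' width on the scale of the data regardless of dimensionality.
#'
#' @param name One of `"linear"`, `"rbf"`, `"polynomial"`.
#' @param gamma Positive kernel width (rbf) or slope (polynomial), or `NULL`
#'   for the data-driven default.
#' @param degree Positive integer degree (polynomial only).
#' @param coef0 Nonnegative offset (polynomial only); nonnegative values keep
#'   the kernel positive semi-definite.
#' @return An object of class `kernel_spec`.
#' @export
#' @examples
#' kernel_spec("rbf", gamma = 0.1)
kernel_spec <- function(name = c("linear", "rbf", "polynomial"),
                        gamma = NULL, degree = 3L, coef0 = 1) {
  name <- match.arg(name)
  if (!is.null(gamma)) {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
      stop("'gamma' must be a single positive number", call. = FALSE)
  }
  if (name == "polynomial") {
    if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
        degree != round(degree))
      stop("'degree' must be a positive integer", call. = FALSE)
    if (!is.numeric(coef0) || length(coef0) != 1L || !is.finite(coef0) || coef0 < 0)
      stop("'coef0' must be a nonnegative number", call. = FALSE)
  }
  structure(list(name = name, gamma = gamma,
                 degree = as.integer(degree), coef0 = coef0),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Kernel:", x$name)
  if (!is.null(x$gamma)) cat(", gamma =", format(x$gamma))
  if (x$name == "polynomial")
    cat(", degree =", x$degree, ", coef0 =", x$coef0)
  cat("\n")
  invisible(x)
}

resolve_gamma <- function(spec, X) {
  if (!is.null(spec$gamma)) return(spec$gamma)
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

validate_expression_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("expression matrix must be numeric", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("expression matrix contains missing or non-finite values; ",
         "impute or filter upstream before running kernel PLS", call. = FALSE)
  X
}

#' Compute the Gram matrix of an expression matrix
#'
#' Evaluates the kernel between every pair of samples. The result is an
#' `n x n` symmetric positive semi-definite matrix whose size does not
#' depend on the number of genes, which is what makes kernel PLS attractive
#' when genes vastly outnumber samples.
#'
#' @param X Numeric samples-by-genes matrix with no missing values.
#' @param spec A [kernel_spec()], or a kernel name that is passed to
#'   [kernel_spec()].
#' @param ... Further arguments to [kernel_spec()] when `spec` is a name.
#' @return A `gram` object: the kernel matrix with attributes `centered`
#'   (logical) and `kernel` (the resolved spec).
#' @export
#' @examples
#' X <- matrix(rnorm(20), 4, 5)
#' K <- compute_gram(X, "rbf")
#' diag(K)  # all 1 for the rbf kernel
compute_gram <- function(X, spec = kernel_spec("linear"), ...) {
  if (is.character(spec)) spec <- kernel_spec(spec, ...)
  stopifnot(inherits(spec, "kernel_spec"))
  X <- validate_expression_matrix(X)
  G <- tcrossprod(X)
  K <- switch(spec$name,
    linear = G,
    rbf = {
      g <- resolve_gamma(spec, X)
      sq <- diag(G)
      d2 <- outer(sq, sq, "+") - 2 * G
      d2[d2 < 0] <- 0  # guard rounding
      exp(-g * d2)
    },
    polynomial = {
      g <- resolve_gamma(spec, X)
      (g * G + spec$coef0)^spec$degree
    }
  )
  if (any(!is.finite(K)))
    stop("non-finite kernel values; rescale the data or adjust kernel parameters",
         call. = FALSE)
  K <- (K + t(K)) / 2
  spec$gamma <- resolve_gamma(spec, X)
  new_gram(K, centered = FALSE, kernel = spec)
}

new_gram <- function(K, centered, kernel = NULL) {
  structure(K, centered = centered, kernel = kernel,
            class = c("gram", class(matrix())))
}

#' Center a Gram matrix in feature space
#'
#' Applies the double-centering projector `(I - 11'/n) K (I - 11'/n)`, the
#' feature-space analogue of subtracting column means from the data matrix.
#' Row and column sums of the result are zero and positive semi-definiteness
#' is preserved. Centering twice is the same as centering once.
#'
#' @param K A Gram matrix as returned by [compute_gram()].
#' @return The centered `gram` object.
#' @export
center_gram <- function(K) {
  K <- unclass(K)
  n <- nrow(K)
  stopifnot(nrow(K) == ncol(K))
  rm_ <- rowMeans(K)
  Kc <- K - matrix(rm_, n, n) - matrix(rm_, n, n, byrow = TRUE) + mean(K)
  Kc <- (Kc + t(Kc)) / 2
  new_gram(Kc, centered = TRUE, kernel = attr(K, "kernel"))
}

is_centered_gram <- function(K) isTRUE(attr(K, "centered"))
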