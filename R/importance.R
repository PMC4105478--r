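#' Per-gene loadings of the retained components
#'
#' Projects each retained score vector back onto the genes: column `h` is
#' `X' t_h` (with `X` column-centered), scaled to unit Euclidean norm. Entry
#' `(j, h)` is the weight of gene `j` on component `h`. With
#' `loading = "corr"` the per-gene Pearson correlation with the scores is
#' used instead, which additionally normalizes genes by their spread.
#'
#' @param X The samples-by-genes matrix the model was fitted on.
#' @param fit A [kpls()] fit.
#' @param loading `"crossprod"` (default, `X't` weights) or `"corr"`.
#' @return A p-by-kappa matrix of unit-norm loading columns. A component
#'   whose loading vector is identically zero keeps a zero column (and a
#'   message is emitted).
#' @export
feature_loadings <- function(X, fit, loading = c("crossprod", "corr")) {
  loading <- match.arg(loading)
  stopifnot(inherits(fit, "kpls"))
  X <- validate_expression_matrix(X)
  if (nrow(X) != fit$n)
    stop("X does not match the samples the model was fitted on", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  W <- switch(loading,
    crossprod = crossprod(Xc, fit$scores),
    corr = {
      sds <- apply(Xc, 2L, stats::sd)
      W0 <- crossprod(Xc, fit$scores) / (fit$n - 1)
      sweep(W0, 1L, pmax(sds, 1e-300), "/") /
        matrix(apply(fit$scores, 2L, stats::sd), ncol(Xc), fit$kappa, byrow = TRUE)
    })
  norms <- sqrt(colSums(W^2))
  zero <- norms < 1e-300
  if (any(zero)) {
    message("component(s) ", paste(which(zero), collapse = ", "),
            " have zero gene loadings and contribute nothing to importance")
    norms[zero] <- 1
  }
  W <- sweep(W, 2L, norms, "/")
  rownames(W) <- fit$gene_ids
  colnames(W) <- colnames(fit$scores)
  W
}

#' Accumulated variation-explanation importance of each gene
#'
#' Combines the unit-norm loadings with the per-component variation
#' explained: the raw score of gene `j` is `sum_h Rd_h * w_{hj}^2` over the
#' retained components, normalized to sum to one over genes. Genes whose
#' expression aligns with components that explain much of the class
#' indicator receive high importance.
#'
#' @param loadings p-by-kappa loading matrix from [feature_loadings()].
#' @param rd Per-component Rd values (or a [kpls()] fit, from which they are
#'   taken).
#' @return A `kpls_ranking` data frame with columns `gene_id`, `importance`
#'   (nonnegative, summing to 1) and `rank` (1 = most important; ties broken
#'   by ascending gene id), ordered by rank. The number of components used
#'   is recorded in attribute `kappa_used`.
#' @export
importance_scores <- function(loadings, rd) {
  if (inherits(rd, "kpls")) rd <- rd$rd
  stopifnot(is.matrix(loadings), length(rd) == ncol(loadings))
  if (all(rd == 0))
    stop("no component explains the response", call. = FALSE)
  raw <- drop(loadings^2 %*% rd)
  importance <- raw / sum(raw)
  gene_id <- rownames(loadings)
  if (is.null(gene_id)) gene_id <- paste0("g", seq_along(importance))
  ord <- order(-importance, gene_id)
  rnk <- integer(length(ord)); rnk[ord] <- seq_along(ord)
  out <- data.frame(gene_id = gene_id[ord],
                    importance = importance[ord],
                    rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, kappa_used = length(rd),
            class = c("kpls_ranking", "data.frame"))
}

#' Fit and rank in one step
#'
#' Convenience wrapper: fits [kpls()] and returns the gene ranking via
#' [feature_loadings()] and [importance_scores()].
#'
#' @inheritParams kpls
#' @param loading Loading definition, see [feature_loadings()].
#' @param ... Passed to [kpls()].
#' @return A `kpls_ranking` data frame; the fit is attached as attribute
#'   `fit`.
#' @export
#' @examples
#' sim <- simulate_microarray(n_samples = 40, n_genes = 200, seed = 7)
#' rk <- kpls_rank(sim$expression, sim$labels, kernel = "rbf")
#' head(rk)
kpls_rank <- function(X, labels, ..., loading = c("crossprod", "corr")) {
  fit <- kpls(X, labels, ...)
  W <- feature_loadings(X, fit, loading = match.arg(loading))
  rk <- importance_scores(W, fit)
  attr(rk, "fit") <- fit
  rk
}

#' Select the top-k genes from a ranking
#'
#' @param ranking A `kpls_ranking` from [importance_scores()].
#' @param k Number of genes to keep, `1 <= k <= p`. The default of 30 sits
#'   in the 20-50 range where selection performance typically plateaus for
#'   microarray-scale data.
#' @return Character vector of the first `k` gene ids in rank order.
#' @export
select_top_k <- function(ranking, k = 30L) {
  stopifnot(inherits(ranking, "data.frame"))
  p <- nrow(ranking)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer", call. = FALSE)
  if (k > p)
    stop("'k' (", k, ") exceeds the number of genes (", p, ")", call. = FALSE)
  ranking$gene_id[order(ranking$rank)][seq_len(k)]
}
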