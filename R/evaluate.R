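#' Stratified cross-validation fold assignment
#'
#' Deals the samples of every class round-robin across folds after a seeded
#' shuffle, so each fold's class proportions match the global ones within
#' one sample and every class appears in every training split. This is the
#' reason multi-class runs use fewer folds: some classes have only a
#' handful of samples.
#'
#' @param labels Class labels.
#' @param n_folds Number of folds; must not exceed the smallest class size.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold ids (1..n_folds), one per sample.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  labels <- as.character(labels)
  sizes <- table(labels)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (n_folds > min(sizes))
    stop("n_folds (", n_folds, ") exceeds the smallest class size (",
         min(sizes), "); every class must be present in both the training ",
         "and the test split of every fold", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  offset <- 0L
  for (cl in names(sizes)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    # stagger the round-robin start so small remainders spread across folds
    offset <- (offset + length(idx)) %% n_folds
  }
  folds
}

#' Two-class area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen sample
#' of the positive class is scored above a randomly chosen sample of the
#' negative class, with ties counting one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores, larger meaning more positive-like.
#' @param labels Two-class labels.
#' @param positive The label treated as positive; defaults to the second
#'   class in first-appearance order.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_two_class(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"))  # 0.75
auc_two_class <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("AUC requires exactly 2 classes, both present", call. = FALSE)
  if (is.null(positive)) positive <- classes[2L]
  if (!positive %in% classes)
    stop("positive class '", positive, "' not present", call. = FALSE)
  pos <- labels == positive
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and expected agreement from the row and
#' column margins. The degenerate case `p_e = 1` returns 1 for perfect
#' agreement and 0 (with a warning) otherwise.
#'
#' @param confusion Square count matrix (predicted x true or vice versa).
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2))  # 0.4
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square", call. = FALSE)
  if (any(confusion < 0)) stop("negative counts", call. = FALSE)
  total <- sum(confusion)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(confusion)) / total
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - p_e) < 1e-12) {
    if (abs(p_o - 1) < 1e-12) return(1)
    warning("degenerate margins (p_e = 1); returning 0", call. = FALSE)
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Built-in classifier contracts
#'
#' Wraps k-nearest-neighbour ([class::knn()]) and a radial-kernel support
#' vector machine ([e1071::svm()]) behind a uniform train/predict contract
#' so [evaluate_selection()] stays classifier-agnostic. A custom classifier
#' is any list with elements `train(X, y) -> model` and
#' `predict(model, X) -> list(class = ..., score = ...)`, where `score` is a
#' numeric vector (two-class problems only, higher = more like the second
#' class) or `NULL`.
#'
#' @param name `"knn"` or `"svm"`.
#' @param knn_k Neighbourhood size for KNN (default 5).
#' @return A classifier contract list.
#' @export
make_classifier <- function(name = c("knn", "svm"), knn_k = 5L) {
  name <- match.arg(name)
  if (name == "knn") {
    list(
      name = "knn",
      train = function(X, y) list(X = X, y = factor(y)),
      predict = function(model, X) {
        pred <- class::knn(model$X, X, model$y, k = min(knn_k, nrow(model$X)),
                           prob = TRUE)
        prob_win <- attr(pred, "prob")
        lev <- levels(model$y)
        score <- if (length(lev) == 2L)
          ifelse(as.character(pred) == lev[2L], prob_win, 1 - prob_win)
        list(class = as.character(pred), score = score)
      })
  } else {
    list(
      name = "svm",
      train = function(X, y) e1071::svm(x = X, y = factor(y),
                                        kernel = "radial"),
      predict = function(model, X) {
        pred <- stats::predict(model, X, decision.values = TRUE)
        lev <- levels(model$fitted)
        score <- NULL
        if (length(lev) == 2L) {
          dv <- attr(pred, "decision.values")
          # decision values are oriented toward the first level of the pair
          score <- if (identical(colnames(dv)[1L],
                                 paste(lev[1L], lev[2L], sep = "/")))
            -dv[, 1L] else dv[, 1L]
        }
        list(class = as.character(pred), score = score)
      })
  }
}

#' Cross-validated evaluation of kernel-PLS gene selection
#'
#' Runs the full filter-then-classify pipeline under stratified k-fold
#' cross-validation: within every fold the kernel-PLS ranking is re-fitted
#' on the training split only (no selection leakage), a classifier is
#' trained on the top `top_k` genes, and accuracy, AUC (two-class only) and
#' Cohen's kappa are computed on the held-out split. Following common
#' practice for these sample sizes, two-class problems default to 10 folds
#' and multi-class problems to 5.
#'
#' @param X Samples-by-genes expression matrix.
#' @param labels Class labels.
#' @param top_k Number of genes selected per fold (default 30).
#' @param n_folds Number of folds; `NULL` picks 10 for two classes, 5
#'   otherwise.
#' @param classifier `"knn"`, `"svm"`, or a contract list from
#'   [make_classifier()].
#' @param knn_k KNN neighbourhood size (default 5).
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [kpls()] (kernel choice and parameters, stopping
#'   controls).
#' @return A `kpls_eval` list: `per_fold` data frame (`fold`, `n_test`,
#'   `acc`, `auc`, `kappa`), `summary` (mean and sd per metric), `selected`
#'   (per-fold gene sets), and the protocol settings.
#' @export
evaluate_selection <- function(X, labels, top_k = 30L, n_folds = NULL,
                               classifier = c("knn", "svm"), knn_k = 5L,
                               seed = 1L, ...) {
  X <- validate_expression_matrix(X)
  labels <- as.character(labels)
  classes <- unique(labels)
  c_ <- length(classes)
  if (is.null(n_folds)) n_folds <- if (c_ == 2L) 10L else 5L
  if (is.character(classifier))
    classifier <- make_classifier(match.arg(classifier), knn_k = knn_k)
  if (top_k > ncol(X))
    stop("top_k exceeds the number of genes", call. = FALSE)
  folds <- stratified_folds(labels, n_folds, seed = seed)

  rows <- vector("list", n_folds)
  selected <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    rk <- kpls_rank(X[tr, , drop = FALSE], labels[tr], ...)
    sel <- select_top_k(rk, top_k)
    selected[[f]] <- sel
    model <- classifier$train(X[tr, sel, drop = FALSE], labels[tr])
    out <- classifier$predict(model, X[te, sel, drop = FALSE])
    truth <- factor(labels[te], levels = classes)
    pred <- factor(out$class, levels = classes)
    acc <- mean(pred == truth)
    auc <- if (c_ == 2L && !is.null(out$score) &&
               length(unique(truth)) == 2L)
      auc_two_class(out$score, as.character(truth), positive = classes[2L])
    else NA_real_
    kap <- cohens_kappa(table(pred, truth))
    rows[[f]] <- data.frame(fold = f, n_test = sum(te), acc = acc,
                            auc = auc, kappa = kap)
  }
  per_fold <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("acc", "auc", "kappa"),
    mean = c(mean(per_fold$acc), mean(per_fold$auc), mean(per_fold$kappa)),
    sd = c(stats::sd(per_fold$acc), stats::sd(per_fold$auc),
           stats::sd(per_fold$kappa)))
  structure(list(per_fold = per_fold, summary = summ, selected = selected,
                 protocol = list(n_folds = n_folds, top_k = top_k,
                                 classifier = classifier$name %||% "custom",
                                 knn_k = knn_k, seed = seed)),
            class = "kpls_eval")
}

#' @export
print.kpls_eval <- function(x, ...) {
  cat("Cross-validated gene-selection evaluation (",
      x$protocol$n_folds, "-fold, top ", x$protocol$top_k, " genes, ",
      x$protocol$classifier, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
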