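#' Simulate a microarray-like expression dataset with known ground truth
#'
#' Generates the few-samples / many-genes structure typical of microarray
#' classification studies, with four gene roles recorded in a truth map:
#'
#' * **informative_linear** — class-shifted Gaussians; the mean shift between
#'   adjacent classes is `effect_size * noise_sd`.
#' * **informative_nonlinear** — genes that carry class information without
#'   any class-mean difference. For two classes these come in pairs whose
#'   sign product encodes the class (an XOR pattern: each gene is a
#'   symmetric two-state signal, and whether the pair agrees or disagrees is
#'   what the class determines); an unpaired leftover gene encodes the class
#'   in its variance. For three or more classes each gene places samples at
#'   a class-specific distance from zero with random sign, so the class is
#'   read from the (quadratic) distance, not the mean.
#' * **redundant** — `redundancy_rho`-correlated copies of randomly chosen
#'   informative genes.
#' * **noise** — i.i.d. Gaussians.
#'
#' Classes are balanced up to rounding unless `class_proportions` is given.
#' The dataset is fully reproducible from the arguments and `seed`.
#'
#' @param n_samples,n_genes Dataset dimensions (defaults 60 x 1000).
#' @param n_informative_linear,n_informative_nonlinear,n_redundant Gene role
#'   counts (defaults 5, 5, 40).
#' @param n_classes Number of classes (default 2).
#' @param effect_size Class-mean shift between adjacent classes, in units of
#'   `noise_sd` (default 1.5); also sets the amplitude of the nonlinear
#'   patterns.
#' @param redundancy_rho Target correlation of redundant genes with their
#'   parent (default 0.8).
#' @param noise_sd Standard deviation of the measurement noise (default 1).
#' @param class_proportions Optional per-class proportions (length
#'   `n_classes`, summing to 1).
#' @param seed Integer seed.
#' @return A `kpls_sim` list: `expression` (n x p matrix with sample and
#'   gene ids), `labels` (character vector), `truth` (data frame gene_id,
#'   role), and `config` (the arguments).
#' @export
#' @examples
#' sim <- simulate_microarray(n_samples = 20, n_genes = 50, seed = 1)
#' table(sim$truth$role)
simulate_microarray <- function(n_samples = 60L, n_genes = 1000L,
                                n_informative_linear = 5L,
                                n_informative_nonlinear = 5L,
                                n_redundant = 40L,
                                n_classes = 2L,
                                effect_size = 1.5,
                                redundancy_rho = 0.8,
                                noise_sd = 1.0,
                                class_proportions = NULL,
                                seed = 1L) {
  n_inf <- n_informative_linear + n_informative_nonlinear
  if (n_inf + n_redundant > n_genes)
    stop("informative + redundant genes exceed n_genes", call. = FALSE)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (n_redundant > 0L && n_inf == 0L)
    stop("redundant genes need at least one informative parent", call. = FALSE)
  if (!is.null(class_proportions)) {
    stopifnot(length(class_proportions) == n_classes,
              all(class_proportions > 0),
              abs(sum(class_proportions) - 1) < 1e-8)
  } else {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (redundancy_rho <= 0 || redundancy_rho >= 1)
    stop("'redundancy_rho' must be in (0, 1)", call. = FALSE)

  sizes <- floor(class_proportions * n_samples)
  rem <- n_samples - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  if (any(sizes < 2L))
    stop("each class must receive at least 2 samples", call. = FALSE)
  class_names <- paste0("class", seq_len(n_classes))
  labels <- rep(class_names, times = sizes)
  cls <- rep(seq_len(n_classes), times = sizes)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- n_samples; p <- n_genes
  X <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  role <- rep("noise", p)
  amp <- effect_size * noise_sd

  idx_lin <- seq_len(n_informative_linear)
  idx_non <- n_informative_linear + seq_len(n_informative_nonlinear)
  idx_red <- n_inf + seq_len(n_redundant)
  role[idx_lin] <- "informative_linear"
  role[idx_non] <- "informative_nonlinear"
  role[idx_red] <- "redundant"

  # linear: additive class-mean ladder on top of the noise draw
  for (j in idx_lin) X[, j] <- X[, j] + amp * (cls - 1)

  # nonlinear: zero class-mean difference by construction
  pair_noise <- 0.25 * noise_sd  # two-state signals measured with modest noise
  if (n_informative_nonlinear > 0L) {
    if (n_classes == 2L) {
      js <- idx_non
      while (length(js) >= 2L) {
        j1 <- js[1L]; j2 <- js[2L]; js <- js[-(1:2)]
        s <- sample(c(-1, 1), n, replace = TRUE)
        ysgn <- ifelse(cls == 1L, 1, -1)
        X[, j1] <- amp * s + stats::rnorm(n, sd = pair_noise)
        X[, j2] <- amp * s * ysgn + stats::rnorm(n, sd = pair_noise)
      }
      for (j in js) {  # odd leftover: variance-coded
        sd_by_class <- ifelse(cls == 1L, noise_sd, noise_sd * (1 + effect_size))
        X[, j] <- stats::rnorm(n, sd = sd_by_class)
      }
    } else {
      for (j in idx_non) {
        r <- amp * (cls - 1)  # class-specific distance from zero
        s <- sample(c(-1, 1), n, replace = TRUE)
        X[, j] <- s * r + stats::rnorm(n, sd = noise_sd)
      }
    }
  }

  # redundant: rho-correlated copies of randomly chosen informative genes
  if (n_redundant > 0L) {
    parents <- sample(c(idx_lin, idx_non), n_redundant, replace = TRUE)
    for (i in seq_len(n_redundant)) {
      parent <- X[, parents[i]]
      ps <- scale(parent)[, 1L]
      X[, idx_red[i]] <- redundancy_rho * ps +
        sqrt(1 - redundancy_rho^2) * stats::rnorm(n)
    }
  }

  gene_ids <- sprintf("gene%0*d", nchar(p), seq_len(p))
  sample_ids <- sprintf("sample%0*d", nchar(n), seq_len(n))
  dimnames(X) <- list(sample_ids, gene_ids)
  structure(list(
    expression = X,
    labels = labels,
    truth = data.frame(gene_id = gene_ids, role = role,
                       stringsAsFactors = FALSE),
    config = list(n_samples = n, n_genes = p,
                  n_informative_linear = n_informative_linear,
                  n_informative_nonlinear = n_informative_nonlinear,
                  n_redundant = n_redundant, n_classes = n_classes,
                  effect_size = effect_size,
                  redundancy_rho = redundancy_rho,
                  noise_sd = noise_sd, seed = as.integer(seed))),
    class = "kpls_sim")
}

#' @export
print.kpls_sim <- function(x, ...) {
  cat("Synthetic expression dataset:",
      nrow(x$expression), "samples x", ncol(x$expression), "genes,",
      length(unique(x$labels)), "classes\n")
  print(table(role = x$truth$role))
  invisible(x)
}

#' Write / read a simulated dataset as TSV files
#'
#' `write_dataset()` writes `expression.tsv` (samples x genes, first column
#' `sample_id`), `labels.tsv` (`sample_id`, `label`) and `truth.tsv`
#' (`gene_id`, `role`) into `dir`. `read_dataset()` reverses it; the
#' round-trip is lossless to well below 1e-9.
#'
#' @param ds A `kpls_sim` object (or any list with `expression`, `labels`,
#'   and optionally `truth`).
#' @param dir Output directory (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `kpls_sim` object (without `config`).
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- as.data.frame(ds$expression)
  expr <- cbind(sample_id = rownames(ds$expression), expr)
  utils::write.table(expr, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(ds$expression), label = ds$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$truth))
    utils::write.table(ds$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  expr_path <- file.path(dir, "expression.tsv")
  ds <- read_expression(expr_path, orientation = "samples_by_genes")
  labels <- read_labels(file.path(dir, "labels.tsv"), rownames(ds))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "role") %in% names(truth)))
      stop("truth.tsv must have columns gene_id and role", call. = FALSE)
    if (!setequal(truth$gene_id, colnames(ds)))
      stop("truth.tsv gene ids do not match expression.tsv header", call. = FALSE)
  }
  structure(list(expression = ds, labels = labels, truth = truth),
            class = "kpls_sim")
}
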