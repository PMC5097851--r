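#' Bundle one cell-line's scores and expression
#'
#' @param name cell-line label.
#' @param scores a [score_matrix()].
#' @param expression named numeric vector over the same genes (any order;
#'   alignment to a common gene universe happens in [align_datasets()]).
#' @return An object of class `cell_line_dataset`.
#' @export
cell_line_dataset <- function(name, scores, expression) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(scores, "score_matrix"),
            is.numeric(expression), !is.null(names(expression)))
  if (!setequal(rownames(scores$values), names(expression))) {
    stop_("dataset '", name, "': score and expression gene sets differ")
  }
  structure(list(name = name, scores = scores, expression = expression),
            class = "cell_line_dataset")
}

#' Align datasets to a common gene universe
#'
#' The gene universe is the intersection of gene ids across all datasets,
#' ordered by sorted gene id; every dataset's scores and expression are
#' subset and reordered to it.
#'
#' @param datasets list of [cell_line_dataset()] objects.
#' @return List of aligned datasets.
#' @export
align_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  universes <- lapply(datasets, function(d) rownames(d$scores$values))
  common <- Reduce(intersect, universes)
  if (length(common) == 0L) stop_("empty gene intersection across datasets")
  common <- sort(common, method = "radix")
  lapply(datasets, function(d) {
    v <- d$scores$values[common, , drop = FALSE]
    cell_line_dataset(d$name, score_matrix(v, has_bias = d$scores$has_bias),
                      d$expression[common])
  })
}

#' Enumerate directed train/test combinations
#'
#' Every ordered (train, test) pair over the given cell-line names,
#' including same-cell-line pairs: `length(names)^2` rows.
#'
#' @param names character vector of cell-line names.
#' @return A `data.frame` with columns `train` and `test`.
#' @export
cross_eval_combinations <- function(names) {
  stopifnot(is.character(names), length(names) >= 1L, !anyDuplicated(names))
  data.frame(train = rep(names, each = length(names)),
             test = rep(names, times = length(names)),
             stringsAsFactors = FALSE)
}

#' Directed cross-cell-line evaluation
#'
#' For every ordered pair (i, j) of cell-lines: fit an L2-regularised model
#' on cell-line i (lambda tuned by the one-SE CV rule within i, never on the
#' test line), predict cell-line j's expression from j's scores, and record
#' the adjusted R2. The diagonal holds same-cell-line fits.
#'
#' @param datasets list of >= 2 [cell_line_dataset()] objects.
#' @param lambda `"auto"` (per-training-line 1-SE CV) or a fixed
#'   non-negative number.
#' @param grid,k_folds,seed,penalize_bias,engine passed to the fitting
#'   routines.
#' @return An object of class `cross_eval`: `names`, `adj_r2` (square
#'   matrix, rows = training line, columns = tested line), `lambdas`,
#'   `fits`.
#' @export
cross_cell_line_eval <- function(datasets, lambda = "auto",
                                 grid = default_lambda_grid(), k_folds = 10L,
                                 seed = 0L, penalize_bias = TRUE,
                                 engine = engine_config()) {
  stopifnot(length(datasets) >= 2L)
  aligned <- align_datasets(datasets)
  nms <- vapply(aligned, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_("duplicate cell-line names")
  combos <- cross_eval_combinations(nms)
  k <- length(nms)
  fits <- vector("list", k)
  names(fits) <- nms
  for (i in seq_len(k)) {
    d <- aligned[[i]]
    fits[[i]] <- fit_expression_model(d$scores, d$expression, lambda = lambda,
                                      grid = grid, k_folds = k_folds,
                                      seed = seed,
                                      penalize_bias = penalize_bias,
                                      engine = engine)
  }
  m <- matrix(NA_real_, k, k, dimnames = list(train = nms, test = nms))
  n_pred <- fits[[1L]]$n_predictors
  for (r in seq_len(nrow(combos))) {
    i <- combos$train[r]
    j <- combos$test[r]
    dj <- aligned[[match(j, nms)]]
    yhat <- predict(fits[[i]], dj$scores)
    m[i, j] <- adjusted_r2(unname(dj$expression), yhat, n_pred)
  }
  structure(list(names = nms, adj_r2 = m,
                 lambdas = vapply(fits, `[[`, numeric(1), "lambda"),
                 fits = fits, combinations = combos),
            class = "cross_eval")
}

#' @export
print.cross_eval <- function(x, ...) {
  cat("Cross-cell-line evaluation over", length(x$names), "cell-lines (",
      nrow(x$combinations), "directed train/test combinations)\n")
  print(round(x$adj_r2, 3))
  invisible(x)
}

#' Residual matrix across cell-lines
#'
#' Entry (m, c) is `Y_c[m] - Yhat_c[m]`: the gene-level prediction error of
#' cell-line c's own model.
#'
#' @param datasets list of aligned [cell_line_dataset()] objects.
#' @param fits list of `epi_fit` objects, one per dataset in the same order.
#' @return Genes x cell-lines numeric matrix.
#' @export
residual_matrix <- function(datasets, fits) {
  stopifnot(length(datasets) == length(fits))
  genes <- rownames(datasets[[1L]]$scores$values)
  for (d in datasets) {
    if (!identical(rownames(d$scores$values), genes)) {
      stop_("datasets are not aligned to a common gene ordering (run ",
            "align_datasets first)")
    }
  }
  res <- vapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    unname(d$expression) - predict(fits[[i]], d$scores)
  }, numeric(length(genes)))
  dimnames(res) <- list(genes, vapply(datasets, `[[`, character(1), "name"))
  res
}

#' Hierarchically cluster cell-lines by residual profiles
#'
#' Agglomerative clustering of the residual-matrix columns; default distance
#' 1 - Pearson correlation, default average linkage.
#'
#' @param residuals genes x cell-lines matrix from [residual_matrix()].
#' @param metric `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return An object of class `residual_dendrogram` wrapping the `hclust`
#'   merge history, with `metric` and `linkage` labels.
#' @export
cluster_cell_lines <- function(residuals,
                               metric = c("correlation", "euclidean"),
                               linkage = c("average", "complete", "single")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(residuals))
  if (ncol(residuals) < 2L) stop_("need >= 2 cell-line columns to cluster")
  if (metric == "correlation") {
    sds <- apply(residuals, 2L, stats::sd)
    if (any(sds == 0)) {
      stop_("constant residual column(s) under the correlation metric: ",
            paste(colnames(residuals)[sds == 0], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(residuals))
  } else {
    d <- stats::dist(t(residuals))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, metric = metric, linkage = linkage,
                 labels = colnames(residuals)),
            class = "residual_dendrogram")
}

#' @export
print.residual_dendrogram <- function(x, ...) {
  cat("Residual dendrogram over", length(x$labels), "cell-lines (",
      x$metric, "distance,", x$linkage, "linkage)\n")
  invisible(x)
}

#' Are two leaves siblings in the dendrogram?
#'
#' TRUE when the two cell-lines are joined directly by a single merge (both
#' enter that merge as singletons).
#'
#' @param dendrogram a `residual_dendrogram`.
#' @param a,b leaf labels.
#' @return Logical scalar.
#' @export
are_siblings <- function(dendrogram, a, b) {
  stopifnot(inherits(dendrogram, "residual_dendrogram"))
  hc <- dendrogram$hclust
  ia <- match(a, hc$labels)
  ib <- match(b, hc$labels)
  if (is.na(ia) || is.na(ib)) stop_("unknown leaf label")
  any(apply(hc$merge, 1L, function(row) {
    all(row < 0) && setequal(-row, c(ia, ib))
  }))
}

#' Serialise a dendrogram as Newick
#'
#' Branch lengths follow the merge heights (via [ape::as.phylo()]).
#'
#' @param dendrogram a `residual_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "residual_dendrogram"))
  ape::write.tree(ape::as.phylo(dendrogram$hclust), file = path)
  invisible(path)
}

#' Distribution of fitted coefficients across cell-lines
#'
#' Five-number summary (min, quartiles by linear interpolation, max) of each
#' model coefficient over a set of fits sharing the same features.
#'
#' @param fits list of `epi_fit` objects with identical feature names.
#' @return A `data.frame` with one row per feature and columns `feature`,
#'   `min`, `q25`, `median`, `q75`, `max`.
#' @export
beta_summary <- function(fits) {
  stopifnot(length(fits) >= 1L)
  feats <- fits[[1L]]$feature_names
  for (f in fits) {
    if (!identical(f$feature_names, feats)) {
      stop_("fits do not share feature names")
    }
  }
  betas <- vapply(fits, `[[`, numeric(length(feats)), "beta")
  betas <- matrix(betas, nrow = length(feats))
  qs <- t(apply(betas, 1L, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE))
  data.frame(feature = feats, min = qs[, 1L], q25 = qs[, 2L],
             median = qs[, 3L], q75 = qs[, 4L], max = qs[, 5L],
             stringsAsFactors = FALSE)
}
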