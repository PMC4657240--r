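#' Principal component analysis of a binding matrix
#'
#' Columns are centered and scaled to unit variance, then decomposed by
#' PCA. Zero-variance columns are dropped with a warning. Component signs
#' are fixed deterministically: within each component, the loading of
#' largest magnitude is made positive.
#'
#' @param matrix A `binding_matrix` from [build_matrix()], or any tibble
#'   with a `peak_id` column and numeric dataset columns.
#' @return An object of class `crm_pca` with elements `scores`
#'   (observations x components), `loadings` (variables x components),
#'   `sdev`, `explained` (variance fractions), `center`, `scale`,
#'   `peak_id`, `dropped` (names of zero-variance columns).
#' @export
fit_pca <- function(matrix) {
  X <- as.matrix(dplyr::select(tibble::as_tibble(matrix), -dplyr::any_of("peak_id")))
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 observations and >= 2 variables", call. = FALSE)
  v <- apply(X, 2, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped) == ncol(X)) stop("all columns have zero variance", call. = FALSE)
  if (length(dropped) > 0) {
    warning("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- scale(X, center = ctr, scale = scl)
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  # deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(
    scores = pr$x,
    loadings = pr$rotation,
    sdev = pr$sdev,
    explained = pr$sdev^2 / sum(pr$sdev^2),
    center = ctr,
    scale = scl,
    peak_id = if ("peak_id" %in% names(matrix)) matrix$peak_id else rownames(X),
    dropped = dropped
  ), class = "crm_pca")
}

#' @export
print.crm_pca <- function(x, ...) {
  cat("<crm_pca> ", nrow(x$scores), " observations, ", ncol(x$scores),
      " components; first explained fractions: ",
      paste(sprintf("%.2f", utils::head(x$explained, 4)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Choose the number of significant components
#'
#' @param model A `crm_pca` from [fit_pca()].
#' @param method `"fixed"` (use `k`; the reference parameterization fixes 4),
#'   `"broken_stick"` (components whose explained-variance fraction exceeds
#'   the broken-stick expectation, counted from the first), or `"kaiser"`
#'   (eigenvalues > 1).
#' @param k Number of components for `method = "fixed"`.
#' @return Integer count of significant components (at least 1).
#' @export
select_components <- function(model, method = c("fixed", "broken_stick", "kaiser"), k = 4) {
  stopifnot(inherits(model, "crm_pca"))
  method <- match.arg(method)
  p <- length(model$explained)
  if (method == "fixed") {
    if (k < 1 || k > p) stop("`k` must be between 1 and ", p, call. = FALSE)
    return(as.integer(k))
  }
  if (method == "kaiser") {
    return(max(1L, sum(model$sdev^2 > 1)))
  }
  bs <- broken_stick(p)
  ok <- model$explained > bs
  n <- if (ok[1]) {
    r <- rle(ok)
    r$lengths[1]
  } else 0L
  max(1L, as.integer(n))
}

# broken-stick expected variance fractions for p components
broken_stick <- function(p) {
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' Ward clustering of PCA scores into classes
#'
#' Ward linkage (Ward.D2 convention) on Euclidean distances of the score
#' matrix, cut into exactly `n_classes` classes. Class ids follow
#' dendrogram leaf order: the leftmost leaf block is class 1.
#'
#' @param scores Numeric matrix of observation scores (rows =
#'   observations), typically the first significant components of a
#'   [fit_pca()] model.
#' @param n_classes Number of classes to cut the tree into.
#' @param ward_criterion `"ward.D2"` (default) or `"ward.D"`.
#' @return List with `labels` (integer vector in 1..n_classes) and `tree`
#'   (the `hclust` object).
#' @export
cluster_classes <- function(scores, n_classes, ward_criterion = c("ward.D2", "ward.D")) {
  ward_criterion <- match.arg(ward_criterion)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n_classes < 1) stop("`n_classes` must be >= 1", call. = FALSE)
  if (n_classes > n) stop("`n_classes` exceeds the number of observations", call. = FALSE)
  hc <- stats::hclust(stats::dist(scores), method = ward_criterion)
  raw <- stats::cutree(hc, k = n_classes)
  labels <- relabel_by_leaf_order(raw, hc)
  list(labels = labels, tree = hc)
}

# renumber cutree labels so the leftmost dendrogram leaf block is class 1
relabel_by_leaf_order <- function(raw, hc) {
  pos <- order(hc$order)            # leaf position of each observation
  first_pos <- tapply(pos, raw, min)
  new_id <- rank(first_pos)
  as.integer(new_id[as.character(raw)])
}

#' Classify peaks from a binding matrix
#'
#' End-to-end classification: PCA with unit-variance scaling, significant
#' component selection, Ward clustering of the significant scores, and a
#' cut into `n_classes` classes numbered by dendrogram leaf order.
#'
#' @param matrix A `binding_matrix` from [build_matrix()].
#' @param n_classes Number of classes (9 in the reference parameterization).
#' @param method,k Component-selection rule, see [select_components()].
#' @param ward_criterion Passed to [cluster_classes()].
#' @return An object of class `crm_class_model` with the PCA model, the
#'   number of significant components, the linkage tree, and a tibble
#'   `classes` of (`peak_id`, `class`).
#' @export
classify_peaks <- function(matrix, n_classes = 9,
                           method = c("fixed", "broken_stick", "kaiser"), k = 4,
                           ward_criterion = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  pca <- fit_pca(matrix)
  ns <- select_components(pca, method = method, k = k)
  cl <- cluster_classes(pca$scores[, seq_len(ns), drop = FALSE], n_classes,
                        ward_criterion = match.arg(ward_criterion))
  structure(list(
    pca = pca,
    n_significant = ns,
    selection_method = method,
    tree = cl$tree,
    n_classes = as.integer(n_classes),
    classes = tibble::tibble(peak_id = pca$peak_id, class = cl$labels)
  ), class = "crm_class_model")
}

#' @export
print.crm_class_model <- function(x, ...) {
  cat("<crm_class_model> ", nrow(x$classes), " peaks in ", x$n_classes,
      " classes (", x$n_significant, " significant components)\n", sep = "")
  print(table(class = x$classes$class))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted class model
#'
#' @param x A `crm_class_model` from [classify_peaks()].
#' @param ... Unused.
#' @return One row per peak: `peak_id`, `class`, and the scores of the
#'   significant components (`PC1`, `PC2`, ...).
#' @export
tidy.crm_class_model <- function(x, ...) {
  sc <- tibble::as_tibble(x$pca$scores[, seq_len(x$n_significant), drop = FALSE])
  dplyr::bind_cols(x$classes, sc)
}

#' Glance at a fitted class model
#'
#' @param x A `crm_class_model`.
#' @param ... Unused.
#' @return One-row tibble: number of observations, variables, significant
#'   components, classes, and variance explained by the significant
#'   components.
#' @export
glance.crm_class_model <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$classes),
    n_vars = nrow(x$pca$loadings),
    n_significant = x$n_significant,
    n_classes = x$n_classes,
    explained_significant = sum(x$pca$explained[seq_len(x$n_significant)])
  )
}

#' Tidy a PCA fit
#'
#' @param x A `crm_pca` from [fit_pca()].
#' @param matrix `"scores"` (default) or `"loadings"`.
#' @param ... Unused.
#' @return Long tibble of scores (per peak) or loadings (per variable).
#' @export
tidy.crm_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    dplyr::bind_cols(tibble::tibble(peak_id = x$peak_id),
                     tibble::as_tibble(x$scores))
  } else {
    dplyr::bind_cols(tibble::tibble(dataset = rownames(x$loadings)),
                     tibble::as_tibble(x$loadings))
  }
}

#' @export
glance.crm_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$sdev),
    explained_pc1 = x$explained[1],
    explained_pc2 = x$explained[2]
  )
}

#' Score plot of a class model
#'
#' @param object A `crm_class_model`.
#' @param ... Unused.
#' @return A ggplot of the first two component scores coloured by class.
#' @export
autoplot.crm_class_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = factor(.data$class))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "class",
                  x = sprintf("PC1 (%.0f%%)", 100 * object$pca$explained[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * object$pca$explained[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
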