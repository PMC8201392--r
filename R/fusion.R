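# Serial feature fusion and classical classification. The four feature
# blocks -- Sv (HOG), Tv (SFTA), Uv (LBP) and xv (deep global-average-pool
# features) -- are z-scored per feature with train-split statistics and
# concatenated in that fixed order into one fused vector per image.

#' Per-feature standardisation statistics
#'
#' Column means and standard deviations of a training feature matrix.
#' Zero-variance features are flagged so [fuse()] can map them to 0 instead
#' of dividing by zero.
#'
#' @param x numeric matrix or tibble of training features.
#' @return a `fusion_stats` list.
#' @export
fusion_stats <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  if (nrow(x) == 1L) sd[] <- 0
  structure(list(mean = mu, sd = sd), class = "fusion_stats")
}

.apply_stats <- function(x, st) {
  x <- as.matrix(x)
  n <- nrow(x)
  z <- (x - rep(st$mean, each = n))
  good <- st$sd > 0
  z[, good] <- z[, good, drop = FALSE] / rep(st$sd[good], each = n)
  z[, !good] <- 0
  z
}

#' Serial fusion of feature blocks
#'
#' Concatenates the blocks in the fixed order Sv, Tv, Uv, xv after
#' per-feature z-scoring (training statistics; zero-variance features pass
#' through as 0). Any block may be `NULL` to disable it, but at least one
#' must be present, and no present block may be empty.
#'
#' @param Sv,Tv,Uv,xv numeric matrices (rows = images) or vectors (a
#'   single image), or `NULL`.
#' @param stats optional named list of `fusion_stats` per block (as
#'   returned by a previous call's `stats` element); when missing, the
#'   statistics are computed from the supplied blocks, which is the
#'   train-split usage.
#' @return a `fused_features` object: `values` (matrix), `block_offsets`
#'   (tibble with `name`, `start` (0-based), `length`) and `stats`.
#' @export
fuse <- function(Sv = NULL, Tv = NULL, Uv = NULL, xv = NULL, stats = NULL) {
  blocks <- list(Sv = Sv, Tv = Tv, Uv = Uv, xv = xv)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) stop("no feature blocks given", call. = FALSE)
  blocks <- lapply(blocks, function(b) {
    if (is.null(dim(b))) b <- matrix(b, nrow = 1L,
                                     dimnames = list(NULL, names(b)))
    as.matrix(b)
  })
  if (any(vapply(blocks, ncol, integer(1)) == 0L)) {
    stop("empty feature block", call. = FALSE)
  }
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1L) stop("blocks disagree on row count", call. = FALSE)
  if (is.null(stats)) stats <- lapply(blocks, fusion_stats)
  z <- mapply(function(b, st) .apply_stats(b, st), blocks,
              stats[names(blocks)], SIMPLIFY = FALSE)
  values <- do.call(cbind, z)
  lens <- vapply(z, ncol, integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  structure(list(values = values,
                 block_offsets = tibble::tibble(name = names(blocks),
                                                start = as.integer(offs),
                                                length = as.integer(lens)),
                 stats = stats),
            class = "fused_features")
}

#' Slice one block back out of a fused vector
#'
#' @param fused a `fused_features` object.
#' @param name block name (`"Sv"`, `"Tv"`, `"Uv"`, `"xv"`).
#' @return the (post-normalization) block matrix.
#' @export
fused_block <- function(fused, name) {
  bo <- fused$block_offsets
  row <- bo[bo$name == name, ]
  if (nrow(row) == 0L) stop("no block named ", name, call. = FALSE)
  fused$values[, row$start + seq_len(row$length), drop = FALSE]
}

#' Fit a classifier on fused features
#'
#' The three classical back-ends of the fusion defense: an RBF-kernel SVM
#' (one-vs-one), cubic-distance k-nearest-neighbors (Minkowski p = 3,
#' k = 10) and a bagged-tree ensemble (random forest, 100 trees).
#'
#' @param features numeric matrix (rows = images).
#' @param labels class labels.
#' @param kind `"svm"`, `"knn_cubic"` or `"ensemble"`.
#' @param seed integer seed for the stochastic back-ends.
#' @param knn_k neighbors for `"knn_cubic"`.
#' @return a `fusion_classifier` object.
#' @export
fit_fusion_classifier <- function(features, labels,
                                  kind = c("svm", "knn_cubic", "ensemble"),
                                  seed = 1L, knn_k = 10L) {
  kind <- match.arg(kind)
  x <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) {
    stop("training labels must contain at least 2 classes", call. = FALSE)
  }
  fit <- withr::with_seed(as.integer(seed), switch(
    kind,
    svm = e1071::svm(x, y, kernel = "radial", probability = TRUE),
    knn_cubic = list(x = x, y = y, k = as.integer(knn_k), p = 3),
    ensemble = randomForest::randomForest(x, y, ntree = 100L)))
  structure(list(kind = kind, fit = fit, classes = levels(y), seed = seed),
            class = "fusion_classifier")
}

.knn_predict <- function(fit, newx) {
  if (ncol(newx) != ncol(fit$x)) {
    stop("feature dimensionality mismatch: got ", ncol(newx),
         ", trained on ", ncol(fit$x), call. = FALSE)
  }
  ntr <- nrow(fit$x)
  k <- min(fit$k, ntr)
  classes <- levels(fit$y)
  prob <- matrix(0, nrow(newx), length(classes),
                 dimnames = list(NULL, classes))
  for (i in seq_len(nrow(newx))) {
    d <- rowSums(abs(fit$x - rep(newx[i, ], each = ntr))^fit$p)^(1 / fit$p)
    nb <- order(d)[seq_len(k)]
    tab <- table(factor(fit$y[nb], levels = classes))
    prob[i, ] <- as.numeric(tab) / k
  }
  prob
}

#' Predict from a fusion classifier
#'
#' @param object a `fusion_classifier`.
#' @param newdata feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return label vector or probability matrix (columns = classes).
#' @export
predict.fusion_classifier <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  prob <- switch(object$kind,
    svm = {
      p <- stats::predict(object$fit, x, probability = TRUE)
      attr(p, "probabilities")[, object$classes, drop = FALSE]
    },
    knn_cubic = .knn_predict(object$fit, x),
    ensemble = stats::predict(object$fit, x, type = "prob")[,
      object$classes, drop = FALSE])
  if (type == "prob") return(prob)
  object$classes[max.col(prob, ties.method = "first")]
}

#' Evaluate a classifier on a test set
#'
#' Overall accuracy, per-class one-vs-rest accuracy/precision/recall/F1,
#' the confusion matrix, and per-class one-vs-rest ROC curves with AUC
#' computed from the continuous class scores.
#'
#' @param classifier a `fusion_classifier` (or any object with a
#'   `predict(object, x, type = "prob")` method over the same classes).
#' @param features test feature matrix.
#' @param labels true test labels.
#' @return a `retfuse_eval` object.
#' @export
evaluate_classifier <- function(classifier, features, labels) {
  x <- as.matrix(features)
  if (nrow(x) == 0L) stop("empty test set", call. = FALSE)
  prob <- predict(classifier, x, type = "prob")
  classes <- classifier$classes
  pred <- classes[max.col(prob, ties.method = "first")]
  truth <- as.character(labels)
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  acc <- sum(diag(cm)) / sum(cm)
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- sum(cm) - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, n = tp + fn,
                   accuracy = (tp + tn) / sum(cm),
                   precision = prec, recall = rec, f1 = f1)
  })
  per <- dplyr::bind_rows(per)
  roc <- lapply(classes, function(cl) {
    resp <- as.integer(truth == cl)
    if (length(unique(resp)) < 2L) return(NULL)
    r <- pROC::roc(resp, prob[, cl], quiet = TRUE,
                   direction = "<", levels = c(0, 1))
    tibble::tibble(class = cl,
                   fpr = 1 - r$specificities,
                   tpr = r$sensitivities,
                   auc = as.numeric(r$auc))
  })
  roc <- dplyr::bind_rows(roc)
  structure(list(accuracy = acc, per_class = per,
                 confusion = cm, roc = roc,
                 macro_auc = if (nrow(roc)) {
                   mean(vapply(split(roc$auc, roc$class),
                               function(a) a[1], numeric(1)))
                 } else NA_real_),
            class = "retfuse_eval")
}

#' @export
print.retfuse_eval <- function(x, ...) {
  cat(sprintf("<retfuse_eval> accuracy %.4f, macro AUC %.4f\n",
              x$accuracy, x$macro_auc))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.retfuse_eval <- function(x, ...) x$per_class

#' @export
glance.retfuse_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_auc = x$macro_auc,
                 n = sum(x$confusion),
                 macro_f1 = mean(x$per_class$f1))
}

#' ROC curves of an evaluation
#'
#' One-vs-rest ROC curve per class, AUC in the legend.
#'
#' @param object a `retfuse_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.retfuse_eval <- function(object, ...) {
  d <- object$roc
  d$label <- sprintf("%s (AUC %.3f)", d$class, d$auc)
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr,
                                  colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of fused features
#'
#' Projects the fused feature matrix on its first two principal components
#' and colours points by label -- the companion figure to the ROC curve.
#'
#' @param fused a `fused_features` object (or plain matrix).
#' @param labels class labels, one per row.
#' @return a ggplot object.
#' @export
plot_fusion_scatter <- function(fused, labels) {
  x <- if (inherits(fused, "fused_features")) fused$values else
    as.matrix(fused)
  pc <- stats::prcomp(x, rank. = 2L)
  d <- tibble::tibble(pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                      label = as.character(labels))
  ggplot2::ggplot(d, ggplot2::aes(.data$pc1, .data$pc2,
                                  colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = NULL) +
    ggplot2::theme_minimal()
}
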