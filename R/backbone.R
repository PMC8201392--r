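# Surrogate backbone: a compact darknet-style CNN (stride-2 conv blocks,
# batch norm, leaky ReLU, global average pooling, softmax head) trained
# with plain SGD on cross-entropy. Stands in for a fine-tuned large
# backbone at desk scale; the architecture is pluggable through the
# generic score/gradient interface, which an affine classifier also
# implements (used for closed-form attack oracles).

#' Training configuration for the surrogate classifier
#'
#' @param epochs passes over the training split.
#' @param learning_rate fixed SGD step size.
#' @param batch_size minibatch size.
#' @param frozen_prefix_fraction fraction in `[0, 1]` of the leading conv
#'   blocks whose parameters (weights, batch-norm statistics) are left
#'   untouched during training; the classification head always trains.
#' @param seed integer seed controlling initialisation and shuffling.
#' @param channels channel plan of the conv blocks.
#' @param momentum classical momentum coefficient of the SGD update
#'   (0 recovers plain fixed-step SGD).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 15L, learning_rate = 0.2,
                         batch_size = 64L, frozen_prefix_fraction = 0,
                         seed = 1L, channels = c(8L, 16L, 32L),
                         momentum = 0.9) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            frozen_prefix_fraction >= 0, frozen_prefix_fraction <= 1,
            momentum >= 0, momentum < 1)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 frozen_prefix_fraction = frozen_prefix_fraction,
                 seed = as.integer(seed),
                 channels = as.integer(channels),
                 momentum = momentum),
            class = "train_config")
}

# Stack a list of H x W x 3 arrays into a (H*W*3) x B matrix.
images_to_matrix <- function(images) {
  vapply(images, as.vector, numeric(length(images[[1]])))
}

#' Train the surrogate classifier
#'
#' Trains the compact CNN on the `train` split of `data` with fixed-step
#' SGD on cross-entropy. When `base_model` is given, its conv blocks are
#' reused and only the classification head is re-initialised for the class
#' count of `data` (the transfer-learning path); combined with
#' `frozen_prefix_fraction` this reproduces head-only fine-tuning.
#'
#' @param data dataset tibble; rows with `split == "train"` are used.
#' @param config a [train_config()].
#' @param base_model optional fitted `retfuse_cnn` whose conv blocks seed
#'   the new model.
#' @return a fitted `retfuse_cnn` object.
#' @export
train_classifier <- function(data, config = train_config(),
                             base_model = NULL) {
  validate_dataset(data)
  tr <- data[data$split == "train", ]
  if (nrow(tr) == 0L) stop("empty train split", call. = FALSE)
  classes <- sort(unique(tr$label))
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  input_size <- dim(tr$image[[1]])[1]
  y <- match(tr$label, classes)
  X <- images_to_matrix(tr$image)
  n <- ncol(X)

  withr::with_seed(config$seed, {
    if (is.null(base_model)) {
      net <- nn_new(input_size, length(classes), config$channels)
    } else {
      net <- base_model$net
      net$n_classes <- length(classes)
      net$head <- list(
        W = matrix(stats::rnorm(net$feature_dim * length(classes),
                                sd = 0.1),
                   net$feature_dim, length(classes)),
        b = numeric(length(classes)))
    }
    nl <- length(net$layers)
    frozen <- seq_len(nl) <= floor(config$frozen_prefix_fraction * nl + 1e-9)

    history <- tibble::tibble(epoch = integer(), loss = numeric(),
                              accuracy = numeric())
    first_loss <- NA_real_
    vel <- NULL
    decay_at <- ceiling(2 * config$epochs / 3)
    for (ep in seq_len(config$epochs)) {
      lr_ep <- if (ep > decay_at) config$learning_rate * 0.3 else
        config$learning_rate
      ord <- sample.int(n)
      ep_loss <- 0
      ep_hits <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        bi <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- X[, bi, drop = FALSE]
        yb <- y[bi]
        fw <- nn_forward(net, Xb, train = TRUE)
        p <- nn_softmax(fw$logits)
        B <- length(bi)
        ll <- -mean(log(pmax(p[cbind(seq_len(B), yb)], 1e-12)))
        if (is.na(first_loss)) first_loss <- ll
        ep_loss <- ep_loss + ll * B
        ep_hits <- ep_hits + sum(max.col(p) == yb)
        dl <- p
        dl[cbind(seq_len(B), yb)] <- dl[cbind(seq_len(B), yb)] - 1
        dl <- dl / B
        grads <- nn_backward(net, fw, dl, train = TRUE)
        st <- nn_sgd_step(net, grads, lr_ep, frozen, vel, config$momentum)
        net <- st$net
        vel <- st$vel
        net <- nn_update_running(net, fw$caches, frozen)
      }
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = ep, loss = ep_loss / n, accuracy = ep_hits / n))
    }
    # Recalibrate BN running statistics with the final parameters: the
    # exponential running estimates lag the momentum-SGD trajectory, so
    # inference-mode statistics are recomputed from full training passes.
    nlayers <- length(net$layers)
    mu_acc <- vector("list", nlayers)
    v_acc <- vector("list", nlayers)
    wsum <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      bi <- s:min(s + config$batch_size - 1L, n)
      fw <- nn_forward(net, X[, bi, drop = FALSE], train = TRUE)
      w <- length(bi)
      for (i in seq_len(nlayers)) {
        if (frozen[i]) next
        mu_acc[[i]] <- if (is.null(mu_acc[[i]])) w * fw$caches[[i]]$mu else
          mu_acc[[i]] + w * fw$caches[[i]]$mu
        v_acc[[i]] <- if (is.null(v_acc[[i]])) w * fw$caches[[i]]$v else
          v_acc[[i]] + w * fw$caches[[i]]$v
      }
      wsum <- wsum + w
    }
    for (i in seq_len(nlayers)) {
      if (frozen[i]) next
      net$layers[[i]]$run_mean <- mu_acc[[i]] / wsum
      net$layers[[i]]$run_var <- v_acc[[i]] / wsum
    }
    structure(list(net = net, classes = classes, config = config,
                   history = history, first_loss = first_loss,
                   input_size = input_size,
                   feature_dim = net$feature_dim,
                   n_classes = length(classes)),
              class = "retfuse_cnn")
  })
}

#' @export
print.retfuse_cnn <- function(x, ...) {
  cat("<retfuse_cnn> ", length(x$net$layers), " conv blocks (",
      paste(x$net$channels, collapse = "-"), "), input ",
      x$input_size, "x", x$input_size, ", classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final training loss %.4f, accuracy %.3f (%d epochs)\n",
                last$loss, last$accuracy, nrow(x$history)))
  }
  invisible(x)
}

#' @export
glance.retfuse_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(n_classes = x$n_classes, input_size = x$input_size,
                 feature_dim = x$feature_dim, epochs = nrow(x$history),
                 initial_loss = x$first_loss, final_loss = last$loss,
                 train_accuracy = last$accuracy)
}

#' @export
tidy.retfuse_cnn <- function(x, ...) x$history

.check_image_size <- function(model, img) {
  d <- dim(img)
  if (d[1] != model$input_size || d[2] != model$input_size) {
    stop("image is ", d[1], "x", d[2], " but the model expects ",
         model$input_size, "x", model$input_size, call. = FALSE)
  }
}

#' Per-class scores (logits) of a model
#'
#' Generic interface the attacks are written against: any classifier that
#' can report per-class real-valued scores and their input gradients can be
#' attacked.
#'
#' @param model fitted classifier.
#' @param images list of image arrays (or a single array).
#' @return numeric matrix, one row per image, one column per class.
#' @export
predict_scores <- function(model, images) UseMethod("predict_scores")

#' @export
predict_scores.retfuse_cnn <- function(model, images) {
  if (!is.list(images)) images <- list(images)
  for (im in images) .check_image_size(model, im)
  fw <- nn_forward(model$net, images_to_matrix(images), train = FALSE)
  colnames(fw$logits) <- model$classes
  fw$logits
}

#' Class-probability vector for one image
#'
#' Softmax over the model scores; components are non-negative and sum to 1.
#'
#' @param model fitted classifier.
#' @param image image array matching the model input size.
#' @return named probability vector.
#' @export
predict_proba <- function(model, image) {
  p <- nn_softmax(predict_scores(model, image))
  stats::setNames(as.numeric(p), colnames(p))
}

#' Predict labels or probabilities for a dataset
#'
#' @param object fitted `retfuse_cnn`.
#' @param data dataset tibble.
#' @param type `"class"` for labels, `"prob"` for a probability matrix.
#' @param ... unused.
#' @return character vector of labels or a probability matrix.
#' @export
predict.retfuse_cnn <- function(object, data, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  p <- nn_softmax(predict_scores(object, data$image))
  if (type == "prob") return(p)
  object$classes[max.col(p)]
}

#' Gradient of the classification loss with respect to the input image
#'
#' Cross-entropy loss of the model at `image` against `true_label`,
#' differentiated through the whole network (inference-mode batch norm).
#'
#' @param model fitted classifier.
#' @param image image array.
#' @param true_label the true class label (or its index).
#' @return gradient array with the same shape as `image`.
#' @export
input_gradient <- function(model, image, true_label) {
  UseMethod("input_gradient")
}

.label_index <- function(model, true_label) {
  if (is.character(true_label)) {
    k <- match(true_label, model$classes)
  } else {
    k <- as.integer(true_label)
  }
  if (is.na(k) || k < 1L || k > length(model$classes)) {
    stop("true_label out of range", call. = FALSE)
  }
  k
}

#' @export
input_gradient.retfuse_cnn <- function(model, image, true_label) {
  .check_image_size(model, image)
  k <- .label_index(model, true_label)
  fw <- nn_forward(model$net, images_to_matrix(list(image)), train = FALSE)
  dl <- nn_softmax(fw$logits)
  dl[1, k] <- dl[1, k] - 1
  g <- nn_backward(model$net, fw, dl, train = FALSE,
                   need_input_grad = TRUE)$dinput
  array(g, dim(image))
}

#' Gradient of one class score with respect to the input image
#'
#' @param model fitted classifier.
#' @param image image array.
#' @param class_index class whose raw score is differentiated.
#' @return gradient array with the same shape as `image`.
#' @export
score_gradient <- function(model, image, class_index) {
  UseMethod("score_gradient")
}

#' @export
score_gradient.retfuse_cnn <- function(model, image, class_index) {
  .check_image_size(model, image)
  k <- .label_index(model, class_index)
  fw <- nn_forward(model$net, images_to_matrix(list(image)), train = FALSE)
  dl <- matrix(0, 1, model$n_classes)
  dl[1, k] <- 1
  g <- nn_backward(model$net, fw, dl, train = FALSE,
                   need_input_grad = TRUE)$dinput
  array(g, dim(image))
}

#' Gradients of every class score with respect to the input image
#'
#' Returns one gradient array per class. The default method loops over
#' [score_gradient()]; the CNN method shares a single batched
#' forward/backward pass across classes.
#'
#' @param model fitted classifier.
#' @param image image array.
#' @return list of gradient arrays, one per class.
#' @export
score_gradients_all <- function(model, image) {
  UseMethod("score_gradients_all")
}

#' @export
score_gradients_all.default <- function(model, image) {
  lapply(seq_along(model$classes), function(k) {
    score_gradient(model, image, k)
  })
}

#' @export
score_gradients_all.retfuse_cnn <- function(model, image) {
  .check_image_size(model, image)
  K <- model$n_classes
  X <- images_to_matrix(rep(list(image), K))
  fw <- nn_forward(model$net, X, train = FALSE)
  g <- nn_backward(model$net, fw, diag(K), train = FALSE,
                   need_input_grad = TRUE)$dinput
  lapply(seq_len(K), function(k) array(g[, k], dim(image)))
}

#' Deep features from the global-average-pool layer
#'
#' The per-channel spatial mean of the final convolutional activation map,
#' the `feature_dim`-long vector the fusion defense concatenates with the
#' handcrafted descriptors.
#'
#' @param model fitted `retfuse_cnn`.
#' @param image image array.
#' @return numeric vector of length `model$feature_dim`.
#' @export
deep_features <- function(model, image) {
  .check_image_size(model, image)
  fw <- nn_forward(model$net, images_to_matrix(list(image)), train = FALSE)
  as.numeric(fw$feats)
}

#' Deep-feature matrix for a dataset
#'
#' @param model fitted `retfuse_cnn`.
#' @param data dataset tibble.
#' @return tibble with columns `xv_1 ... xv_d`.
#' @export
deep_feature_matrix <- function(model, data) {
  fw <- nn_forward(model$net, images_to_matrix(data$image), train = FALSE)
  m <- fw$feats
  colnames(m) <- paste0("xv_", seq_len(ncol(m)))
  tibble::as_tibble(m)
}

#' Affine (linear) classifier with analytic gradients
#'
#' Scores are `W x + b` over the flattened image. Implements the same
#' score/gradient interface as the CNN, so attacks run unchanged; on this
#' model DeepFool has a closed form, which the test-suite oracles exploit.
#'
#' @param W K x D weight matrix (one row per class).
#' @param b length-K intercept vector.
#' @param classes optional class names.
#' @return an `affine_classifier` object.
#' @export
affine_classifier <- function(W, b = numeric(nrow(W)), classes = NULL) {
  stopifnot(is.matrix(W), length(b) == nrow(W))
  if (is.null(classes)) classes <- paste0("C", seq_len(nrow(W)))
  structure(list(W = W, b = b, classes = classes,
                 n_classes = nrow(W), input_size = NA_integer_),
            class = "affine_classifier")
}

#' @export
predict_scores.affine_classifier <- function(model, images) {
  if (!is.list(images)) images <- list(images)
  X <- vapply(images, as.vector, numeric(ncol(model$W)))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(images))
  s <- t(model$W %*% X + model$b)
  colnames(s) <- model$classes
  s
}

#' @export
input_gradient.affine_classifier <- function(model, image, true_label) {
  k <- .label_index(model, true_label)
  p <- nn_softmax(predict_scores(model, image))
  e <- as.numeric(p)
  e[k] <- e[k] - 1
  g <- as.numeric(crossprod(model$W, e))
  if (!is.null(dim(image))) array(g, dim(image)) else g
}

#' @export
score_gradient.affine_classifier <- function(model, image, class_index) {
  k <- .label_index(model, class_index)
  g <- model$W[k, ]
  if (!is.null(dim(image))) array(g, dim(image)) else g
}

#' Save / load a fitted model
#'
#' Thin wrappers over [saveRDS()]/[readRDS()]; checkpoints are
#' self-contained (parameters, class labels, training config, history).
#'
#' @param model fitted model.
#' @param path checkpoint file path.
#' @return `read_model` returns the model; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
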