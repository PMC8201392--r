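# Adversarial image generation: fast gradient sign method (FGSM),
# multiplicative speckle noise, and DeepFool (iterative projection onto the
# nearest linearized one-vs-all class boundary). All outputs are clipped
# back to [0, 1] so attacked images remain displayable and reusable for
# retraining.

#' Specification of an attack
#'
#' @param kind `"fgsm"`, `"speckle"` or `"deepfool"`.
#' @param epsilon FGSM step multiplier (the l-infinity budget).
#' @param s speckle-noise variance in `[0, 1]`; defaults to 0.5.
#' @param max_iter DeepFool iteration cap.
#' @param overshoot DeepFool final scaling `(1 + overshoot)`.
#' @param seed integer seed (used by the stochastic speckle attack;
#'   per-image substreams are derived from it and the item index).
#' @return an `attack_spec` list.
#' @export
attack_spec <- function(kind = c("fgsm", "speckle", "deepfool"),
                        epsilon = 0.05, s = 0.5, max_iter = 50L,
                        overshoot = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(epsilon >= 0, max_iter >= 1L, overshoot >= 0)
  if (s < 0 || s > 1) stop("s must lie in [0, 1]", call. = FALSE)
  structure(list(kind = kind, epsilon = epsilon, s = s,
                 max_iter = as.integer(max_iter), overshoot = overshoot,
                 seed = as.integer(seed)),
            class = "attack_spec")
}

.attack_result <- function(original, adversarial, perturbation, success,
                           iterations_used = 1L) {
  structure(list(adversarial = adversarial, perturbation = perturbation,
                 success = success,
                 iterations_used = as.integer(iterations_used)),
            class = "attack_result")
}

#' @export
print.attack_result <- function(x, ...) {
  cat("<attack_result> success:", x$success,
      " iterations:", x$iterations_used,
      " max|perturbation|:", signif(max(abs(x$perturbation)), 4), "\n")
  invisible(x)
}

.predicted_index <- function(model, image) {
  which.max(predict_scores(model, image)[1, ])
}

#' Fast gradient sign method attack
#'
#' Perturbs the image by `epsilon` times the sign of the gradient of the
#' classification loss with respect to the input, then clips to `[0, 1]`:
#' the single step that maximally increases the loss under an l-infinity
#' budget. `sign(0)` is taken as 0 so flat-gradient pixels are left alone.
#'
#' @param model classifier implementing [predict_scores()] and
#'   [input_gradient()].
#' @param image image array in `[0, 1]`.
#' @param true_label the image's true class.
#' @param epsilon perturbation budget (0 returns the image unchanged).
#' @return an `attack_result`; `adversarial` satisfies
#'   `max(abs(adversarial - image)) <= epsilon`.
#' @export
fgsm <- function(model, image, true_label, epsilon = 0.05) {
  stopifnot(epsilon >= 0)
  orig_pred <- .predicted_index(model, image)
  g <- input_gradient(model, image, true_label)
  pert <- epsilon * sign(g)
  adv <- clip01(image + pert)
  new_pred <- .predicted_index(model, adv)
  .attack_result(image, adv, adv - image, new_pred != orig_pred)
}

#' Multiplicative speckle-noise attack
#'
#' Adds signal-proportional granular noise, `S = I + n * I`, with `n` drawn
#' i.i.d. per pixel from the zero-mean uniform distribution with variance
#' `s` (i.e. uniform on `[-sqrt(3 s), +sqrt(3 s)]`), then clips to `[0, 1]`.
#' This is the noise model of coherent imaging (ultrasound, SAR) used here
#' as an attack.
#'
#' @param image image array in `[0, 1]`.
#' @param s noise variance in `[0, 1]`; default 0.5.
#' @param seed integer seed.
#' @param model optional classifier, only used to fill in the success flag.
#' @return an `attack_result`.
#' @export
speckle <- function(image, s = 0.5, seed = 1L, model = NULL) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]", call. = FALSE)
  if (s == 0) {
    return(.attack_result(image, image, 0 * image, FALSE))
  }
  half <- sqrt(3 * s)
  n <- withr::with_seed(as.integer(seed), {
    array(stats::runif(length(image), -half, half), dim(image))
  })
  adv <- clip01(image + n * image)
  success <- if (!is.null(model)) {
    .predicted_index(model, adv) != .predicted_index(model, image)
  } else NA
  .attack_result(image, adv, adv - image, success)
}

#' DeepFool attack
#'
#' Iteratively moves the image to the nearest decision boundary of the
#' classifier linearized at the current point (one-vs-all scheme over all
#' classes), stopping as soon as the predicted label changes or `max_iter`
#' is reached. The accumulated perturbation is finally scaled by
#' `(1 + overshoot)` to step just across the boundary. On an affine
#' classifier one iteration is exact: the returned perturbation equals the
#' analytic projection onto the nearest class boundary.
#'
#' @param model classifier implementing [predict_scores()] and
#'   [score_gradient()].
#' @param image image array in `[0, 1]`.
#' @param max_iter iteration cap; if exhausted the result is returned with
#'   `success = FALSE`.
#' @param overshoot final perturbation scaling.
#' @return an `attack_result`; `perturbation` is the unclipped
#'   `(1 + overshoot)`-scaled minimal perturbation, `adversarial` its
#'   clipped application.
#' @export
deepfool <- function(model, image, max_iter = 50L, overshoot = 0.02) {
  stopifnot(max_iter >= 1L, overshoot >= 0)
  k0 <- .predicted_index(model, image)
  K <- length(predict_scores(model, image)[1, ])
  r_total <- 0 * image
  iters <- 0L
  for (it in seq_len(max_iter)) {
    # the candidate adversarial point carries the overshoot; the
    # linearization point does not (standard DeepFool bookkeeping)
    x_adv <- image + (1 + overshoot) * r_total
    if (it > 1L && .predicted_index(model, x_adv) != k0) break
    x <- image + r_total
    sc <- predict_scores(model, x)[1, ]
    grads <- score_gradients_all(model, x)
    g0 <- grads[[k0]]
    best <- NULL
    for (k in seq_len(K)) {
      if (k == k0) next
      wk <- grads[[k]] - g0
      fk <- sc[k] - sc[k0]
      nw <- sqrt(sum(wk^2))
      if (nw < 1e-12) next
      dist <- abs(fk) / nw
      if (is.null(best) || dist < best$dist) {
        best <- list(dist = dist, wk = wk, fk = fk, nw = nw)
      }
    }
    if (is.null(best)) break
    iters <- it
    # projection onto the linearized boundary of the closest class
    r_total <- r_total + (abs(best$fk) / best$nw^2) * best$wk
  }
  pert <- (1 + overshoot) * r_total
  adv <- clip01(image + pert)
  success <- .predicted_index(model, adv) != k0
  .attack_result(image, adv, pert, success, iters)
}

#' Attack every image of a dataset
#'
#' Applies the attack described by `spec` to each row; original labels and
#' splits are retained and provenance is set to the attack kind. Speckle
#' noise uses a per-image RNG substream derived from `(spec$seed, row)`, so
#' results do not depend on processing order.
#'
#' @param model classifier under attack.
#' @param data dataset tibble.
#' @param spec an [attack_spec()].
#' @return dataset tibble of adversarial images.
#' @export
attack_dataset <- function(model, data, spec) {
  validate_dataset(data)
  if (nrow(data) == 0L) stop("dataset is empty", call. = FALSE)
  out <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    res <- tryCatch(
      switch(spec$kind,
             fgsm = fgsm(model, data$image[[i]], data$label[i],
                         spec$epsilon),
             speckle = speckle(data$image[[i]], spec$s,
                               seed = (spec$seed * 1000003L + i) %%
                                 2147483647L),
             deepfool = deepfool(model, data$image[[i]], spec$max_iter,
                                 spec$overshoot)),
      error = function(e) {
        stop("attack failed on item ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
    out[[i]] <- res$adversarial
  }
  tibble::tibble(image = out, label = data$label, split = data$split,
                 provenance = spec$kind, id = data$id)
}
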