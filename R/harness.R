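# Adversarial-training harness: regime dataset construction, training
# sessions, cross-testing matrices and the defense summary. Attacked pools
# are generated once against the clean-trained model (static adversarial
# training) and built strictly from the train split.

#' Adversarial-training regime
#'
#' The four canonical regimes mix the clean training images with attacked
#' copies in fixed proportions per class: AT1 (half original, half FGSM),
#' AT2 (half original, half speckle), AT3 (half original, half DeepFool)
#' and MAT (equal quarters of original, FGSM, speckle and DeepFool).
#'
#' @param name `"AT1"`, `"AT2"`, `"AT3"`, `"MAT"`, or a custom name when
#'   `composition` is given.
#' @param composition optional named numeric vector of provenance
#'   fractions summing to 1 (overrides the canonical composition).
#' @return a `regime` object.
#' @export
regime <- function(name, composition = NULL) {
  if (is.null(composition)) {
    composition <- switch(name,
      AT1 = c(original = 0.5, fgsm = 0.5),
      AT2 = c(original = 0.5, speckle = 0.5),
      AT3 = c(original = 0.5, deepfool = 0.5),
      MAT = c(original = 0.25, fgsm = 0.25, speckle = 0.25,
              deepfool = 0.25),
      stop("unknown regime ", name, call. = FALSE))
  }
  if (abs(sum(composition) - 1) > 1e-8) {
    stop("composition fractions must sum to 1", call. = FALSE)
  }
  structure(list(name = name, composition = composition), class = "regime")
}

# Largest-remainder integer allocation of n items to fractions f.
.allocate <- function(n, f) {
  raw <- n * f
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Build the training dataset of a regime
#'
#' Per class, samples the composition fractions without replacement from
#' the original train split and from the attacked pools, so that the total
#' per-class count equals the original per-class train count. The
#' degenerate composition `c(original = 1)` returns the train split
#' unchanged (same row order), making a regime session bit-reproducible
#' against plain training.
#'
#' @param original dataset tibble; its `train` split is the clean pool.
#' @param attacked named list of dataset tibbles keyed by provenance
#'   (`fgsm`, `speckle`, `deepfool`), typically [attack_dataset()] outputs
#'   on the train split.
#' @param regime a [regime()].
#' @param seed integer seed for the per-class sampling.
#' @return dataset tibble with the regime's mixture, all `split = "train"`.
#' @export
build_regime_dataset <- function(original, attacked, regime, seed = 1L) {
  tr <- original[original$split == "train", ]
  comp <- regime$composition
  if (identical(names(comp), "original") && comp[["original"]] == 1) {
    return(tr)
  }
  pools <- c(list(original = tr), attacked)
  missing <- setdiff(names(comp), names(pools))
  if (length(missing)) {
    stop("no attacked pool for provenance ", missing[1], call. = FALSE)
  }
  classes <- sort(unique(tr$label))
  withr::with_seed(as.integer(seed), {
    parts <- list()
    for (cl in classes) {
      n_cl <- sum(tr$label == cl)
      counts <- .allocate(n_cl, comp)
      for (j in seq_along(comp)) {
        pv <- names(comp)[j]
        pool <- pools[[pv]]
        pool <- pool[pool$label == cl & pool$split == "train", ]
        if (nrow(pool) < counts[j]) {
          stop("pool '", pv, "' has ", nrow(pool), " items of class ", cl,
               " but the regime needs ", counts[j], call. = FALSE)
        }
        take <- pool[sample.int(nrow(pool), counts[j]), ]
        parts[[length(parts) + 1L]] <- take
      }
    }
    dplyr::bind_rows(parts)
  })
}

#' Run one adversarial-training session
#'
#' Generates the attacked pools required by the regime from the train
#' split, attacking the clean-trained model; builds the regime mixture;
#' and trains a new model from scratch with the same configuration.
#'
#' @param regime a [regime()].
#' @param data full dataset tibble (train and test splits).
#' @param clean_model the model trained on the clean train split; attacks
#'   are generated against it.
#' @param attack_specs named list of [attack_spec()]s keyed by provenance.
#' @param config [train_config()] for the retraining.
#' @param attacked_train optional precomputed attacked train pools (named
#'   list), to avoid regenerating them across regimes.
#' @param seed sampling seed for the regime mixture.
#' @return list with elements `model`, `train_data`, `regime`.
#' @export
run_session <- function(regime, data, clean_model, attack_specs,
                        config = train_config(), attacked_train = NULL,
                        seed = 1L) {
  tr <- data[data$split == "train", ]
  need <- setdiff(names(regime$composition), "original")
  if (is.null(attacked_train)) attacked_train <- list()
  for (kind in need) {
    if (is.null(attacked_train[[kind]])) {
      spec <- attack_specs[[kind]]
      if (is.null(spec)) {
        stop("no attack spec for provenance ", kind, call. = FALSE)
      }
      attacked_train[[kind]] <- attack_dataset(clean_model, tr, spec)
    }
  }
  mix <- build_regime_dataset(data, attacked_train, regime, seed)
  model <- train_classifier(mix, config)
  list(model = model, train_data = mix, regime = regime,
       attacked_train = attacked_train)
}

#' Cross-test a model against clean and attacked test sets
#'
#' For every (true class, attack) cell: the majority predicted label and
#' the mean predicted-probability mass per class (as percentages, the
#' cross-testing matrix shape), plus a per-test-set summary of
#' correct-label percentages covering the clean set and each attack.
#'
#' @param model classifier to test.
#' @param clean_test dataset tibble (the clean test split).
#' @param attacked_tests named list of attacked test sets keyed by attack.
#' @return a `robustness_report`: list with `cells` and `summary` tibbles.
#' @export
cross_test_matrix <- function(model, clean_test, attacked_tests) {
  classes <- model$classes
  cells <- list()
  for (kind in names(attacked_tests)) {
    ds <- attacked_tests[[kind]]
    for (cl in sort(unique(clean_test$label))) {
      sub <- ds[ds$label == cl, ]
      if (nrow(sub) == 0L) {
        warning("no images of class ", cl, " in attacked set ", kind)
        next
      }
      prob <- predict(model, sub, type = "prob")
      pred <- classes[max.col(prob, ties.method = "first")]
      maj <- names(sort(table(pred), decreasing = TRUE))[1]
      pct <- 100 * colMeans(prob)
      row <- tibble::tibble(label = cl, attack = kind,
                            predicted = maj)
      for (k in seq_along(classes)) {
        row[[paste0("pct_", classes[k])]] <- pct[k]
      }
      cells[[length(cells) + 1L]] <- row
    }
  }
  sets <- c(list(original = clean_test), attacked_tests)
  summary <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    ds <- sets[[nm]]
    tibble::tibble(test = nm,
                   n = nrow(ds),
                   correct_pct = 100 * mean(predict(model, ds) == ds$label))
  }))
  structure(list(cells = dplyr::bind_rows(cells), summary = summary),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  print(x$cells)
  print(x$summary)
  invisible(x)
}

#' @export
tidy.robustness_report <- function(x, ...) x$cells

#' @export
glance.robustness_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("test", "correct_pct")],
                     names_from = "test", values_from = "correct_pct")
}

#' Heatmap of a cross-testing matrix
#'
#' @param object a `robustness_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.robustness_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$cells,
                           dplyr::starts_with("pct_"),
                           names_to = "assigned", values_to = "pct")
  d$assigned <- sub("^pct_", "", d$assigned)
  ggplot2::ggplot(d, ggplot2::aes(.data$assigned, .data$label,
                                  fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", .data$pct)), size = 3) +
    ggplot2::facet_wrap(~ .data$attack) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "probability mass assigned to", y = "true class",
                  fill = "%") +
    ggplot2::theme_minimal()
}

#' Summarize defenses across training sessions
#'
#' One row per (training regime, test composition) with the correct-label
#' percentage -- the defense summary table.
#'
#' @param sessions named list of fitted models (the name is the training
#'   dataset description).
#' @param test_sets named list of dataset tibbles (the name is the testing
#'   dataset description).
#' @param pairs optional 2-column data frame (`training`, `testing`)
#'   restricting which combinations are reported; default is all.
#' @return tibble with columns `training`, `testing`, `correct_pct`.
#' @export
summarize_defense <- function(sessions, test_sets, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- expand.grid(training = names(sessions),
                         testing = names(test_sets),
                         stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    m <- sessions[[pairs$training[i]]]
    ds <- test_sets[[pairs$testing[i]]]
    tibble::tibble(training = pairs$training[i],
                   testing = pairs$testing[i],
                   correct_pct = 100 * mean(predict(m, ds) == ds$label))
  })
  dplyr::bind_rows(out)
}

#' Run the full attack-and-defense study
#'
#' The end-to-end pipeline at desk scale: generate (or accept) a labelled
#' dataset, train the clean model, craft FGSM / speckle / DeepFool attacks
#' on both splits against it, retrain under the requested regimes, and
#' assemble the cross-testing matrices and the defense summary.
#'
#' @param data dataset tibble; when `NULL` one is generated from
#'   `per_class`, `params` and `seed`.
#' @param per_class images per grade for the generated dataset.
#' @param params [synth_params()] for the generator.
#' @param config [train_config()]; its seed is re-derived from `seed`.
#' @param attack_specs named list of [attack_spec()]s.
#' @param regimes character vector of regime names to run.
#' @param seed master seed: controls generation, training and sampling.
#' @param test_frac test fraction for the generated dataset.
#' @return a `retfuse_study` object.
#' @export
run_study <- function(data = NULL, per_class = 150L,
                      params = synth_params(),
                      config = train_config(),
                      attack_specs = list(
                        fgsm = attack_spec("fgsm"),
                        speckle = attack_spec("speckle"),
                        deepfool = attack_spec("deepfool")),
                      regimes = c("AT1", "AT2", "AT3", "MAT"),
                      seed = 1L, test_frac = 1 / 3) {
  seed <- as.integer(seed)
  config$seed <- seed
  if (is.null(data)) {
    data <- generate_dataset(per_class, params, seed = seed,
                             test_frac = test_frac)
  }
  tr <- data[data$split == "train", ]
  te <- data[data$split == "test", ]

  clean_model <- train_classifier(data, config)

  for (k in names(attack_specs)) attack_specs[[k]]$seed <- seed
  attacked_test <- lapply(attack_specs, function(sp) {
    attack_dataset(clean_model, te, sp)
  })
  names(attacked_test) <- names(attack_specs)

  attacked_train <- NULL
  models <- list(clean = clean_model)
  tables <- list(clean = cross_test_matrix(clean_model, te, attacked_test))
  for (rg in regimes) {
    ses <- run_session(regime(rg), data, clean_model, attack_specs,
                       config, attacked_train, seed = seed)
    attacked_train <- ses$attacked_train
    models[[rg]] <- ses$model
    tables[[rg]] <- cross_test_matrix(ses$model, te, attacked_test)
  }

  # test compositions: each regime is summarized against the mixture of
  # clean test images and its own attacks; MAT and the criterion use the
  # full four-way mixture
  mixed_full <- dplyr::bind_rows(c(list(te), unname(attacked_test)))
  test_sets <- list(original = te,
                    fgsm = attacked_test$fgsm,
                    speckle = attacked_test$speckle,
                    deepfool = attacked_test$deepfool,
                    `original+fgsm` = dplyr::bind_rows(te,
                                                       attacked_test$fgsm),
                    `original+speckle` = dplyr::bind_rows(
                      te, attacked_test$speckle),
                    `original+deepfool` = dplyr::bind_rows(
                      te, attacked_test$deepfool),
                    mixed = mixed_full)
  pairs <- rbind(
    data.frame(training = "clean",
               testing = c("original", "fgsm", "speckle", "deepfool")),
    if ("AT1" %in% regimes) data.frame(training = "AT1",
                                       testing = "original+fgsm"),
    if ("AT2" %in% regimes) data.frame(training = "AT2",
                                       testing = "original+speckle"),
    if ("AT3" %in% regimes) data.frame(training = "AT3",
                                       testing = "original+deepfool"),
    if ("MAT" %in% regimes) data.frame(training = "MAT",
                                       testing = "mixed"))
  summary <- summarize_defense(models, test_sets, pairs)
  mixed_rates <- summarize_defense(
    models, test_sets["mixed"],
    data.frame(training = names(models), testing = "mixed"))

  structure(list(data = data, clean_model = clean_model,
                 attacked_test = attacked_test,
                 attacked_train = attacked_train,
                 models = models, tables = tables,
                 summary = summary, mixed_rates = mixed_rates,
                 config = config, attack_specs = attack_specs,
                 seed = seed),
            class = "retfuse_study")
}

#' @export
print.retfuse_study <- function(x, ...) {
  cat("<retfuse_study> seed", x$seed, "-",
      nrow(x$data), "images,", length(x$models), "models\n")
  print(x$summary)
  invisible(x)
}

#' @export
glance.retfuse_study <- function(x, ...) {
  clean <- x$tables$clean$summary
  tibble::tibble(
    seed = x$seed,
    clean_test_acc = clean$correct_pct[clean$test == "original"] / 100,
    fgsm_acc = clean$correct_pct[clean$test == "fgsm"] / 100,
    mat_mixed_acc = if ("MAT" %in% names(x$models)) {
      x$mixed_rates$correct_pct[x$mixed_rates$training == "MAT"] / 100
    } else NA_real_,
    clean_mixed_acc =
      x$mixed_rates$correct_pct[x$mixed_rates$training == "clean"] / 100)
}

#' Feature-fusion defense benchmark on a study
#'
#' Fits the three fusion classifiers (deep-only, handcrafted-only, fused)
#' on clean train-split features and evaluates each on the clean test
#' split (the headline fusion comparison) and, as a secondary diagnostic,
#' on the mixed test set (clean plus all attacked test images).
#'
#' @param study a `retfuse_study`.
#' @param kind classifier back-end (see [fit_fusion_classifier()]).
#' @param seed integer seed.
#' @return list with an `accuracies` tibble (one row per feature set and
#'   test composition) and the clean-test `retfuse_eval`s.
#' @export
run_fusion_benchmark <- function(study, kind = "ensemble", seed = 1L) {
  tr <- study$data[study$data$split == "train", ]
  te <- study$data[study$data$split == "test", ]
  mixed <- dplyr::bind_rows(c(list(te), unname(study$attacked_test)))
  n_clean <- nrow(te)

  hand_tr <- handcrafted_features(tr)
  hand_te <- handcrafted_features(mixed)
  deep_tr <- deep_feature_matrix(study$clean_model, tr)
  deep_te <- deep_feature_matrix(study$clean_model, mixed)

  sv <- function(x) as.matrix(dplyr::select(x, dplyr::starts_with("Sv_")))
  tv <- function(x) as.matrix(dplyr::select(x, dplyr::starts_with("Tv_")))
  uv <- function(x) as.matrix(dplyr::select(x, dplyr::starts_with("Uv_")))

  f_tr <- fuse(Sv = sv(hand_tr), Tv = tv(hand_tr), Uv = uv(hand_tr),
               xv = as.matrix(deep_tr))
  f_te <- fuse(Sv = sv(hand_te), Tv = tv(hand_te), Uv = uv(hand_te),
               xv = as.matrix(deep_te), stats = f_tr$stats)
  h_tr <- fuse(Sv = sv(hand_tr), Tv = tv(hand_tr), Uv = uv(hand_tr))
  h_te <- fuse(Sv = sv(hand_te), Tv = tv(hand_te), Uv = uv(hand_te),
               stats = h_tr$stats)
  d_tr <- fuse(xv = as.matrix(deep_tr))
  d_te <- fuse(xv = as.matrix(deep_te), stats = d_tr$stats)

  evals <- list()
  accs <- list()
  sets <- list(deep = list(d_tr, d_te),
               handcrafted = list(h_tr, h_te),
               fused = list(f_tr, f_te))
  clean_rows <- seq_len(n_clean)
  for (nm in names(sets)) {
    clf <- fit_fusion_classifier(sets[[nm]][[1]]$values, tr$label,
                                 kind = kind, seed = seed)
    x_te <- sets[[nm]][[2]]$values
    ev_clean <- evaluate_classifier(clf, x_te[clean_rows, , drop = FALSE],
                                    te$label)
    pred_mixed <- predict(clf, x_te)
    evals[[nm]] <- ev_clean
    accs[[nm]] <- tibble::tibble(
      features = nm, classifier = kind,
      test = c("clean", "mixed"),
      accuracy = c(ev_clean$accuracy, mean(pred_mixed == mixed$label)))
  }
  list(accuracies = dplyr::bind_rows(accs), evals = evals)
}
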