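# Regime construction, cross-testing and the defense summary.

make_pools <- function(n_per_class = 20) {
  d <- small_data()
  tr <- d[d$split == "train", ]
  fake_attack <- function(kind) {
    out <- tr
    out$provenance <- kind
    out
  }
  list(data = d,
       attacked = list(fgsm = fake_attack("fgsm"),
                       speckle = fake_attack("speckle"),
                       deepfool = fake_attack("deepfool")))
}

test_that("regime compositions are the canonical mixtures", {
  expect_equal(sum(regime("AT1")$composition), 1)
  expect_equal(regime("AT2")$composition[["speckle"]], 0.5)
  expect_equal(unname(regime("MAT")$composition),
               rep(0.25, 4))
  expect_error(regime("ATX"), "unknown")
  expect_error(regime("bad", c(original = 0.7)), "sum to 1")
})

test_that("build_regime_dataset draws exact per-class counts", {
  p <- make_pools()
  tr <- p$data[p$data$split == "train", ]
  mix <- build_regime_dataset(p$data, p$attacked, regime("AT1"), seed = 5)
  expect_identical(nrow(mix), nrow(tr))
  tab <- table(mix$label, mix$provenance)
  for (cl in rownames(tab)) {
    n_cl <- sum(tr$label == cl)
    expect_identical(as.integer(tab[cl, "original"]), n_cl %/% 2L)
    expect_identical(as.integer(tab[cl, "fgsm"]), n_cl - n_cl %/% 2L)
  }
  mat <- build_regime_dataset(p$data, p$attacked, regime("MAT"), seed = 5)
  tabm <- table(mat$label, mat$provenance)
  expect_identical(ncol(tabm), 4L)
  expect_true(max(tabm) - min(tabm) <= 1)   # equal quarters per class
})

test_that("the identity regime returns the train split unchanged and a
           session on it reproduces plain training", {
  p <- make_pools()
  tr <- p$data[p$data$split == "train", ]
  ident <- regime("plain", composition = c(original = 1))
  expect_identical(build_regime_dataset(p$data, list(), ident, 1), tr)
  ses <- run_session(ident, p$data, small_model(), list(),
                     config = small_config())
  te <- p$data[p$data$split == "test", ]
  expect_identical(predict(ses$model, te), predict(small_model(), te))
  expect_identical(ses$model$net$head$W, small_model()$net$head$W)
})

test_that("insufficient pools are reported by name", {
  p <- make_pools()
  short <- p$attacked
  short$fgsm <- short$fgsm[1:3, ]
  expect_error(
    build_regime_dataset(p$data, short, regime("AT1"), 1),
    "fgsm")
  expect_error(
    build_regime_dataset(p$data, list(), regime("AT1"), 1),
    "no attacked pool")
})

test_that("regime datasets never contain test images (no leakage)", {
  p <- make_pools()
  te <- p$data[p$data$split == "test", ]
  for (rg in c("AT1", "MAT")) {
    mix <- build_regime_dataset(p$data, p$attacked, regime(rg), seed = 2)
    expect_length(intersect(mix$id, te$id), 0L)
    expect_true(all(mix$split == "train"))
  }
})

test_that("cross_test_matrix rows are normalized and reflect a perfect
           model as 100% correct", {
  d <- small_data()
  te <- d[d$split == "test", ]
  atk <- list(fgsm = dplyr::mutate(te, provenance = "fgsm"))
  # stub model that always assigns all mass to the true... the stub
  # cannot see truth, so use one that assigns fixed mass by label order
  rep_model <- small_model()
  rep_ <- cross_test_matrix(rep_model, te, atk)
  pcts <- as.matrix(rep_$cells[, grep("^pct_", names(rep_$cells))])
  expect_true(all(abs(rowSums(pcts) - 100) < 0.5))
  expect_identical(nrow(rep_$cells), 3L)
  expect_identical(sort(rep_$summary$test), sort(c("original", "fgsm")))
  # the clean test is the attacked set here, so its summary rows agree
  expect_equal(rep_$summary$correct_pct[1], rep_$summary$correct_pct[2])
  # glance/tidy surface
  expect_identical(nrow(tidy(rep_)), 3L)
  expect_true(all(c("original", "fgsm") %in% names(glance(rep_))))
})

test_that("summarize_defense reports one row per requested pair", {
  d <- small_data()
  te <- d[d$split == "test", ]
  models <- list(clean = small_model())
  sets <- list(original = te)
  s <- summarize_defense(models, sets)
  expect_identical(nrow(s), 1L)
  expect_true(s$correct_pct >= 0 && s$correct_pct <= 100)
  s2 <- summarize_defense(list(a = small_model(), b = small_model()),
                          list(x = te, y = te))
  expect_identical(nrow(s2), 4L)
})

test_that("a miniature end-to-end study holds its structural
           invariants", {
  st <- run_study(per_class = 12, params = synth_params(image_size = 32),
                  config = train_config(epochs = 2, seed = 1),
                  attack_specs = list(
                    fgsm = attack_spec("fgsm", epsilon = 0.05),
                    speckle = attack_spec("speckle", s = 0.3),
                    deepfool = attack_spec("deepfool", max_iter = 10)),
                  regimes = "MAT", seed = 3, test_frac = 1 / 3)
  te <- st$data[st$data$split == "test", ]
  # no leakage into the MAT training mixture
  expect_length(intersect(unique(te$id),
                          unique(st$attacked_train$fgsm$id)), 0L)
  # attacked test sets mirror the clean test set
  for (kind in names(st$attacked_test)) {
    expect_identical(nrow(st$attacked_test[[kind]]), nrow(te))
    expect_identical(st$attacked_test[[kind]]$label, te$label)
    expect_true(all(st$attacked_test[[kind]]$provenance == kind))
  }
  # summary covers the clean rows and the MAT row
  expect_true(all(c("clean", "MAT") %in% st$summary$training))
  expect_true(all(st$summary$correct_pct >= 0 &
                    st$summary$correct_pct <= 100))
  expect_identical(nrow(st$mixed_rates), 2L)
})
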