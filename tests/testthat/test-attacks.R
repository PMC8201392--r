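# Attack operators against closed-form oracles on affine classifiers and
# contract checks on the trained surrogate.

test_that("fgsm respects the identity and l-infinity contracts", {
  m <- small_model()
  img <- small_data()$image[[1]]
  lab <- small_data()$label[1]
  r0 <- fgsm(m, img, lab, epsilon = 0)
  expect_identical(r0$adversarial, img)
  for (eps in c(0.01, 0.05, 0.2)) {
    r <- fgsm(m, img, lab, epsilon = eps)
    expect_lte(max(abs(r$adversarial - img)), eps + 1e-12)
    expect_true(all(r$adversarial >= 0 & r$adversarial <= 1))
  }
})

test_that("fgsm matches the analytic gradient on a linear-softmax model
           and increases its loss", {
  set.seed(42)
  D <- 12
  W <- matrix(rnorm(2 * D), 2, D)
  b <- c(0.3, -0.1)
  mod <- affine_classifier(W, b)
  x <- runif(D) * 0.6 + 0.2
  # hand computation: grad = t(W) %*% (softmax(Wx+b) - onehot)
  z <- as.numeric(W %*% x + b)
  p <- exp(z - max(z)); p <- p / sum(p)
  e <- p; e[1] <- e[1] - 1
  ghand <- as.numeric(crossprod(W, e))
  eps <- 0.01
  r <- fgsm(mod, x, 1L, epsilon = eps)
  expect_equal(as.numeric(r$adversarial),
               pmin(pmax(x + eps * sign(ghand), 0), 1), tolerance = 1e-12)
  loss <- function(v) {
    z <- as.numeric(W %*% v + b); -(z[1] - log(sum(exp(z))))
  }
  expect_gt(loss(as.numeric(r$adversarial)), loss(x))
})

test_that("speckle noise obeys the identity, default and moment
           contracts", {
  img <- random_image(32, 5)
  r <- speckle(img, s = 0)
  expect_identical(r$adversarial, img)
  # omitted s uses the 0.5 default
  expect_equal(speckle(img, seed = 9)$adversarial,
               speckle(img, s = 0.5, seed = 9)$adversarial)
  expect_error(speckle(img, s = 1.5), "\\[0, 1\\]")
  # moments at s = 0.04 on a mid-gray image (no clipping): mean 0.5,
  # variance s * 0.5^2
  s <- 0.04
  big <- array(0.5, c(100, 100, 3))
  out <- speckle(big, s = s, seed = 31)$adversarial
  n <- length(out)
  se <- sqrt(s * 0.25 / n)
  expect_lt(abs(mean(out) - 0.5), 4 * se)
  expect_lt(abs(stats::var(as.vector(out)) - s * 0.25), 0.05 * s * 0.25)
})

test_that("speckle uses order-independent per-image substreams in
           attack_dataset", {
  d <- small_data()[1:6, ]
  sp <- attack_spec("speckle", s = 0.3, seed = 7)
  full <- attack_dataset(small_model(), d, sp)
  head3 <- attack_dataset(small_model(), d[1:3, ], sp)
  expect_equal(full$image[1:3], head3$image)
})

test_that("deepfool equals the hyperplane closed form on binary affine
           classifiers", {
  set.seed(7)
  for (rep in 1:10) {
    D <- sample(5:40, 1)
    W <- matrix(rnorm(2 * D), 2, D)
    b <- rnorm(2)
    mod <- affine_classifier(W, b)
    x <- runif(D)
    k0 <- which.max(as.numeric(W %*% x + b))
    other <- 3L - k0
    w <- W[other, ] - W[k0, ]
    f <- sum(w * x) + b[other] - b[k0]   # negative at x
    overshoot <- 0.02
    closed <- (1 + overshoot) * (-f) * w / sum(w^2)
    r <- deepfool(mod, x, max_iter = 10, overshoot = overshoot)
    expect_lt(max(abs(as.numeric(r$perturbation) - closed)) /
                max(abs(closed)), 1e-6)
    expect_identical(r$iterations_used, 1L)
  }
})

test_that("deepfool picks the analytically nearest one-vs-all boundary", {
  set.seed(13)
  for (rep in 1:5) {
    D <- 9
    # orthogonal weight rows with distinct norms
    W <- matrix(0, 3, D)
    W[1, 1] <- runif(1, 0.5, 2)
    W[2, 2] <- runif(1, 0.5, 2)
    W[3, 3] <- runif(1, 0.5, 2)
    b <- rnorm(3, sd = 0.1)
    x <- runif(D)
    mod <- affine_classifier(W, b)
    sc <- as.numeric(W %*% x + b)
    k0 <- which.max(sc)
    cands <- setdiff(1:3, k0)
    dists <- vapply(cands, function(k) {
      w <- W[k, ] - W[k0, ]
      abs(sc[k] - sc[k0]) / sqrt(sum(w^2))
    }, numeric(1))
    nearest <- cands[which.min(dists)]
    r <- deepfool(mod, x, max_iter = 10, overshoot = 0.02)
    # the step is along the nearest boundary's normal
    w_near <- W[nearest, ] - W[k0, ]
    cosang <- sum(r$perturbation * w_near) /
      sqrt(sum(r$perturbation^2) * sum(w_near^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
    # and the new label is the nearest class
    if (r$success) {
      expect_identical(
        unname(which.max(predict_scores(mod, r$adversarial)[1, ])),
        nearest)
    }
  }
})

test_that("deepfool success implies a changed label, and its l2 norm is
           below fgsm's at equal success on affine classifiers", {
  set.seed(23)
  for (rep in 1:8) {
    mod <- random_affine(K = 3, D = 20, seed = rep * 17)
    x <- runif(20)
    rdf <- deepfool(mod, x, max_iter = 30)
    k0 <- which.max(predict_scores(mod, x)[1, ])
    if (rdf$success) {
      expect_true(which.max(predict_scores(mod, rdf$adversarial)[1, ])
                  != k0)
      # find the smallest fgsm epsilon (grid) that also flips the label
      flip_eps <- NA
      for (eps in seq(0.005, 0.5, by = 0.005)) {
        rf <- fgsm(mod, x, k0, epsilon = eps)
        if (rf$success) { flip_eps <- eps; break }
      }
      if (!is.na(flip_eps)) {
        rf <- fgsm(mod, x, k0, epsilon = flip_eps)
        expect_lte(sqrt(sum(rdf$perturbation^2)),
                   sqrt(sum(rf$perturbation^2)) + 1e-9)
      }
    }
  }
})

test_that("attack_dataset preserves size, labels and ids and sets
           provenance", {
  d <- small_data()[1:8, ]
  m <- small_model()
  out <- attack_dataset(m, d, attack_spec("fgsm", epsilon = 0.03))
  expect_identical(nrow(out), nrow(d))
  expect_identical(out$label, d$label)
  expect_identical(out$id, d$id)
  expect_true(all(out$provenance == "fgsm"))
  # epsilon 0: images unchanged, only provenance differs
  out0 <- attack_dataset(m, d, attack_spec("fgsm", epsilon = 0))
  expect_identical(out0$image, d$image)
})

test_that("attacked test images are misclassified at least as often as
           clean ones", {
  m <- small_model()
  te <- small_data()[small_data()$split == "test", ]
  clean_err <- mean(predict(m, te) != te$label)
  adv <- attack_dataset(m, te, attack_spec("fgsm", epsilon = 0.05))
  adv_err <- mean(predict(m, adv) != adv$label)
  expect_gte(adv_err, clean_err)
})
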