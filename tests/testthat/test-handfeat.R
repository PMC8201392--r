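# Handcrafted descriptors against hand computations and brute-force
# oracles.

test_that("lbp_code matches hand evaluation of the threshold rule", {
  # equal neighbors: the >= tie rule sets every bit
  expect_identical(lbp_code(matrix(5, 3, 3)), 255L)
  # all neighbors strictly below the centre
  p <- matrix(1, 3, 3); p[2, 2] <- 9
  expect_identical(lbp_code(p), 0L)
  # clockwise-from-top-left neighbors (6,5,2,1,7,8,9,3) around centre 5:
  # bits (1,1,0,0,1,1,1,0) -> 1 + 2 + 16 + 32 + 64 = 115
  p <- matrix(0, 3, 3)
  p[2, 2] <- 5
  p[1, 1] <- 6; p[1, 2] <- 5; p[1, 3] <- 2; p[2, 3] <- 1
  p[3, 3] <- 7; p[3, 2] <- 8; p[3, 1] <- 9; p[2, 1] <- 3
  expect_identical(lbp_code(p), 115L)
})

test_that("lbp_features is a normalized histogram consistent with a
           brute-force recomputation", {
  set.seed(11)
  for (rep in 1:5) {
    g <- matrix(runif(15 * 12), 15, 12)
    u <- lbp_features(g)
    expect_length(u, 256L)
    expect_equal(sum(u), 1, tolerance = 1e-9)
    # brute force: loop pixels, call the single-patch kernel
    counts <- integer(256)
    for (i in 2:(nrow(g) - 1)) {
      for (j in 2:(ncol(g) - 1)) {
        code <- lbp_code(g[(i - 1):(i + 1), (j - 1):(j + 1)])
        counts[code + 1L] <- counts[code + 1L] + 1L
      }
    }
    expect_equal(unname(u), counts / sum(counts))
  }
  # constant image: ties put every pixel at code 255
  u <- lbp_features(matrix(0.4, 8, 8))
  expect_equal(unname(u[256]), 1)
  expect_error(lbp_features(matrix(0, 2, 5)), "3x3")
})

test_that("lbp histogram is invariant under 180-degree rotation of a
           symmetric pattern", {
  set.seed(3)
  g <- matrix(runif(64), 8, 8)
  g <- (g + img_rotate(g, 180)) / 2   # make the pattern 180-symmetric
  expect_equal(lbp_features(g), lbp_features(img_rotate(g, 180)))
})

test_that("hog_features matches hand evaluation on degenerate inputs", {
  # constant image: zero gradients, zero-norm guard keeps the vector zero
  h <- hog_features(matrix(0.7, 32, 32))
  expect_true(all(h == 0))
  expect_false(anyNA(h))
  # vertical step edge: gradient purely horizontal, so all mass falls in
  # the first (0-degree) orientation bin of each cell histogram
  g <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  h <- hog_features(g)
  m <- matrix(h, nrow = 9)   # bins x (cells-in-blocks * blocks)
  expect_true(sum(m[2:9, ]) == 0)
  expect_true(sum(m[1, ]) > 0)
})

test_that("hog_features length follows the dimensional formula", {
  g <- matrix(runif(64 * 64), 64, 64)
  expect_length(hog_features(g, cell = 8, block = 2, bins = 9),
                9 * 4 * 49)       # bins x cells/block x blocks
  expect_length(hog_features(g, cell = 16, block = 2, bins = 6),
                6 * 4 * 9)
  expect_error(hog_features(matrix(0, 8, 8), cell = 8, block = 2),
               "too small")
})

test_that("sfta_thresholds at nt=1 equals exhaustive Otsu search", {
  otsu1 <- function(gray) {
    h <- tabulate(as.integer(gray) + 1L, 256L); p <- h / sum(h)
    mu_t <- sum(p * (0:255))
    best <- -Inf; bt <- NA
    for (t in 0:254) {
      w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
      if (w0 <= 0 || w1 <= 0) next
      m0 <- sum(p[1:(t + 1)] * (0:t)) / w0
      m1 <- (mu_t - w0 * m0) / w1
      v <- w0 * w1 * (m0 - m1)^2
      if (v > best) { best <- v; bt <- t }
    }
    bt
  }
  set.seed(21)
  for (rep in 1:25) {
    g <- matrix(sample(0:255, 144, TRUE, prob = runif(256)^2), 12, 12)
    if (length(unique(as.vector(g))) < 2) next
    expect_identical(sfta_thresholds(g, 1L), otsu1(g))
  }
  expect_error(sfta_thresholds(matrix(7L, 4, 4), 1L), "constant")
})

test_that("sfta_thresholds separates well-separated modes (nt = 2
           brute-force check)", {
  # two-delta histogram: single threshold between the modes
  g2 <- matrix(rep(c(50L, 200L), c(40, 60)), 10, 10)
  t1 <- sfta_thresholds(g2, 1L)
  expect_true(t1 >= 50 && t1 < 200)
  # three-delta histogram: the nt=2 pair equals exhaustive pair search
  g3 <- matrix(rep(c(30L, 120L, 220L), c(30, 40, 30)), 10, 10)
  th <- sfta_thresholds(g3, 2L)
  p <- tabulate(as.vector(g3) + 1L, 256L) / length(g3)
  M <- cumsum(p * (0:255)); P <- cumsum(p)
  seg <- function(a, b) {      # between-class term of levels a..b, 1-based
    w <- P[b] - if (a > 1) P[a - 1] else 0
    m <- M[b] - if (a > 1) M[a - 1] else 0
    if (w > 0) m^2 / w else 0
  }
  best <- -Inf; bp <- NULL
  for (t1 in 0:253) for (t2 in (t1 + 1):254) {
    v <- seg(1, t1 + 1) + seg(t1 + 2, t2 + 1) + seg(t2 + 2, 256)
    if (v > best) { best <- v; bp <- c(t1, t2) }
  }
  expect_identical(as.integer(th), as.integer(bp))
  expect_true(th[1] >= 30 && th[1] < 120 && th[2] >= 120 && th[2] < 220)
})

test_that("ttbd_binaries implements half-open bands exactly", {
  g <- matrix(c(0L, 10L, 20L, 30L), 2, 2)
  b <- ttbd_binaries(g, c(10L, 20L))
  expect_length(b, 4L)
  # band (10, 20]: pixel equal to the lower bound excluded, upper included
  expect_identical(as.vector(b[[1]]), c(FALSE, FALSE, TRUE, FALSE))
  # band (20, 30]
  expect_identical(as.vector(b[[2]]), c(FALSE, FALSE, FALSE, TRUE))
  # binarizations (10, 30] and (20, 30]
  expect_identical(as.vector(b[[3]]), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(as.vector(b[[4]]), c(FALSE, FALSE, FALSE, TRUE))
  # all-zero image with a positive lower threshold
  z <- ttbd_binaries(matrix(0L, 3, 3), c(5L))
  expect_true(all(!z[[1]]) && all(!z[[2]]))
})

test_that("border_image applies the 8-neighbor rule", {
  m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
  b <- border_image(m)
  expect_identical(sum(b), 16L)          # perimeter of a 5x5 square
  expect_true(all(!b[4:6, 4:6]))         # interior cleared
  expect_true(all(b[3, 3:7]))
  # isolated pixel survives; empty map stays empty
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  expect_identical(border_image(one) != 0, one != 0)
  expect_true(all(!border_image(matrix(0, 4, 4))))
  # frame-touching object: out-of-bounds neighbors count as background,
  # so the frame is border while the interior 2x2 is not
  full <- border_image(matrix(1, 4, 4))
  expect_true(all(full[c(1, 4), ]) && all(full[, c(1, 4)]))
  expect_true(all(!full[2:3, 2:3]))
})

test_that("box_counting_dim matches an independent box-count oracle", {
  oracle_dim <- function(map, sizes = c(2L, 4L, 8L, 16L)) {
    pts <- which(map != 0, arr.ind = TRUE)
    if (nrow(pts) == 0) return(0)
    n <- vapply(sizes, function(s) {
      nrow(unique(cbind(ceiling(pts[, 1] / s), ceiling(pts[, 2] / s))))
    }, numeric(1))
    stats::coef(stats::lm(log(n) ~ log(1 / sizes)))[[2]]
  }
  expect_identical(box_counting_dim(matrix(0, 8, 8)), 0)
  one <- matrix(0, 32, 32); one[5, 9] <- 1
  expect_equal(box_counting_dim(one), 0)
  line <- matrix(0, 64, 64); line[32, ] <- 1
  d <- box_counting_dim(line)
  expect_gte(d, 0.9); expect_lte(d, 1.1)
  expect_equal(d, oracle_dim(line), tolerance = 1e-10)
  set.seed(9)
  blob <- matrix(runif(64 * 64) < 0.2, 64, 64)
  expect_equal(box_counting_dim(blob), oracle_dim(blob),
               tolerance = 1e-10)
})

test_that("sfta_features has fixed length and matches a bare-loop
           recomputation on a toy image", {
  # 8x8 two-region image, nt = 1
  g <- matrix(40L, 8, 8); g[3:6, 3:6] <- 200L
  tv <- sfta_features(g, sfta_config(nt = 1L, box_sizes = c(2L, 4L)))
  expect_length(tv, 6L)
  th <- sfta_thresholds(g, 1L)
  expect_true(th >= 40 && th < 200)
  # both binary images equal the bright square here (single threshold)
  sq <- g > th
  brd <- border_image(sq)
  expect_equal(unname(tv[1]), box_counting_dim(brd, c(2L, 4L)))
  expect_equal(unname(tv[2]), 200)      # mean gray of the region
  expect_equal(unname(tv[3]), 16)       # region pixel count
  expect_equal(unname(tv[4:6]), unname(tv[1:3]))
  # content-independent length at the default configuration
  set.seed(4)
  r <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  expect_length(sfta_features(r), 24L)
})

test_that("sfta features are invariant under flips and 90-degree
           rotations", {
  img <- generate_fundus("DR2", synth_params(), seed = 77)
  g <- rgb_to_gray(img, bits = 8)
  tv <- sfta_features(g)
  expect_equal(sfta_features(img_flip_h(g)), tv)
  expect_equal(sfta_features(img_flip_v(g)), tv)
  expect_equal(sfta_features(img_rotate(g, 90)), tv)
  expect_equal(sfta_features(img_rotate(g, 180)), tv)
})

test_that("handcrafted_features assembles named blocks per image", {
  d <- small_data()[1:4, ]
  ft <- handcrafted_features(d)
  expect_identical(nrow(ft), 4L)
  expect_true(any(startsWith(names(ft), "Sv_")))
  expect_true(any(startsWith(names(ft), "Tv_")))
  expect_true(any(startsWith(names(ft), "Uv_")))
  # deterministic
  expect_equal(handcrafted_features(d), ft)
})
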