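# Synthetic fundus-style image generator.
#
# The generator emulates the gross appearance of retinal fundus photographs
# at three diabetic-retinopathy severities: a circular fundus field on a
# dark background, an optic-disc highlight, a branching dark vessel tree,
# bright exudate-like blobs and small dark microaneurysm-like lesions whose
# counts grow with severity. Only the monotone grade-to-lesion-count
# relation is contractual; the geometry is a stylized invention.

#' Parameters of the synthetic fundus generator
#'
#' @param image_size side length in pixels of the generated square image
#'   (default 64, the desk-scale working resolution).
#' @param lesions_per_grade named list mapping each grade to an integer
#'   `c(min, max)` range for the number of dark microaneurysm-like lesions.
#'   Ranges must be non-decreasing from DR1 to DR3.
#' @param bright_per_grade same shape, for bright exudate-like blobs.
#' @param vessel_branches number of primary vessel branches leaving the
#'   optic disc.
#' @param noise_floor standard deviation of the additive pixel noise.
#' @return a `synth_params` list.
#' @export
synth_params <- function(image_size = 64L,
                         lesions_per_grade = list(DR1 = c(1L, 3L),
                                                  DR2 = c(5L, 8L),
                                                  DR3 = c(11L, 16L)),
                         bright_per_grade = list(DR1 = c(0L, 1L),
                                                 DR2 = c(2L, 4L),
                                                 DR3 = c(5L, 8L)),
                         vessel_branches = 5L,
                         noise_floor = 0.02) {
  stopifnot(image_size >= 32L, vessel_branches >= 1L, noise_floor >= 0)
  for (ranges in list(lesions_per_grade, bright_per_grade)) {
    stopifnot(identical(sort(names(ranges)), dr_labels()))
    lo <- vapply(dr_labels(), function(l) ranges[[l]][1], numeric(1))
    hi <- vapply(dr_labels(), function(l) ranges[[l]][2], numeric(1))
    if (any(lo < 0) || any(hi < lo)) {
      stop("lesion count ranges must be non-negative with min <= max",
           call. = FALSE)
    }
    if (is.unsorted(lo) || is.unsorted(hi)) {
      stop("lesion count ranges must be non-decreasing from DR1 to DR3",
           call. = FALSE)
    }
  }
  structure(list(image_size = as.integer(image_size),
                 lesions_per_grade = lesions_per_grade,
                 bright_per_grade = bright_per_grade,
                 vessel_branches = as.integer(vessel_branches),
                 noise_floor = noise_floor),
            class = "synth_params")
}

# Draw a filled disc into channel arrays; returns the pixel index set.
.disc_pixels <- function(S, cr, cc, radius) {
  r0 <- max(1L, floor(cr - radius)); r1 <- min(S, ceiling(cr + radius))
  c0 <- max(1L, floor(cc - radius)); c1 <- min(S, ceiling(cc + radius))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc2 <- rep(c0:c1, each = r1 - r0 + 1L)
  keep <- (rr - cr)^2 + (cc2 - cr * 0 - cc)^2 <= radius^2
  cbind(rr[keep], cc2[keep])
}

#' Generate one synthetic fundus image
#'
#' Deterministic for a fixed `(label, params, seed)` triple. The returned
#' array carries two attributes used by validation code: `lesion_mask`, a
#' logical matrix marking the dark-lesion pixels, and `lesion_count`, the
#' number of lesions drawn. Lesions are placed with a minimum separation so
#' they form distinct connected components in the mask.
#'
#' @param label one of `"DR1"`, `"DR2"`, `"DR3"`.
#' @param params a [synth_params()] object.
#' @param seed integer seed.
#' @return a `size x size x 3` image array in `[0, 1]`.
#' @export
generate_fundus <- function(label, params = synth_params(), seed = 1L) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% dr_labels())) {
    stop("label must be one of ", paste(dr_labels(), collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    S <- params$image_size
    ctr <- (S + 1) / 2
    R <- 0.47 * S
    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)
    d2 <- (rr - ctr)^2 + (cc - ctr)^2
    field <- d2 <= R^2
    shade <- pmax(0, 1 - 0.35 * d2 / R^2)

    base <- c(0.55, 0.30, 0.12) + stats::runif(3, -0.04, 0.04)
    img <- array(0.03, c(S, S, 3L))
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[field] <- (base[ch] * shade)[field]
      img[, , ch] <- pl
    }

    # optic disc: bright ellipse off-centre
    th <- stats::runif(1, 0, 2 * pi)
    od <- c(ctr + 0.55 * R * sin(th), ctr + 0.55 * R * cos(th))
    od_r <- 0.10 * S
    g <- exp(-((rr - od[1])^2 + (cc - od[2])^2) / (2 * (od_r / 1.6)^2))
    od_col <- c(0.95, 0.85, 0.55)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - g * field) +
        od_col[ch] * g * field
    }

    # vessel tree: random walks from the optic disc, darkening the field
    vcol <- c(0.32, 0.10, 0.06)
    vmask <- matrix(FALSE, S, S)
    n_steps <- round(1.2 * S)
    for (b in seq_len(params$vessel_branches)) {
      pos <- od
      dir <- stats::runif(1, 0, 2 * pi)
      branch_at <- sample.int(n_steps, 1L)
      for (s in seq_len(n_steps)) {
        dir <- dir + stats::rnorm(1, 0, 0.25)
        pos <- pos + c(sin(dir), cos(dir))
        pr <- round(pos[1]); pc <- round(pos[2])
        if (pr < 1 || pr > S || pc < 1 || pc > S) break
        if ((pr - ctr)^2 + (pc - ctr)^2 > R^2) break
        vmask[pr, pc] <- TRUE
        if (s == branch_at) {
          # secondary branch
          p2 <- pos; d2v <- dir + stats::runif(1, -1.2, 1.2)
          for (s2 in seq_len(n_steps %/% 2)) {
            d2v <- d2v + stats::rnorm(1, 0, 0.25)
            p2 <- p2 + c(sin(d2v), cos(d2v))
            q1 <- round(p2[1]); q2 <- round(p2[2])
            if (q1 < 1 || q1 > S || q2 < 1 || q2 > S) break
            if ((q1 - ctr)^2 + (q2 - ctr)^2 > R^2) break
            vmask[q1, q2] <- TRUE
          }
        }
      }
    }
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[vmask] <- 0.35 * pl[vmask] + 0.65 * vcol[ch]
      img[, , ch] <- pl
    }

    # bright exudate-like blobs
    brng <- params$bright_per_grade[[label]]
    nb <- if (brng[2] >= brng[1]) {
      sample(seq.int(brng[1], brng[2]), 1L)
    } else 0L
    if (nb > 0) {
      for (k in seq_len(nb)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * 0.8 * R
        pb <- c(ctr + rad * sin(ang), ctr + rad * cos(ang))
        sg <- stats::runif(1, 0.012, 0.022) * S
        gb <- exp(-((rr - pb[1])^2 + (cc - pb[2])^2) / (2 * sg^2))
        bc <- c(0.95, 0.90, 0.40)
        for (ch in 1:3) {
          img[, , ch] <- img[, , ch] * (1 - 0.9 * gb * field) +
            bc[ch] * 0.9 * gb * field
        }
      }
    }

    # dark microaneurysm-like lesions; rejection-placed with a minimum
    # separation so the mask components stay distinct
    lrng <- params$lesions_per_grade[[label]]
    nl <- sample(seq.int(lrng[1], lrng[2]), 1L)
    lmask <- matrix(FALSE, S, S)
    lcol <- c(0.18, 0.05, 0.05)
    # lesion radius grows with severity: microaneurysm-like dots in DR1,
    # hemorrhage-like patches in DR3
    r_unit <- max(2, round(0.03 * S))
    r_rng <- switch(label,
                    DR1 = c(1L, max(1L, r_unit - 1L)),
                    DR2 = c(1L, r_unit),
                    DR3 = c(2L, r_unit + 1L))
    max_r <- r_rng[2]
    centers <- matrix(numeric(0), ncol = 2)
    placed <- 0L
    tries <- 0L
    while (placed < nl && tries < 400L) {
      tries <- tries + 1L
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.82 * R
      pl <- c(ctr + rad * sin(ang), ctr + rad * cos(ang))
      if (nrow(centers) > 0 &&
          min((centers[, 1] - pl[1])^2 + (centers[, 2] - pl[2])^2) <
            (2 * max_r + 3)^2) next
      r_les <- sample(seq.int(r_rng[1], r_rng[2]), 1L)
      px <- .disc_pixels(S, pl[1], pl[2], r_les)
      if (nrow(px) == 0L) next
      centers <- rbind(centers, pl)
      lmask[px] <- TRUE
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[px] <- 0.25 * plane[px] + 0.75 * lcol[ch]
        img[, , ch] <- plane
      }
      placed <- placed + 1L
    }

    if (params$noise_floor > 0) {
      img <- img + array(stats::rnorm(S * S * 3, 0, params$noise_floor),
                         c(S, S, 3L))
    }
    img <- clip01(img)
    attr(img, "lesion_mask") <- lmask
    attr(img, "lesion_count") <- placed
    img
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws `per_class` images per grade and assigns a stratified train/test
#' split. Per-image seeds are derived from `seed` and the image index, so a
#' subset of the data is reproducible independent of generation order.
#'
#' @param per_class images per grade.
#' @param params a [synth_params()] object.
#' @param seed integer seed.
#' @param test_frac fraction of each class assigned to the test split.
#' @return dataset tibble (see [image_dataset()]).
#' @export
generate_dataset <- function(per_class, params = synth_params(), seed = 1L,
                             test_frac = 0.3) {
  stopifnot(per_class >= 1, test_frac >= 0, test_frac < 1)
  seed <- as.integer(seed)
  labels <- rep(dr_labels(), each = per_class)
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    images[[i]] <- generate_fundus(labels[i], params,
                                   seed = (seed * 7919L + i) %% 2147483647L)
  }
  n_test <- round(per_class * test_frac)
  split <- withr::with_seed(seed, {
    unlist(lapply(dr_labels(), function(l) {
      s <- rep("train", per_class)
      s[sample.int(per_class, n_test)] <- "test"
      s
    }))
  })
  ids <- paste0(rep(dr_labels(), each = per_class), "_",
                sprintf("%05d", rep(seq_len(per_class), 3L)))
  image_dataset(images, labels, split, id = ids)
}

#' Horizontal flip (mirror columns)
#' @param img image array or matrix.
#' @return flipped image.
#' @export
img_flip_h <- function(img) {
  if (length(dim(img)) == 3L) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  else img[, rev(seq_len(ncol(img))), drop = FALSE]
}

#' Vertical flip (mirror rows)
#' @param img image array or matrix.
#' @return flipped image.
#' @export
img_flip_v <- function(img) {
  if (length(dim(img)) == 3L) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  else img[rev(seq_len(nrow(img))), , drop = FALSE]
}

#' Exact rotation by a multiple of 90 degrees
#'
#' Pure index permutation (no interpolation), counter-clockwise.
#'
#' @param img image array or matrix.
#' @param angle one of 90, 180, 270.
#' @return rotated image.
#' @export
img_rotate <- function(img, angle) {
  if (!angle %in% c(90, 180, 270)) {
    stop("angle must be 90, 180 or 270", call. = FALSE)
  }
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  apply_plane <- function(f, x) {
    if (length(dim(x)) == 3L) {
      planes <- lapply(1:3, function(ch) f(x[, , ch]))
      array(unlist(planes), c(dim(planes[[1]]), 3L))
    } else f(x)
  }
  k <- angle / 90
  out <- img
  for (i in seq_len(k)) out <- apply_plane(rot1, out)
  out
}

# The augmentation orbit: named list of transform functions.
.aug_transforms <- function(angles = c(90, 180, 270)) {
  tf <- list(flip_h = img_flip_h, flip_v = img_flip_v)
  for (a in angles) {
    tf[[paste0("rot", a)]] <- local({
      aa <- a
      function(img) img_rotate(img, aa)
    })
  }
  tf
}

#' Augment a dataset by flips and exact rotations
#'
#' Grows the dataset to `n_target` items by applying horizontal/vertical
#' flips and rotations from `angles` (index permutations, so every
#' augmented image is exactly a member of the flip/rotation orbit of some
#' original). Per-class proportions are preserved to within one item;
#' labels, split and provenance are inherited from the source image.
#'
#' @param data dataset tibble.
#' @param n_target total number of items after augmentation; must be at
#'   least `nrow(data)`. Equal to `nrow(data)` returns the input unchanged.
#' @param seed integer seed.
#' @param angles rotation angle set (multiples of 90).
#' @return augmented dataset tibble.
#' @export
augment_dataset <- function(data, n_target, seed = 1L,
                            angles = c(90, 180, 270)) {
  validate_dataset(data)
  n0 <- nrow(data)
  if (n_target < n0) {
    stop("n_target (", n_target, ") must be >= dataset size (", n0, ")",
         call. = FALSE)
  }
  if (n_target == n0) return(data)
  tfs <- .aug_transforms(angles)
  extra_total <- n_target - n0
  cls <- unique(data$label)
  n_cls <- table(data$label)[cls]
  # largest-remainder allocation of the extra items across classes
  quota <- extra_total * as.numeric(n_cls) / n0
  extra <- floor(quota)
  rem <- extra_total - sum(extra)
  if (rem > 0) {
    ord <- order(quota - extra, decreasing = TRUE)
    extra[ord[seq_len(rem)]] <- extra[ord[seq_len(rem)]] + 1
  }
  new_rows <- withr::with_seed(as.integer(seed), {
    out <- vector("list", length(cls))
    for (ci in seq_along(cls)) {
      k <- extra[ci]
      if (k == 0) next
      idx <- which(data$label == cls[ci])
      combos <- tidyr::expand_grid(i = idx, t = seq_along(tfs))
      combos <- combos[sample.int(nrow(combos)), ]
      take <- combos[rep_len(seq_len(nrow(combos)), k), ]
      imgs <- purrr::map2(take$i, take$t,
                          function(i, t) tfs[[t]](data$image[[i]]))
      out[[ci]] <- tibble::tibble(image = imgs,
                                  label = data$label[take$i],
                                  split = data$split[take$i],
                                  provenance = data$provenance[take$i],
                                  id = paste0(data$id[take$i], "_aug",
                                              seq_len(k)))
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(data, new_rows)
}
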