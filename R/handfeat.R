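# Handcrafted texture descriptors: local binary patterns (LBP), histogram
# of oriented gradients (HOG) and segmentation-based fractal texture
# analysis (SFTA). All three are deterministic and produce vectors whose
# length depends only on the configuration, never on image content.

# ---------------------------------------------------------------- LBP ----

#' LBP code of a single 3x3 neighborhood
#'
#' Thresholds the 8 neighbors against the centre (`>=` counts as 1, so
#' equal values set the bit) and reads them as a binary number, bit p
#' weighted `2^p` with the neighbors ordered clockwise from the top-left
#' corner.
#'
#' @param patch 3x3 numeric matrix.
#' @return integer code in 0--255.
#' @export
lbp_code <- function(patch) {
  stopifnot(is.matrix(patch), all(dim(patch) == c(3L, 3L)))
  centre <- patch[2, 2]
  # clockwise from top-left: (1,1) (1,2) (1,3) (2,3) (3,3) (3,2) (3,1) (2,1)
  nb <- c(patch[1, 1], patch[1, 2], patch[1, 3], patch[2, 3],
          patch[3, 3], patch[3, 2], patch[3, 1], patch[2, 1])
  sum(as.integer(nb >= centre) * bitwShiftL(1L, 0:7))
}

#' LBP feature vector (Uv)
#'
#' Computes the 8-neighbor LBP code at every interior pixel and returns the
#' normalized 256-bin histogram of codes.
#'
#' @param gray `H x W` numeric matrix (H, W >= 3).
#' @return numeric vector of length 256 summing to 1, named `Uv_0 ... Uv_255`.
#' @export
lbp_features <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  if (H < 3L || W < 3L) stop("image must be at least 3x3", call. = FALSE)
  ctr <- gray[2:(H - 1), 2:(W - 1)]
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                 c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, H - 2L, W - 2L)
  for (p in seq_along(shifts)) {
    dr <- shifts[[p]][1]; dc <- shifts[[p]][2]
    nb <- gray[(2 + dr):(H - 1 + dr), (2 + dc):(W - 1 + dc)]
    code <- code + (nb >= ctr) * bitwShiftL(1L, p - 1L)
  }
  h <- tabulate(as.vector(code) + 1L, nbins = 256L)
  stats::setNames(h / sum(h), paste0("Uv_", 0:255))
}

# ---------------------------------------------------------------- HOG ----

# Central-difference gradients with replicated edges.
.cdiff <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  up <- gray[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- gray[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  lf <- gray[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- gray[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  list(gx = (rt - lf) / 2,   # along image columns (x direction)
       gy = (dn - up) / 2)   # along image rows (y direction)
}

#' HOG feature vector (Sv)
#'
#' Gradients by central differences, magnitude-weighted orientation
#' histograms over square cells (unsigned orientations, `atan2`-based so a
#' zero x-gradient maps to the 90-degree bin), then L2 normalization over
#' sliding blocks of `block x block` cells (zero-norm blocks stay zero).
#' The vector length is `bins * block^2 * n_blocks`, fixed by the
#' configuration: a 64x64 image with 8-pixel cells, 2x2 blocks and 9 bins
#' gives 9 * 4 * 49 = 1764.
#'
#' @param gray `H x W` numeric matrix, at least one block large.
#' @param cell cell side in pixels.
#' @param block block side in cells.
#' @param bins number of unsigned orientation bins over `[0, 180)`.
#' @return named numeric vector `Sv_1 ...`.
#' @export
hog_features <- function(gray, cell = 8L, block = 2L, bins = 9L) {
  H <- nrow(gray); W <- ncol(gray)
  ncr <- H %/% cell
  ncc <- W %/% cell
  if (ncr < block || ncc < block) {
    stop("image too small for one ", block, "x", block, " block of ",
         cell, "-pixel cells", call. = FALSE)
  }
  g <- .cdiff(gray)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx)           # (-pi, pi]
  ang <- ang %% pi                   # unsigned orientation in [0, pi)
  bin <- pmin(floor(ang / (pi / bins)), bins - 1L) + 1L
  # cell histograms
  hist_cells <- array(0, c(bins, ncr, ncc))
  ci <- (rep(seq_len(H), times = W) - 1L) %/% cell + 1L
  cj <- (rep(seq_len(W), each = H) - 1L) %/% cell + 1L
  keep <- ci <= ncr & cj <= ncc
  lin <- as.vector(bin)[keep] + (ci[keep] - 1L) * bins +
    (cj[keep] - 1L) * bins * ncr
  acc <- rowsum(as.vector(mag)[keep], lin)
  hist_cells[as.integer(rownames(acc))] <- acc
  # sliding blocks, L2 normalized
  nbr <- ncr - block + 1L
  nbc <- ncc - block + 1L
  out <- numeric(bins * block * block * nbr * nbc)
  pos <- 0L
  len <- bins * block * block
  for (bj in seq_len(nbc)) {
    for (bi in seq_len(nbr)) {
      v <- as.vector(hist_cells[, bi:(bi + block - 1L),
                                bj:(bj + block - 1L)])
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
      out[pos + seq_len(len)] <- v
      pos <- pos + len
    }
  }
  stats::setNames(out, paste0("Sv_", seq_along(out)))
}

# --------------------------------------------------------------- SFTA ----

#' Multilevel Otsu thresholds
#'
#' Chooses `nt` gray-level thresholds maximizing the between-class variance
#' of the 256-level histogram (the multimodal Otsu criterion), by exact
#' dynamic programming over interval sums. Thresholds are returned strictly
#' increasing; a threshold `t` splits levels into `<= t` and `> t`.
#'
#' @param gray matrix of integer gray levels 0--255 (see
#'   [rgb_to_gray()] with `bits = 8`).
#' @param nt number of thresholds (>= 1).
#' @return integer vector of `nt` thresholds.
#' @export
sfta_thresholds <- function(gray, nt = 4L) {
  lv <- as.integer(gray)
  if (any(lv < 0L) || any(lv > 255L)) {
    stop("gray levels must be integers in 0..255", call. = FALSE)
  }
  if (length(unique(lv)) < 2L) {
    stop("constant image has no valid threshold", call. = FALSE)
  }
  nt <- as.integer(nt)
  stopifnot(nt >= 1L)
  h <- tabulate(lv + 1L, nbins = 256L)
  p <- h / sum(h)
  # cumulative sums for interval statistics
  P <- cumsum(p)
  M <- cumsum(p * (0:255))
  P0 <- c(0, P)
  M0 <- c(0, M)
  # icost_vec(a, b): between-class contribution w * mu^2 of levels a..b,
  # vectorized over a (1-based levels)
  icost_vec <- function(a, b) {
    w <- P[b] - P0[a]
    m <- M[b] - M0[a]
    # empty intervals have m == 0 as well; guard the denominator only
    (m * m) / (w + (w < 1e-300))
  }
  # dp[k, b]: best sum of w*mu^2 splitting levels 1..b into k groups
  K <- nt + 1L
  dp <- matrix(-Inf, K, 256L)
  arg <- matrix(0L, K, 256L)
  dp[1, ] <- (M * M) / (P + (P < 1e-300))
  for (k in 2:K) {
    for (b in k:256) {
      a <- k:b
      v <- dp[k - 1L, a - 1L] + icost_vec(a, b)
      ba <- which.max(v)
      dp[k, b] <- v[ba]
      arg[k, b] <- a[ba]
    }
  }
  # backtrack: thresholds are the (0-based) level just below each cut
  th <- integer(nt)
  b <- 256L
  for (k in K:2) {
    a <- arg[k, b]
    th[k - 1L] <- a - 2L     # levels a..b are > threshold (a-2) 0-based
    b <- a - 1L
  }
  sort(unique(th))
}

#' Two-threshold binary decomposition (TTBD bands)
#'
#' Builds `2 * nt` binary images from a sorted threshold list: the
#' consecutive-pair bands `(t_i, t_{i+1}]` (with the image maximum closing
#' the last band) and the single-threshold binarizations `(t_i, max]`.
#' Band membership is half-open: a pixel equal to the lower bound is 0,
#' equal to the upper bound is 1.
#'
#' @param gray matrix of gray levels.
#' @param thresholds sorted threshold vector.
#' @return list of logical matrices, length `2 * length(thresholds)`.
#' @export
ttbd_binaries <- function(gray, thresholds) {
  stopifnot(!is.unsorted(thresholds))
  top <- max(gray)
  bands <- vector("list", 2L * length(thresholds))
  uppers <- c(thresholds[-1], top)
  for (i in seq_along(thresholds)) {
    bands[[i]] <- gray > thresholds[i] & gray <= uppers[i]
  }
  for (i in seq_along(thresholds)) {
    bands[[length(thresholds) + i]] <- gray > thresholds[i] & gray <= top
  }
  bands
}

#' Border map of a binary image
#'
#' A pixel of the border map is 1 iff the binary pixel is 1 and at least
#' one of its 8 neighbors is 0; out-of-bounds neighbors count as 0, so
#' object pixels touching the image frame are border pixels.
#'
#' @param binary logical or 0/1 matrix.
#' @return logical matrix of the same size.
#' @export
border_image <- function(binary) {
  b <- binary != 0
  H <- nrow(b); W <- ncol(b)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- b
  all_nb <- matrix(TRUE, H, W)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      all_nb <- all_nb & pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    }
  }
  b & !all_nb
}

#' Box-counting fractal dimension of a border map
#'
#' Least-squares slope of `log(occupied boxes)` against `log(1 / box size)`
#' over dyadic box sizes. An empty map has dimension 0 by convention; a
#' single pixel (one box at every scale) gives 0; a straight line gives
#' approximately 1.
#'
#' @param border logical or 0/1 matrix.
#' @param box_sizes strictly increasing powers of two.
#' @return fractal dimension estimate.
#' @export
box_counting_dim <- function(border, box_sizes = c(2L, 4L, 8L, 16L)) {
  stopifnot(all(box_sizes == 2^round(log2(box_sizes))),
            !is.unsorted(box_sizes, strictly = TRUE))
  b <- border != 0
  if (!any(b)) return(0)
  pix <- which(b, arr.ind = TRUE)
  counts <- vapply(box_sizes, function(s) {
    boxes <- unique((pix[, 1] - 1L) %/% s * 1e6 + (pix[, 2] - 1L) %/% s)
    length(boxes)
  }, numeric(1))
  x <- log(1 / box_sizes)
  y <- log(counts)
  xc <- x - mean(x)
  if (sum(xc^2) == 0) return(0)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' SFTA configuration
#'
#' @param nt number of multilevel Otsu thresholds (default 4, giving a
#'   24-long feature vector).
#' @param box_sizes dyadic box-counting scales.
#' @return an `sfta_config` list.
#' @export
sfta_config <- function(nt = 4L, box_sizes = c(2L, 4L, 8L, 16L)) {
  stopifnot(nt >= 1L,
            all(box_sizes == 2^round(log2(box_sizes))),
            !is.unsorted(box_sizes, strictly = TRUE))
  structure(list(nt = as.integer(nt), box_sizes = as.integer(box_sizes)),
            class = "sfta_config")
}

#' SFTA feature vector (Tv)
#'
#' Decomposes the 8-bit image into `2 * nt` binary images
#' ([ttbd_binaries()]) and, for each, measures the box-counting fractal
#' dimension of its border, the mean gray level of the region (0--255
#' scale; 0 for an empty region) and the region pixel count: a vector of
#' length `6 * nt`.
#'
#' @param gray matrix of integer gray levels 0--255.
#' @param config an [sfta_config()].
#' @return named numeric vector `Tv_1 ... Tv_{6 nt}`.
#' @export
sfta_features <- function(gray, config = sfta_config()) {
  th <- sfta_thresholds(gray, config$nt)
  # pad the threshold list if ties collapsed it (degenerate histograms)
  while (length(th) < config$nt) th <- sort(unique(c(th, max(th) + 1L)))
  bands <- ttbd_binaries(gray, th)
  out <- numeric(3L * length(bands))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    brd <- border_image(b)
    out[3L * i - 2L] <- box_counting_dim(brd, config$box_sizes)
    out[3L * i - 1L] <- if (any(b)) mean(gray[b]) else 0
    out[3L * i] <- sum(b)
  }
  stats::setNames(out, paste0("Tv_", seq_along(out)))
}

# ---------------------------------------------------- dataset surface ----

#' Handcrafted feature matrix for a dataset
#'
#' Converts each image to grayscale and concatenates the requested
#' descriptor blocks per image (in the order Sv (HOG), Tv (SFTA),
#' Uv (LBP)).
#'
#' @param data dataset tibble.
#' @param methods subset of `c("hog", "sfta", "lbp")`.
#' @param hog_cell,hog_block,hog_bins HOG parameters.
#' @param sfta an [sfta_config()].
#' @return tibble of features, one row per image.
#' @export
handcrafted_features <- function(data,
                                 methods = c("hog", "sfta", "lbp"),
                                 hog_cell = 8L, hog_block = 2L,
                                 hog_bins = 9L,
                                 sfta = sfta_config()) {
  validate_dataset(data)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(data$image, function(img) {
    g <- rgb_to_gray(img)
    parts <- list()
    if ("hog" %in% methods) {
      parts$hog <- hog_features(g, hog_cell, hog_block, hog_bins)
    }
    if ("sfta" %in% methods) {
      g8 <- matrix(as.integer(round(g * 255)), nrow(g), ncol(g))
      parts$sfta <- sfta_features(g8, sfta)
    }
    if ("lbp" %in% methods) parts$lbp <- lbp_features(g)
    unlist(parts, use.names = TRUE)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- sub("^(hog|sfta|lbp)\\.", "", colnames(m))
  tibble::as_tibble(m)
}
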