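#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# The three diabetic-retinopathy severity grades used throughout.
dr_labels <- function() c("DR1", "DR2", "DR3")

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Validate an RGB image tensor
#'
#' An image tensor is a plain numeric `H x W x 3` array with all values in
#' `[0, 1]` and both spatial sides at least 32 pixels (smaller arrays are
#' accepted when `strict = FALSE`, which the handcrafted descriptors use for
#' toy fixtures).
#'
#' @param img numeric array.
#' @param strict enforce the minimum 32-pixel side length.
#' @return `img`, invisibly, after validation.
#' @export
validate_image <- function(img, strict = TRUE) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  if (strict && (dim(img)[1] < 32L || dim(img)[2] < 32L)) {
    stop("image sides must be at least 32 pixels", call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    stop("image values must lie in [0, 1]", call. = FALSE)
  }
  invisible(img)
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114).
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param bits if `8`, quantize to integer gray levels 0--255 (the scale the
#'   SFTA thresholding operates on); `NULL` keeps values in `[0, 1]`.
#' @return an `H x W` matrix.
#' @export
rgb_to_gray <- function(img, bits = NULL) {
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  if (!is.null(bits)) {
    if (bits != 8) stop("only 8-bit quantization is supported", call. = FALSE)
    g <- matrix(as.integer(round(g * 255)), nrow(g), ncol(g))
  }
  g
}

#' Resize an image to the network input size
#'
#' Deterministic bilinear resampling to `size x size x 3`; output values are
#' clipped to `[0, 1]`. An image already at the target size is returned
#' unchanged. The default 224 matches the preprocessing used for the
#' full-resolution pipeline; the desk-scale benchmark works at 64.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param size target side length in pixels.
#' @return a `size x size x 3` array.
#' @export
preprocess <- function(img, size = 224L) {
  validate_image(img, strict = FALSE)
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(img, colormode = "Color"), w = size, h = size))
  clip01(array(out, c(size, size, 3L)))
}

#' Assemble an image dataset tibble
#'
#' The tabular container used by every pipeline stage: one row per image,
#' with the pixel array held in a list-column.
#'
#' @param images list of `H x W x 3` arrays in `[0, 1]`.
#' @param label character or factor of grade labels (`DR1`/`DR2`/`DR3`).
#' @param split `"train"` or `"test"` per image.
#' @param provenance one of `"original"`, `"fgsm"`, `"speckle"`,
#'   `"deepfool"` per image.
#' @param id stable per-source-image identifiers (generated when missing);
#'   attacked copies keep the id of their source image, which is what the
#'   train/test leakage checks compare.
#' @return a tibble with columns `image`, `label`, `split`, `provenance`,
#'   `id`.
#' @export
image_dataset <- function(images, label, split = "train",
                          provenance = "original", id = NULL) {
  stopifnot(is.list(images), length(images) >= 1L)
  if (is.null(id)) id <- sprintf("img%05d", seq_along(images))
  tb <- tibble::tibble(
    image = images,
    label = as.character(label),
    split = rep_len(as.character(split), length(images)),
    provenance = rep_len(as.character(provenance), length(images)),
    id = as.character(id)
  )
  validate_dataset(tb)
  tb
}

#' Validate an image dataset tibble
#'
#' Checks the column contract, label presence, and the value range of a
#' sample of images.
#'
#' @param data dataset tibble as built by [image_dataset()].
#' @return `data`, invisibly.
#' @export
validate_dataset <- function(data) {
  need <- c("image", "label", "split", "provenance")
  if (!all(need %in% names(data))) {
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data$label)) stop("every item needs a label", call. = FALSE)
  bad <- setdiff(unique(data$provenance),
                 c("original", "fgsm", "speckle", "deepfool"))
  if (length(bad)) stop("unknown provenance: ", bad[1], call. = FALSE)
  bad <- setdiff(unique(data$split), c("train", "test"))
  if (length(bad)) stop("unknown split: ", bad[1], call. = FALSE)
  invisible(data)
}

#' Per-class image counts of a dataset
#'
#' @param data dataset tibble.
#' @return tibble with columns `label`, `split`, `provenance`, `n`.
#' @export
class_counts <- function(data) {
  dplyr::count(data, .data$label, .data$split, .data$provenance, name = "n")
}

#' Write a dataset to a directory of PNG files
#'
#' Layout is `root/<split>/<label>/<id>.png` with a `manifest.csv`
#' (columns path, label, split, provenance) at the root. Pixel values are
#' quantized to 8 bits by the PNG encoder.
#'
#' @param data dataset tibble.
#' @param dir output directory (created if missing).
#' @return the manifest tibble, invisibly.
#' @export
write_dataset <- function(data, dir) {
  validate_dataset(data)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    sub <- file.path(dir, data$split[i], data$label[i])
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    rel <- file.path(data$split[i], data$label[i],
                     sprintf("img_%05d_%s.png", i, data$provenance[i]))
    png::writePNG(aperm(data$image[[i]], c(1, 2, 3)), file.path(dir, rel))
    paths[i] <- rel
  }
  manifest <- tibble::tibble(path = paths, label = data$label,
                             split = data$split,
                             provenance = data$provenance, id = data$id)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset root containing `manifest.csv`.
#' @return dataset tibble.
#' @export
read_dataset <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  images <- lapply(mf$path, function(p) {
    px <- png::readPNG(file.path(dir, p))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    array(px[, , 1:3], c(dim(px)[1], dim(px)[2], 3L))
  })
  image_dataset(images, mf$label, mf$split, mf$provenance, id = mf$id)
}

#' Plot an image tensor
#'
#' @param img `H x W x 3` array.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  validate_image(img, strict = FALSE)
  H <- dim(img)[1]
  W <- dim(img)[2]
  df <- tidyr::expand_grid(row = seq_len(H), col = seq_len(W))
  df$fill <- grDevices::rgb(img[, , 1][cbind(df$row, df$col)],
                            img[, , 2][cbind(df$row, df$col)],
                            img[, , 3][cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title)
}
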