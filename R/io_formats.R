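# Optional readers/writers for standard image-classification file layouts, so
# synthetic data can flow through the same paths as the real benchmarks:
# IDX (the MNIST dialect), CIFAR-10 binary batches, and directory-of-PNG
# class banks.

#' Write images / labels in IDX format
#'
#' Images are rescaled to 0..255 unsigned bytes (per-dataset min/max); labels
#' are written 0-based as in the original dialect.
#'
#' @param data A dataset (`x`, `y`, `image_shape`).
#' @param image_path,label_path Output file paths.
#' @export
write_idx <- function(data, image_path, label_path) {
  H <- data$image_shape[1]; W <- data$image_shape[2]
  if (data$image_shape[3] != 1)
    stop("write_idx supports single-channel images only")
  n <- nrow(data$x)
  rng <- range(data$x)
  bytes <- matrix(as.integer(round((data$x - rng[1]) / max(rng[2] - rng[1], 1e-12) * 255)),
                  nrow = n)
  con <- file(image_path, "wb")
  writeBin(c(0L, 0L, 8L, 3L), con, size = 1)
  writeBin(c(n, H, W), con, size = 4, endian = "big")
  # IDX stores row-major pixels; our layout is column-major (H, W)
  perm <- as.vector(t(matrix(seq_len(H * W), H, W)))
  for (i in seq_len(n)) writeBin(bytes[i, perm], con, size = 1)
  close(con)
  con <- file(label_path, "wb")
  writeBin(c(0L, 0L, 8L, 1L), con, size = 1)
  writeBin(n, con, size = 4, endian = "big")
  writeBin(as.integer(data$y - 1L), con, size = 1)
  close(con)
  invisible(c(image_path, label_path))
}

#' Read an IDX image/label pair
#'
#' @param image_path,label_path Files written in the IDX dialect.
#' @return A dataset (`x` scaled to 0..1, `y` 1-based, `image_shape`).
#' @export
read_idx <- function(image_path, label_path) {
  con <- file(image_path, "rb")
  magic <- readBin(con, "integer", 4, size = 1)
  if (!identical(magic[3:4], c(8L, 3L))) { close(con); stop("not an IDX3 image file") }
  dims <- readBin(con, "integer", 3, size = 4, endian = "big")
  n <- dims[1]; H <- dims[2]; W <- dims[3]
  raw_px <- readBin(con, "integer", n * H * W, size = 1, signed = FALSE)
  close(con)
  # row-major pixel stream back to the (H, W) column-major layout
  cm <- seq_len(H * W)
  map <- ((cm - 1) %% H) * W + (cm - 1) %/% H + 1
  x <- matrix(raw_px, n, H * W, byrow = TRUE)
  x <- x[, map, drop = FALSE] / 255
  con <- file(label_path, "rb")
  readBin(con, "integer", 4, size = 1)
  nl <- readBin(con, "integer", 1, size = 4, endian = "big")
  y <- readBin(con, "integer", nl, size = 1, signed = FALSE) + 1L
  close(con)
  list(x = x, y = y, n_classes = length(unique(y)),
       image_shape = c(H, W, 1L))
}

#' Read CIFAR-10 binary batch files
#'
#' Each record is 1 label byte followed by 3072 pixel bytes (3 row-major
#' 32x32 planes).
#'
#' @param paths Character vector of `data_batch_*.bin` files.
#' @return A dataset (`x` scaled to 0..1, `y` 1-based, shape 32x32x3).
#' @export
read_cifar10_bin <- function(paths) {
  xs <- list(); ys <- list()
  rowmajor <- as.vector(t(matrix(seq_len(32 * 32), 32, 32)))
  perm <- c(rowmajor, rowmajor + 1024L, rowmajor + 2048L)
  for (p in paths) {
    raw_bytes <- readBin(p, "integer", file.info(p)$size, size = 1, signed = FALSE)
    m <- matrix(raw_bytes, ncol = 3073, byrow = TRUE)
    ys[[p]] <- m[, 1] + 1L
    xp <- m[, -1, drop = FALSE] / 255
    xs[[p]] <- xp[, order(perm), drop = FALSE]
  }
  list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
       n_classes = 10L, image_shape = c(32L, 32L, 3L))
}

#' Write a class bank as a directory of PNG files
#'
#' One subdirectory per class, one grayscale PNG per item (requires the
#' `png` package).
#'
#' @param bank A class bank (`x`, `y`, `image_shape`).
#' @param dir Output directory.
#' @export
write_png_bank <- function(bank, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("write_png_bank requires the 'png' package")
  H <- bank$image_shape[1]; W <- bank$image_shape[2]
  rng <- range(bank$x)
  for (cl in sort(unique(bank$y))) {
    cdir <- file.path(dir, sprintf("class_%03d", cl))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    idx <- which(bank$y == cl)
    for (j in seq_along(idx)) {
      img <- matrix((bank$x[idx[j], ] - rng[1]) / max(rng[2] - rng[1], 1e-12), H, W)
      png::writePNG(img, file.path(cdir, sprintf("item_%04d.png", j)))
    }
  }
  invisible(dir)
}

#' Read a directory-of-PNG class bank
#'
#' @param dir Directory with one subdirectory per class.
#' @return A class bank (`x`, `y`, `n_classes`, `image_shape`).
#' @export
read_png_bank <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("read_png_bank requires the 'png' package")
  cdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(cdirs)) stop("no class subdirectories in ", dir)
  xs <- list(); ys <- list()
  for (ci in seq_along(cdirs)) {
    files <- sort(list.files(cdirs[ci], pattern = "\\.png$", full.names = TRUE))
    imgs <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      as.vector(img)
    })
    xs[[ci]] <- do.call(rbind, imgs)
    ys[[ci]] <- rep(ci, length(files))
  }
  probe <- png::readPNG(list.files(cdirs[1], pattern = "\\.png$", full.names = TRUE)[1])
  list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
       n_classes = length(cdirs),
       image_shape = c(dim(probe)[1], dim(probe)[2], 1L))
}
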