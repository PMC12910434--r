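#' Fluorescence image stack
#'
#' A 2D image or 3D z-stack of nonnegative intensities with voxel sizes and
#' a channel role tag. Data are indexed `[row (y), column (x), z]`; pixel
#' indices are 0-based half-open at the interface level, with physical
#' units (um) attached here.
#'
#' @param data numeric matrix or 3D array of intensities.
#' @param voxel_size length-3 numeric `(dx, dy, dz)` in um; `dz` defaults to
#'   0.13 um (the 130-nm confocal z-step used for Nyquist sampling).
#' @param channel role tag: one of lamin, actin, vecad, yap, vinculin,
#'   pmlc, dna, mixed.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, voxel_size = c(0.1, 0.1, 0.13),
                        channel = c("lamin", "actin", "vecad", "yap",
                                    "vinculin", "pmlc", "dna", "mixed")) {
  channel <- match.arg(channel)
  if (length(dim(data)) == 2L) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop("data must be 2D or 3D")
  if (any(data < 0)) stop("intensities must be nonnegative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 2L) voxel_size <- c(voxel_size, 0.13)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive numbers (dx, dy, dz)")
  }
  structure(list(data = data, voxel_size = voxel_size, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack [%s]: %d x %d px, %d planes, voxel %.3g x %.3g x %.3g um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Maximum-intensity projection along z
#' @param stack an [image_stack()].
#' @return matrix (y by x).
#' @export
max_projection <- function(stack) {
  apply(stack$data, c(1, 2), max)
}

#' Mean-intensity projection along z (optionally over a plane subset)
#' @param stack an [image_stack()].
#' @param planes z indices to average (default all).
#' @return matrix (y by x).
#' @export
mean_projection <- function(stack, planes = NULL) {
  d <- stack$data
  if (!is.null(planes)) d <- d[, , planes, drop = FALSE]
  apply(d, c(1, 2), mean)
}

#' Write an image stack to a multi-page TIFF with a YAML sidecar
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at `<path>.yaml`.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- stack$data
  mx <- max(d, 1)
  pages <- lapply(seq_len(dim(d)[3]), function(k) d[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(voxel_size = as.list(stack$voxel_size),
                        channel = stack$channel,
                        intensity_scale = mx),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#' @param path TIFF path with `<path>.yaml` sidecar.
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  d <- simplify2array(pages) * meta$intensity_scale
  if (length(dim(d)) == 2L) d <- array(d, c(dim(d), 1L))
  image_stack(d, voxel_size = unlist(meta$voxel_size), channel = meta$channel)
}
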