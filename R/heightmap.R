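#' Monolayer height map and roughness from a combined-channel stack
#'
#' Binarizes the (channel-combined) 3D stack by a global Otsu threshold,
#' measures the apical-basal distance in every pixel column, crops an edge
#' margin (channel-wall artifacts), fills uncovered columns with the
#' iterated mean of adjacent covered pixels, and block-averages the grid by
#' `downsample` to suppress high-frequency noise. The monolayer roughness
#' is the standard deviation of the final height grid.
#'
#' @param stack an [image_stack()] with the channels already summed (tag
#'   `mixed`), or a list of stacks to sum.
#' @param crop_margin edge margin to discard (um).
#' @param downsample integer block size for spatial down-sampling.
#' @return a `height_map`: list with `grid` (heights, um), `mask_covered`
#'   (pre-interpolation coverage at the downsampled grid), `roughness_sd`
#'   (um), `pixel_size` (um, after downsampling).
#' @export
monolayer_height_map <- function(stack, crop_margin = 2, downsample = 4L) {
  if (is.list(stack) && !inherits(stack, "image_stack")) {
    dat <- Reduce(`+`, lapply(stack, function(s) s$data))
    stack <- image_stack(dat, stack[[1]]$voxel_size, "mixed")
  }
  d <- stack$data
  vx <- stack$voxel_size
  mn <- norm01(d)
  if (max(mn) == 0) stop("no cells: empty stack")
  th <- EBImage::otsu(EBImage::Image(as.vector(mn), dim = c(length(mn), 1)))
  bw <- mn > th
  if (!any(bw)) stop("no cells: empty field after thresholding")
  nz <- dim(bw)[3]
  zidx <- array(rep(seq_len(nz), each = prod(dim(bw)[1:2])), dim(bw))
  top <- apply(ifelse(bw, zidx, NA_integer_), c(1, 2), function(v)
    if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE))
  bot <- apply(ifelse(bw, zidx, NA_integer_), c(1, 2), function(v)
    if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE))
  h <- (top - bot + 1L) * vx[3]
  # crop margin
  my <- round(crop_margin / vx[2]); mx <- round(crop_margin / vx[1])
  if (2 * my >= nrow(h) || 2 * mx >= ncol(h)) {
    stop("crop_margin covers the entire field")
  }
  if (my > 0) h <- h[(my + 1):(nrow(h) - my), , drop = FALSE]
  if (mx > 0) h <- h[, (mx + 1):(ncol(h) - mx), drop = FALSE]
  covered <- !is.na(h)
  if (!any(covered)) stop("no cells: field fully uncovered after cropping")
  # fill uncovered pixels with the mean of adjacent covered pixels, iterated
  hh <- h; hh[is.na(hh)] <- 0
  cov <- covered * 1
  while (any(cov == 0)) {
    sh <- function(m, dr, dc) {
      out <- matrix(0, nrow(m), ncol(m))
      rs <- (1 + max(0, dr)):(nrow(m) + min(0, dr))
      cs <- (1 + max(0, dc)):(ncol(m) + min(0, dc))
      out[rs, cs] <- m[rs - dr, cs - dc]
      out
    }
    ssum <- sh(hh * cov, 1, 0) + sh(hh * cov, -1, 0) +
      sh(hh * cov, 0, 1) + sh(hh * cov, 0, -1)
    scnt <- sh(cov, 1, 0) + sh(cov, -1, 0) + sh(cov, 0, 1) + sh(cov, 0, -1)
    newly <- cov == 0 & scnt > 0
    if (!any(newly)) break
    hh[newly] <- ssum[newly] / scnt[newly]
    cov[newly] <- 1
  }
  # block-average downsample
  ds <- max(1L, as.integer(downsample))
  nr <- (nrow(hh) %/% ds) * ds; nc <- (ncol(hh) %/% ds) * ds
  hh <- hh[seq_len(nr), seq_len(nc), drop = FALSE]
  covered <- covered[seq_len(nr), seq_len(nc), drop = FALSE]
  if (ds > 1L) {
    block <- function(m) {
      m1 <- rowsum(m, rep(seq_len(nr %/% ds), each = ds)) / ds
      t(rowsum(t(m1), rep(seq_len(nc %/% ds), each = ds)) / ds)
    }
    hh <- block(hh)
    covered <- block(covered * 1) > 0.5
  }
  structure(list(
    grid = hh,
    mask_covered = covered,
    roughness_sd = stats::sd(as.vector(hh)),
    pixel_size = vx[1:2] * ds
  ), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height_map: %d x %d grid (%.3g um/px), roughness SD = %.3g um\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size[1], x$roughness_sd))
  invisible(x)
}

#' Render a height map to PNG and 32-bit TIFF
#' @param hm a `height_map`.
#' @param path_base output path without extension.
#' @return paths written, invisibly.
#' @export
write_height_map <- function(hm, path_base) {
  tiff_path <- paste0(path_base, ".tif")
  png_path <- paste0(path_base, ".png")
  g <- hm$grid
  tiff::writeTIFF(g / max(g, 1), tiff_path, bits.per.sample = 32L)
  grDevices::png(png_path, width = 480, height = 480)
  graphics::image(t(g)[, nrow(g):1], col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = sprintf("roughness SD %.2f um", hm$roughness_sd))
  grDevices::dev.off()
  invisible(c(tiff_path, png_path))
}
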