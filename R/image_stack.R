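#' Multi-channel, multi-slice calibrated image stack
#'
#' Container for fluorescence stacks: a 4D intensity array indexed
#' `[y, x, z, channel]` plus physical calibration and a channel-role map.
#' Roles name what each channel stains (`plaque`, `iba1`, `lamp1`,
#' `nuclei`, `fitc`); downstream operations look channels up by role so
#' acquisition order never matters.
#'
#' @param pixels 4D numeric array `[y, x, z, channel]`, finite and >= 0.
#' @param pixel_size_um lateral calibration, micrometres per pixel.
#' @param z_step_um axial step between slices, micrometres.
#' @param channel_roles named integer vector mapping role -> channel index.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(pixels, pixel_size_um, z_step_um = 1,
                        channel_roles = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and non-negative")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (!is.null(channel_roles)) {
    bad <- channel_roles < 1 | channel_roles > dim(pixels)[4]
    if (any(bad))
      stop("channel role(s) out of range: ",
           paste(names(channel_roles)[bad], collapse = ", "))
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, channel_roles = channel_roles),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d x %d px, %d slice(s), %d channel(s), %.3g um/px\n",
              d[1], d[2], d[3], d[4], x$pixel_size_um))
  if (!is.null(x$channel_roles))
    cat("  roles:", paste(names(x$channel_roles), x$channel_roles,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Look a channel up by role, with an actionable error when missing.
stack_channel_index <- function(stack, role) {
  if (is.null(stack$channel_roles) || !(role %in% names(stack$channel_roles)))
    stop("channel role '", role, "' is not declared on this stack")
  unname(stack$channel_roles[[role]])
}

#' Extract one channel of a projected (2D) stack as a matrix
#'
#' @param img `ImageStack` (typically a projection with one z-slice) or a
#'   matrix (returned unchanged).
#' @param role channel role name, ignored for matrix input.
#' @param z slice index (default 1).
#' @return numeric matrix.
#' @export
get_channel <- function(img, role, z = 1) {
  if (is.matrix(img)) return(img)
  stopifnot(inherits(img, "ImageStack"))
  img$pixels[, , z, stack_channel_index(img, role)]
}

#' Write an `ImageStack` as a multi-page TIFF
#'
#' One page per z-slice per channel, channel-major within slice
#' (page order: z1c1, z1c2, ..., z2c1, ...). Intensities are clipped to
#' `[0, 1]` and stored as 16-bit. Calibration and roles are not stored in
#' the TIFF; keep them in the run configuration.
#'
#' @param stack `ImageStack`.
#' @param path output file path.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$pixels)
  pages <- vector("list", d[3] * d[4])
  k <- 1
  for (z in seq_len(d[3])) for (ch in seq_len(d[4])) {
    pages[[k]] <- pmin(pmax(stack$pixels[, , z, ch], 0), 1)
    k <- k + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF path.
#' @param n_channels number of channels interleaved per slice.
#' @param pixel_size_um,z_step_um physical calibration (TIFF pages carry
#'   none; these must come from the run configuration).
#' @param channel_roles named role -> index map.
#' @return `ImageStack`.
#' @export
read_stack_tiff <- function(path, n_channels, pixel_size_um, z_step_um = 1,
                            channel_roles = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% n_channels != 0)
    stop("page count ", length(pages), " is not a multiple of n_channels")
  nz <- length(pages) / n_channels
  d1 <- dim(pages[[1]])
  px <- array(0, dim = c(d1[1], d1[2], nz, n_channels))
  k <- 1
  for (z in seq_len(nz)) for (ch in seq_len(n_channels)) {
    px[, , z, ch] <- pages[[k]]
    k <- k + 1
  }
  image_stack(px, pixel_size_um, z_step_um, channel_roles)
}
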