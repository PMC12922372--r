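#' A single-channel 2-D intensity image
#'
#' The unit every metric consumes: a non-negative intensity matrix plus the
#' pixel size in micrometres per pixel. Pixels are indexed `[row, col]`
#' (1-based, row-major as displayed); pixel centres sit at integer
#' coordinates.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size micrometres per pixel, > 0.
#' @param channel channel label.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size, channel = "unnamed") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("image intensities must be finite")
  if (any(pixels < 0)) stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel = as.character(channel)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> '%s': %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either a channel_image or a bare matrix (pixel_size then required).
.as_channel <- function(image, pixel_size = NULL, channel = "unnamed") {
  if (inherits(image, "channel_image")) return(image)
  if (is.matrix(image)) {
    if (is.null(pixel_size)) stop("pixel_size required when passing a bare matrix")
    return(channel_image(image, pixel_size, channel))
  }
  stop("image must be a channel_image or a matrix")
}

#' Per-cell compartment model
#'
#' Boolean masks for one cell: nucleus, whole cell, cytosol and (optionally)
#' an envelope ring. Construction enforces the compartment algebra:
#' the nucleus is contained in the cell and the cytosol is
#' `cell AND NOT nucleus` (the mask logic used for cytoplasmic signal).
#'
#' @param cell_id identifier.
#' @param nucleus_mask,cell_mask logical matrices of identical shape.
#' @param ring_mask optional envelope-ring mask.
#' @param ring_params optional `c(inner_um, outer_um)` offsets used to build
#'   the ring.
#' @return an object of class `segmented_cell`.
#' @export
segmented_cell <- function(cell_id, nucleus_mask, cell_mask,
                           ring_mask = NULL, ring_params = NULL) {
  stopifnot(is.matrix(nucleus_mask), is.matrix(cell_mask),
            all(dim(nucleus_mask) == dim(cell_mask)))
  mode(nucleus_mask) <- "logical"
  mode(cell_mask) <- "logical"
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus_mask must be contained in cell_mask")
  if (.n_components(nucleus_mask) != 1L)
    stop("nucleus_mask must be a single connected component")
  structure(list(cell_id = cell_id,
                 nucleus_mask = nucleus_mask,
                 cell_mask = cell_mask,
                 cytosol_mask = cell_mask & !nucleus_mask,
                 ring_mask = ring_mask,
                 ring_params = ring_params),
            class = "segmented_cell")
}

#' @export
print.segmented_cell <- function(x, ...) {
  cat(sprintf("<segmented_cell> %s: nucleus %d px, cell %d px, cytosol %d px%s\n",
              as.character(x$cell_id), sum(x$nucleus_mask), sum(x$cell_mask),
              sum(x$cytosol_mask),
              if (is.null(x$ring_mask)) "" else sprintf(", ring %d px", sum(x$ring_mask))))
  invisible(x)
}
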