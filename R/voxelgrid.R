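#' Two-channel 3D intensity stack
#'
#' A `voxel_grid` holds one imaging frame of a two-channel confocal stack:
#' a green reporter channel (e.g. EGFP-YAP) and a red nuclear-marker channel
#' (e.g. H2B-mCherry), both as 3D arrays indexed `[z, y, x]` (1-based), plus
#' the physical voxel size in micrometres.
#'
#' @param green Numeric 3D array of non-negative green-channel intensities.
#' @param red Numeric 3D array of non-negative red-channel intensities,
#'   same dimensions as `green`.
#' @param voxel_size Numeric length-3 vector, micrometres per voxel in
#'   `(z, y, x)` order. All entries must be `> 0`.
#' @param frame_index Integer frame number (0-based time index), `>= 0`.
#'
#' @return An object of class `voxel_grid`: a list with elements `green`,
#'   `red`, `voxel_size`, `frame_index`.
#' @examples
#' g <- array(1, dim = c(4, 8, 8))
#' vg <- voxel_grid(g, g, voxel_size = c(1, 0.3, 0.3))
#' dim(vg$green)
#' @export
voxel_grid <- function(green, red, voxel_size = c(1.0, 0.3, 0.3),
                       frame_index = 0L) {
  if (!is.array(green) || length(dim(green)) != 3L)
    stop("`green` must be a 3D array")
  if (!is.array(red) || length(dim(red)) != 3L)
    stop("`red` must be a 3D array")
  if (!identical(dim(green), dim(red)))
    stop("`green` and `red` must have identical dimensions")
  if (min(green) < 0 || min(red) < 0)
    stop("intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers (z, y, x) in micrometres")
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L)
    stop("`frame_index` must be a non-negative integer")
  structure(
    list(green = green, red = red, voxel_size = voxel_size,
         frame_index = frame_index),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels (z,y,x), voxel size %.3g x %.3g x %.3g um, frame %d\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$frame_index))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$green)

#' Per-cell 2D cytoplasm outline
#'
#' A closed polygon drawn around one cell at one z-plane, in voxel
#' coordinates, emulating a manually drawn cell outline. Pixel membership
#' uses pixel-centre containment: a pixel belongs to the outline's interior
#' iff its centre (its integer `(y, x)` index) lies strictly inside the
#' polygon.
#'
#' @param label Integer nucleus label the outline belongs to.
#' @param z Integer z-plane index (1-based).
#' @param vertices Numeric matrix with columns `(y, x)`, one vertex per row,
#'   in order around the polygon (closure is implicit). At least 3 vertices;
#'   the polygon must be simple (non-self-intersecting is assumed, not
#'   verified beyond basic checks).
#' @return An object of class `cell_outline`.
#' @examples
#' sq <- rbind(c(2, 2), c(2, 12), c(12, 12), c(12, 2))
#' cell_outline(1L, z = 3L, vertices = sq)
#' @export
cell_outline <- function(label, z, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("`vertices` must be an n x 2 matrix (y, x) with n >= 3")
  if (any(!is.finite(vertices))) stop("vertices must be finite")
  structure(
    list(label = as.integer(label), z = as.integer(z),
         vertices = unname(vertices)),
    class = "cell_outline"
  )
}

#' @export
print.cell_outline <- function(x, ...) {
  cat(sprintf("<cell_outline> label %d, z = %d, %d vertices\n",
              x$label, x$z, nrow(x$vertices)))
  invisible(x)
}

# internal: validate that a label exists in a nucleus_mask
assert_label <- function(mask, label) {
  if (!label %in% mask$table$label)
    stop(sprintf("label %d not present in mask", as.integer(label)))
  invisible(TRUE)
}
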