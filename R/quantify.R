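#' Mean channel intensity over a nucleus
#'
#' Unweighted arithmetic mean of one channel over a labelled nucleus,
#' either over all its voxels (3D) or restricted to one z-plane.
#' Voxels are weighted equally regardless of anisotropy, matching the
#' "average pixel intensity per nucleus" convention.
#'
#' @param grid A [voxel_grid()].
#' @param mask A `nucleus_mask` computed from the same stack.
#' @param label Nucleus label.
#' @param channel `"green"` or `"red"`.
#' @param plane Optional z-plane index; when given the mean is over that
#'   plane's pixels only.
#' @return Mean intensity (numeric scalar).
#' @export
nuclear_mean_intensity <- function(grid, mask, label,
                                   channel = c("green", "red"),
                                   plane = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "nucleus_mask"))
  channel <- match.arg(channel)
  assert_label(mask, label)
  if (!identical(dim(grid$green), dim(mask$labels)))
    stop("grid and mask dimensions differ")
  img <- grid[[channel]]
  if (is.null(plane)) {
    sel <- mask$labels == label
  } else {
    plane <- as.integer(plane)
    if (plane < 1L || plane > dim(img)[1])
      stop(sprintf("plane %d outside stack", plane))
    sel <- array(FALSE, dim(img))
    sel[plane, , ] <- mask$labels[plane, , ] == label
  }
  n <- sum(sel)
  if (n == 0L)
    stop(sprintf("label %d has no voxels at plane %d", label, plane))
  sum(img[sel]) / n
}

#' 3D nuclear green/red intensity ratio
#'
#' The reporter-to-marker ratio over the full 3D nucleus: mean green over
#' the label's voxels divided by mean red over the same voxels. With a
#' histone-fusion red marker this cancels nucleus-to-nucleus differences
#' in imaging depth and expression.
#'
#' @inheritParams nuclear_mean_intensity
#' @return Ratio (numeric scalar).
#' @export
nuclear_ratio_3d <- function(grid, mask, label) {
  g <- nuclear_mean_intensity(grid, mask, label, "green")
  r <- nuclear_mean_intensity(grid, mask, label, "red")
  if (r <= 0)
    stop(sprintf("undefined ratio: red mean is %g for label %d", r, label))
  g / r
}

#' 2D central-plane nuclear green/red ratio
#'
#' The same quotient restricted to the nucleus's central plane (see
#' [select_central_plane()]), emulating single-z-plane manual
#' measurements.
#'
#' @inheritParams nuclear_mean_intensity
#' @return Ratio (numeric scalar).
#' @export
nuclear_ratio_2d <- function(grid, mask, label) {
  zc <- select_central_plane(mask, label)
  g <- nuclear_mean_intensity(grid, mask, label, "green", plane = zc)
  r <- nuclear_mean_intensity(grid, mask, label, "red", plane = zc)
  if (r <= 0)
    stop(sprintf("undefined ratio: red mean is %g for label %d at plane %d",
                 r, label, zc))
  g / r
}

#' Nuclear-to-cytoplasmic green ratio
#'
#' Computed in 2D at the outline's z-plane, matching the manual outline
#' workflow: mean green over the nucleus pixels at that plane divided by
#' mean green over the cytoplasm region (outline interior minus nucleus).
#'
#' @inheritParams nuclear_mean_intensity
#' @param outline A [cell_outline()] for `label`.
#' @return N/C ratio (numeric scalar).
#' @export
nc_ratio <- function(grid, mask, outline, label = outline$label) {
  stopifnot(inherits(outline, "cell_outline"))
  if (label != outline$label)
    stop("`label` disagrees with the outline's label")
  cyto <- cytoplasm_region(outline, mask)
  z <- attr(cyto, "z")
  nuc_mean <- nuclear_mean_intensity(grid, mask, label, "green", plane = z)
  plane_green <- grid$green[z, , ]
  cyto_vals <- plane_green[cbind(cyto$y, cyto$x)]
  cyto_mean <- mean(cyto_vals)
  if (cyto_mean <= 0)
    stop(sprintf("undefined N/C ratio: cytoplasm mean is %g for label %d",
                 cyto_mean, label))
  nuc_mean / cyto_mean
}

#' Normalise cell intensities to dorsal-aorta reference cells
#'
#' Divides each measured cell's nuclear green mean by the average nuclear
#' green mean of `n_ref` reference (DA-class) cells from the same embryo.
#' Reference cells are taken deterministically in ascending `cell_id`
#' order. The default of 6 reference cells can be relaxed to a minimum of
#' 3 when fewer references are available.
#'
#' @param pl_measures data.frame of measured cells (needs `embryo_id`,
#'   `cell_id`, `mean_green_nuc_3d`).
#' @param da_measures data.frame of reference cells, same columns, same
#'   single `embryo_id`.
#' @param n_ref Number of reference cells to average (default 6, min 3).
#' @return `pl_measures` with a `da_norm` column added; the reference
#'   cell ids and their mean are recorded in attributes `"da_cells"` and
#'   `"da_reference_mean"`.
#' @examples
#' pl <- data.frame(embryo_id = "e1", cell_id = 1, mean_green_nuc_3d = 30)
#' da <- data.frame(embryo_id = "e1", cell_id = 2:7,
#'                  mean_green_nuc_3d = c(10, 20, 30, 20, 10, 30))
#' da_normalize(pl, da)$da_norm  # 30 / 20 = 1.5
#' @export
da_normalize <- function(pl_measures, da_measures, n_ref = 6L) {
  n_ref <- as.integer(n_ref)
  if (n_ref < 3L) stop("`n_ref` must be >= 3")
  need <- c("embryo_id", "cell_id", "mean_green_nuc_3d")
  stopifnot(all(need %in% names(pl_measures)),
            all(need %in% names(da_measures)))
  ids <- unique(c(pl_measures$embryo_id, da_measures$embryo_id))
  if (length(ids) != 1L)
    stop(sprintf("mixed embryo ids: %s", paste(ids, collapse = ", ")))
  if (nrow(da_measures) < n_ref)
    stop(sprintf(
      "insufficient reference cells: %d DA cells available, %d required",
      nrow(da_measures), n_ref))
  da_sorted <- da_measures[order(da_measures$cell_id), , drop = FALSE]
  ref <- da_sorted[seq_len(n_ref), , drop = FALSE]
  ref_mean <- mean(ref$mean_green_nuc_3d)
  if (ref_mean <= 0) stop("reference mean is not positive")
  out <- pl_measures
  out$da_norm <- out$mean_green_nuc_3d / ref_mean
  attr(out, "da_cells") <- ref$cell_id
  attr(out, "da_reference_mean") <- ref_mean
  out
}

#' Nucleus-masked maximum-intensity heatmap
#'
#' Maximum-intensity z-projection of the green channel restricted to
#' nucleus voxels (zero elsewhere), for rendering reporter levels as a
#' heatmap within nuclei.
#'
#' @param grid A [voxel_grid()].
#' @param mask A `nucleus_mask`.
#' @param projection Projection type; only `"max"` is supported.
#' @return A list of class `nuc_heatmap`: `image` (2D matrix, y by x),
#'   `limits` (colour-scale range), `projection`.
#' @export
render_heatmap <- function(grid, mask, projection = "max") {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "nucleus_mask"))
  projection <- match.arg(projection, "max")
  masked <- grid$green
  masked[mask$labels == 0L] <- 0
  if (nrow(mask$table) == 0L)
    warning("empty mask: heatmap is blank")
  img <- apply(masked, c(2, 3), max)
  structure(
    list(image = img, limits = range(img), projection = projection),
    class = "nuc_heatmap"
  )
}

#' Write a heatmap to PNG with a colour-scale sidecar
#'
#' Renders the masked projection with a blue-to-red palette (red = high
#' reporter signal) and writes the colour-scale limits to a JSON sidecar
#' (`<path>.json`) so figures remain quantitatively interpretable.
#'
#' @param heatmap A `nuc_heatmap` from [render_heatmap()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "nuc_heatmap"))
  img <- heatmap$image
  grDevices::png(path, width = ncol(img), height = nrow(img),
                 type = "cairo")
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  pal <- grDevices::colorRampPalette(
    c("black", "blue", "cyan", "yellow", "red"))(256)
  # image() draws x right, y up; transpose and flip to keep (y, x) layout
  graphics::image(t(img[rev(seq_len(nrow(img))), , drop = FALSE]),
                  col = pal, zlim = heatmap$limits, axes = FALSE,
                  useRaster = TRUE)
  jsonlite::write_json(
    list(limits = heatmap$limits, projection = heatmap$projection,
         palette = "black-blue-cyan-yellow-red"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.nuc_heatmap <- function(x, ...) {
  cat(sprintf("<nuc_heatmap> %d x %d (y,x), limits [%.3g, %.3g]\n",
              nrow(x$image), ncol(x$image), x$limits[1], x$limits[2]))
  invisible(x)
}

#' Measure every nucleus in a segmented stack
#'
#' Convenience wrapper producing one tidy row per nucleus with the 3D and
#' 2D green/red ratios; N/C ratio and DA normalisation are filled in by
#' [nc_ratio()] / [da_normalize()] when outlines or reference cells are
#' available. Undefined ratios are reported as `NA`, never as infinities.
#'
#' @param grid A [voxel_grid()].
#' @param mask A `nucleus_mask`.
#' @param embryo_id Identifier copied into every row.
#' @param cell_class Class label for every row (e.g. `"PL"`, `"DA"`).
#' @return data.frame, one row per label: `embryo_id`, `cell_id`, `class`,
#'   `frame`, `volume_voxels`, `mean_green_nuc_3d`, `mean_red_nuc_3d`,
#'   `ratio_3d`, `ratio_2d`, `central_plane`, `threshold_used`.
#' @export
measure_cells <- function(grid, mask, embryo_id = "embryo1",
                          cell_class = "PL") {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "nucleus_mask"))
  labs <- mask$table$label
  rows <- lapply(labs, function(lb) {
    g3 <- nuclear_mean_intensity(grid, mask, lb, "green")
    r3 <- nuclear_mean_intensity(grid, mask, lb, "red")
    zc <- select_central_plane(mask, lb)
    r3d <- if (r3 > 0) g3 / r3 else NA_real_
    r2d <- tryCatch(nuclear_ratio_2d(grid, mask, lb),
                    error = function(e) NA_real_)
    data.frame(embryo_id = embryo_id, cell_id = lb, class = cell_class,
               frame = grid$frame_index,
               volume_voxels = mask$table$voxels[mask$table$label == lb],
               mean_green_nuc_3d = g3, mean_red_nuc_3d = r3,
               ratio_3d = r3d, ratio_2d = r2d, central_plane = zc,
               threshold_used = mask$threshold_used)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    embryo_id = character(), cell_id = integer(), class = character(),
    frame = integer(), volume_voxels = integer(),
    mean_green_nuc_3d = numeric(), mean_red_nuc_3d = numeric(),
    ratio_3d = numeric(), ratio_2d = numeric(), central_plane = integer(),
    threshold_used = numeric())
  rownames(out) <- NULL
  out
}
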