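#' Otsu threshold of an intensity sample
#'
#' Classic between-class variance maximisation on a 256-bin histogram.
#' Only the supplied values are used; callers typically pass the nonzero
#' voxels of the red channel so the empty background does not dominate.
#'
#' @param values Numeric vector of intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold intensity (a bin edge), or `NA_real_` when the
#'   sample is empty or constant.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) return(NA_real_)
  rng <- range(values)
  if (rng[1] == rng[2]) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(values, breaks,
                                        rightmost.closed = TRUE),
                           nbins = n_bins))
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (mt - m[-n_bins]) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv)
  breaks[k + 1L]
}

# Relabel a raw component labelling: drop components below min_volume,
# order remaining labels by descending voxel count, ties by ascending
# (z, y, x) of the component's minimum coordinate.
relabel_by_size <- function(raw, min_volume) {
  n_raw <- max(raw, 0L)
  if (n_raw == 0L) return(list(labels = raw, table = empty_mask_table()))
  dims <- dim(raw)
  idx <- which(raw > 0L)
  lab <- raw[idx]
  zyx <- arrayInd(idx, dims)
  sizes <- tabulate(lab, nbins = n_raw)
  keep <- which(sizes >= min_volume)
  if (length(keep) == 0L) {
    out <- array(0L, dims)
    return(list(labels = out, table = empty_mask_table()))
  }
  minz <- rep(Inf, n_raw); miny <- rep(Inf, n_raw); minx <- rep(Inf, n_raw)
  mz <- tapply(zyx[, 1], lab, min); minz[as.integer(names(mz))] <- mz
  my <- tapply(zyx[, 2], lab, min); miny[as.integer(names(my))] <- my
  mx <- tapply(zyx[, 3], lab, min); minx[as.integer(names(mx))] <- mx
  ord <- keep[order(-sizes[keep], minz[keep], miny[keep], minx[keep])]
  remap <- integer(n_raw)
  remap[ord] <- seq_along(ord)
  out <- array(0L, dims)
  out[idx] <- remap[lab]
  kept_idx <- idx[remap[lab] > 0L]
  kept_lab <- remap[lab][remap[lab] > 0L]
  kept_zyx <- arrayInd(kept_idx, dims)
  tab <- data.frame(
    label = seq_along(ord),
    voxels = as.integer(sizes[ord]),
    centroid_z = as.numeric(tapply(kept_zyx[, 1], kept_lab, mean)),
    centroid_y = as.numeric(tapply(kept_zyx[, 2], kept_lab, mean)),
    centroid_x = as.numeric(tapply(kept_zyx[, 3], kept_lab, mean))
  )
  list(labels = out, table = tab)
}

empty_mask_table <- function() {
  data.frame(label = integer(), voxels = integer(),
             centroid_z = numeric(), centroid_y = numeric(),
             centroid_x = numeric())
}

#' Segment nuclei in 3D from the red channel
#'
#' Thresholds the red (nuclear marker) channel and labels the connected
#' components (26-connectivity). Components smaller than `min_volume`
#' voxels are removed. Labels are assigned in descending component size;
#' ties break by ascending `(z, y, x)` of the component's minimum
#' coordinate, so a segmentation is fully deterministic.
#'
#' The green channel is never consulted: masking depends on the nuclear
#' marker only.
#'
#' @param grid A [voxel_grid()].
#' @param method `"otsu"` (default; threshold from the nonzero red
#'   histogram) or `"absolute"`.
#' @param threshold Required intensity cutoff when `method = "absolute"`.
#' @param min_volume Minimum component size in voxels (default 30).
#' @return An object of class `nucleus_mask`: list with `labels` (integer
#'   3D array, 0 = background), `table` (per-label voxel count and
#'   centroid), `threshold_used`, `voxel_size`.
#' @examples
#' sim <- generate_stack(synthetic_params(n_pl = 3, n_da = 0,
#'                                        noise_model = "none", seed = 2))
#' m <- segment_nuclei_3d(sim$grid, method = "absolute", threshold = 100)
#' m$table
#' @export
segment_nuclei_3d <- function(grid, method = c("otsu", "absolute"),
                              threshold = NULL, min_volume = 30L) {
  stopifnot(inherits(grid, "voxel_grid"))
  method <- match.arg(method)
  min_volume <- as.integer(min_volume)
  if (min_volume < 1L) stop("`min_volume` must be >= 1")
  red <- grid$red
  if (method == "absolute") {
    if (is.null(threshold)) stop("`threshold` required for method = 'absolute'")
    thr <- as.numeric(threshold)
  } else {
    thr <- otsu_threshold(red[red > 0])
    if (is.na(thr)) {
      # all-zero (or constant) red channel: empty mask, threshold undefined
      return(structure(
        list(labels = array(0L, dim(red)), table = empty_mask_table(),
             threshold_used = NA_real_, voxel_size = grid$voxel_size),
        class = "nucleus_mask"))
    }
  }
  fg <- red >= thr
  raw <- .label_components_3d(fg, 26L)
  rl <- relabel_by_size(raw, min_volume)
  structure(
    list(labels = rl$labels, table = rl$table, threshold_used = thr,
         voxel_size = grid$voxel_size),
    class = "nucleus_mask"
  )
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d nuclei, threshold %s\n",
              nrow(x$table),
              if (is.na(x$threshold_used)) "undefined"
              else format(x$threshold_used, digits = 4)))
  invisible(x)
}

#' Central z-plane of a nucleus
#'
#' The representative 2D plane of a nucleus is the rounded z-centroid of
#' its voxels; a tie at `.5` resolves to the lower plane index.
#'
#' @param mask A `nucleus_mask`.
#' @param label Nucleus label.
#' @return Integer z-plane index (1-based).
#' @export
select_central_plane <- function(mask, label) {
  stopifnot(inherits(mask, "nucleus_mask"))
  assert_label(mask, label)
  cz <- mask$table$centroid_z[mask$table$label == label]
  as.integer(ceiling(cz - 0.5))  # round-half-down
}

# Pixel centres strictly inside a polygon (even-odd rule). `py`, `px` are
# vectors of candidate pixel centres; vertices is the (y, x) matrix.
points_in_polygon <- function(py, px, vertices) {
  ny <- vertices[, 1]; nx <- vertices[, 2]
  n <- length(ny)
  jj <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(py))
  for (i in seq_len(n)) {
    j <- jj[i]
    yi <- ny[i]; xi <- nx[i]; yj <- ny[j]; xj <- nx[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Cytoplasm region of a cell at its outline plane
#'
#' Pixels whose centres lie strictly inside the outline polygon at the
#' outline's z-plane, minus the pixels of the cell's nucleus mask at that
#' plane. The result is guaranteed disjoint from the nucleus.
#'
#' @param outline A [cell_outline()].
#' @param mask A `nucleus_mask` containing the outline's label.
#' @return data.frame of pixel coordinates `y`, `x` (1-based) at plane
#'   `attr(, "z")`.
#' @export
cytoplasm_region <- function(outline, mask) {
  stopifnot(inherits(outline, "cell_outline"), inherits(mask, "nucleus_mask"))
  assert_label(mask, outline$label)
  dims <- dim(mask$labels)
  if (outline$z < 1L || outline$z > dims[1])
    stop(sprintf("outline plane %d outside stack (1..%d)", outline$z, dims[1]))
  v <- outline$vertices
  yr <- max(1L, floor(min(v[, 1]))):min(dims[2], ceiling(max(v[, 1])))
  xr <- max(1L, floor(min(v[, 2]))):min(dims[3], ceiling(max(v[, 2])))
  gy <- rep(yr, times = length(xr))
  gx <- rep(xr, each = length(yr))
  inside <- points_in_polygon(gy, gx, v)
  gy <- gy[inside]; gx <- gx[inside]
  if (length(gy) == 0L)
    stop("outline polygon contains no pixel centres")
  plane <- mask$labels[outline$z, , ]
  in_nuc <- plane[cbind(gy, gx)] == outline$label
  gy2 <- gy[!in_nuc]; gx2 <- gx[!in_nuc]
  if (length(gy2) == 0L)
    stop(sprintf("empty cytoplasm region: outline for label %d lies entirely within the nucleus mask",
                 outline$label))
  out <- data.frame(y = gy2, x = gx2)
  attr(out, "z") <- outline$z
  out
}
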