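# Separable Gaussian smoothing of a 3D array; sigma given per axis in
# voxels. Reflective boundary handling.
gaussian_smooth_3d <- function(img, sigma_vox) {
  smooth_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-half:half)^2) / (2 * sigma^2))
    k <- k / sum(k)
    n <- dim(a)[axis]
    # reflect-pad indices
    idx <- c(rev(seq_len(min(half, n))), seq_len(n),
             rev(n + 1 - seq_len(min(half, n))))
    while (length(idx) < n + 2 * half)  # tiny axes: repeat reflection
      idx <- c(idx[1], idx, idx[length(idx)])
    conv1 <- function(v) {
      vp <- v[idx]
      out <- numeric(n)
      for (t in seq_along(k))
        out <- out + k[t] * vp[(t - 1) + seq_len(n)]
      out
    }
    apply_axis(a, axis, conv1)
  }
  out <- img
  for (ax in 1:3) out <- smooth_axis(out, ax, sigma_vox[ax])
  out
}

# apply a vector function along one axis of a 3D array, preserving shape
apply_axis <- function(a, axis, f) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- apply(m, 2, f)
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

# discrete Laplacian in physical units (second difference per axis divided
# by the squared voxel pitch), replicate boundary
laplacian_3d <- function(img, voxel_size) {
  second_diff <- function(a, axis, h) {
    d <- dim(a)[axis]
    if (d < 3) return(array(0, dim(a)))
    f <- function(v) {
      n <- length(v)
      vp <- c(v[1], v, v[n])
      (vp[1:n] - 2 * v + vp[3:(n + 2)]) / h^2
    }
    apply_axis(a, axis, f)
  }
  second_diff(img, 1, voxel_size[1]) +
    second_diff(img, 2, voxel_size[2]) +
    second_diff(img, 3, voxel_size[3])
}

#' Detect spot-like nuclei by Laplacian-of-Gaussian blob detection
#'
#' Smooths the channel with an anisotropy-aware Gaussian at scale
#' `diameter / 2` (sigma = radius / sqrt(3), the 3D blob-matching scale),
#' computes the scale-normalised negative Laplacian response, and keeps
#' local maxima above threshold with greedy minimum-separation
#' suppression: maxima are accepted in descending response order (ties by
#' ascending `(z, y, x)`) and discarded if within `diameter` micrometres
#' of an accepted spot.
#'
#' @param channel 3D intensity array `[z, y, x]`.
#' @param diameter Expected spot (nucleus) diameter in micrometres.
#' @param intensity_threshold Response threshold relative to the maximum
#'   LoG response (default 0.1), making detection invariant to global
#'   intensity gain. Set an attribute-free absolute threshold via
#'   `absolute = TRUE`.
#' @param voxel_size Micrometres per voxel `(z, y, x)`.
#' @param absolute If TRUE, `intensity_threshold` is an absolute response
#'   cutoff.
#' @param exclude_border Drop maxima within one Gaussian sigma of the
#'   stack border, where the boundary handling of the Laplacian creates
#'   spurious responses (default TRUE).
#' @return data.frame of spot centroids: `z`, `y`, `x` (1-based voxel
#'   coordinates) and `response`, ordered by descending response.
#' @export
detect_spots <- function(channel, diameter, intensity_threshold = 0.1,
                         voxel_size = c(1.0, 0.3, 0.3), absolute = FALSE,
                         exclude_border = TRUE) {
  stopifnot(is.array(channel), length(dim(channel)) == 3L)
  if (diameter <= 0) stop("`diameter` must be > 0")
  if (max(channel) <= 0)
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      response = numeric()))
  sigma_um <- (diameter / 2) / sqrt(3)
  sigma_vox <- sigma_um / voxel_size
  sm <- gaussian_smooth_3d(channel, sigma_vox)
  resp <- -sigma_um^2 * laplacian_3d(sm, voxel_size)
  floor_value <- if (absolute) intensity_threshold else
    intensity_threshold * max(resp)
  idx <- .local_maxima_3d(resp, floor_value)
  if (length(idx) == 0L)
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      response = numeric()))
  zyx <- arrayInd(idx, dim(channel))
  rs <- resp[idx]
  if (exclude_border) {
    b <- pmax(1, ceiling(sigma_vox))
    d <- dim(channel)
    ok <- zyx[, 1] > b[1] & zyx[, 1] <= d[1] - b[1] &
      zyx[, 2] > b[2] & zyx[, 2] <= d[2] - b[2] &
      zyx[, 3] > b[3] & zyx[, 3] <= d[3] - b[3]
    zyx <- zyx[ok, , drop = FALSE]; rs <- rs[ok]
    if (nrow(zyx) == 0L)
      return(data.frame(z = integer(), y = integer(), x = integer(),
                        response = numeric()))
  }
  ord <- order(-rs, zyx[, 1], zyx[, 2], zyx[, 3])
  zyx <- zyx[ord, , drop = FALSE]; rs <- rs[ord]
  pos_um <- sweep(zyx, 2, voxel_size, `*`)
  keep <- logical(nrow(zyx))
  for (i in seq_len(nrow(zyx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt(rowSums((pos_um[keep, , drop = FALSE] -
                          matrix(pos_um[i, ], sum(keep), 3,
                                 byrow = TRUE))^2))
    if (all(dd >= diameter)) keep[i] <- TRUE
  }
  data.frame(z = zyx[keep, 1], y = zyx[keep, 2], x = zyx[keep, 3],
             response = rs[keep])
}

#' Count spots inside a half-open region
#'
#' @param centroids data.frame with `z`, `y`, `x` columns (voxel
#'   coordinates).
#' @param bounds Numeric matrix 3 x 2 (rows z, y, x; columns lower,
#'   upper): lower bound inclusive, upper bound exclusive.
#' @return Integer count.
#' @export
count_in_region <- function(centroids, bounds) {
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 3L, ncol(bounds) == 2L)
  if (any(bounds[, 2] < bounds[, 1])) stop("inverted region bounds")
  if (nrow(centroids) == 0L) return(0L)
  inb <- centroids$z >= bounds[1, 1] & centroids$z < bounds[1, 2] &
    centroids$y >= bounds[2, 1] & centroids$y < bounds[2, 2] &
    centroids$x >= bounds[3, 1] & centroids$x < bounds[3, 2]
  sum(inb)
}

#' Per-embryo vessel-fragment percentage across somites
#'
#' Each embryo is scored per somite as present (1) or absent (0); the
#' per-embryo percentage is `100 * sum(present) / n_somites`, and the
#' group summary is the mean and SEM of the per-embryo percentages.
#'
#' @param scores data.frame with `embryo_id`, `somite_index`, `present`
#'   (0/1) and optionally `group`.
#' @return A list with `per_embryo` (data.frame `embryo_id`, `group`,
#'   `percent`) and `summary` (one [group_summary()] row per group).
#' @examples
#' sc <- expand.grid(embryo_id = c("e1", "e2"), somite_index = 1:6)
#' sc$present <- 1L
#' sc$group <- "sibling"
#' fragment_percentage(sc)$summary  # 100% +/- 0
#' @export
fragment_percentage <- function(scores) {
  need <- c("embryo_id", "somite_index", "present")
  stopifnot(all(need %in% names(scores)))
  if (!all(scores$present %in% c(0L, 1L)))
    stop("`present` must be 0 or 1")
  if (!"group" %in% names(scores)) scores$group <- "all"
  ns <- tapply(scores$somite_index, scores$embryo_id,
               function(s) length(unique(s)))
  if (length(unique(ns)) != 1L)
    stop("every embryo must have the same number of scored somites")
  n_somites <- ns[[1]]
  agg <- stats::aggregate(present ~ embryo_id + group, scores, sum)
  agg$percent <- 100 * agg$present / n_somites
  per_embryo <- agg[order(agg$group, agg$embryo_id),
                    c("embryo_id", "group", "percent")]
  rownames(per_embryo) <- NULL
  groups <- unique(per_embryo$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    gs <- group_summary(per_embryo$percent[per_embryo$group == g])
    data.frame(group = g, n = gs$n, mean = gs$mean, sem = gs$sem)
  }))
  list(per_embryo = per_embryo, summary = summ)
}

#' Classify transplant graft size from its somite span
#'
#' Grafts spanning 1 somite are small, 3 somites medium, 4-5 somites
#' large. The published class boundaries overlap at a span of 2
#' ("small 1-2", "medium 2-3"); a span of exactly 2 is resolved to
#' medium, with a warning surfacing the overlap. Spans above 5 classify
#' as large with a warning. Single-cell grafts must be excluded upstream.
#'
#' @param span Integer somite span, `>= 1`.
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
graft_size_class <- function(span) {
  span <- as.integer(span)
  if (is.na(span) || span < 1L) stop("`span` must be an integer >= 1")
  if (span == 1L) return("small")
  if (span == 2L) {
    warning("span 2 lies in the overlapping small/medium boundary; classified as medium")
    return("medium")
  }
  if (span == 3L) return("medium")
  if (span <= 5L) return("large")
  warning(sprintf("span %d exceeds the large class (4-5 somites); classified as large", span))
  "large"
}

#' Frequency of embryos whose graft contributes to a vessel type
#'
#' @param grafts data.frame with `embryo_id` and logical (or 0/1) columns
#'   `arterial`, `venous`, `lymphatic`.
#' @param vessel One of `"arterial"`, `"venous"`, `"lymphatic"`.
#' @return A list: `percent` (of embryos contributing), `k` (count),
#'   `n` (total embryos).
#' @examples
#' g <- data.frame(embryo_id = 1:24, lymphatic = c(rep(1, 2), rep(0, 22)),
#'                 arterial = 1, venous = 1)
#' contribution_frequency(g, "lymphatic")$percent  # 2/24 = 8.3%
#' @export
contribution_frequency <- function(grafts,
                                   vessel = c("arterial", "venous",
                                              "lymphatic")) {
  vessel <- match.arg(vessel)
  if (nrow(grafts) == 0L) stop("no graft records supplied")
  if (!vessel %in% names(grafts))
    stop(sprintf("column '%s' missing from graft records", vessel))
  contrib <- as.logical(grafts[[vessel]])
  k <- sum(contrib)
  n <- nrow(grafts)
  list(percent = 100 * k / n, k = k, n = n)
}
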