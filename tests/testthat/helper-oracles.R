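# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (no Rcpp, no vectorised shortcuts) so tests
# compare two independent routes to the same quantity.

# Pure-R 26-connectivity flood fill; returns an integer label array in
# first-encounter order. Slow but trivially correct.
oracle_components <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  nbh <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nbh <- nbh[rowSums(abs(nbh)) > 0, ]
  cur <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!fg[z, y, x] || lab[z, y, x] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(z, y, x), ncol = 3)
    lab[z, y, x] <- cur
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nbh))) {
        w <- v + nbh[k, ]
        if (any(w < 1) || any(w > d)) next
        if (fg[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}

# Explicit-loop mean of `img` over voxels where `labels == lab`
oracle_masked_mean <- function(img, labels, lab, plane = NULL) {
  d <- dim(img)
  total <- 0; n <- 0L
  zs <- if (is.null(plane)) seq_len(d[1]) else plane
  for (z in zs) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (labels[z, y, x] == lab) {
      total <- total + img[z, y, x]
      n <- n + 1L
    }
  }
  if (n == 0L) stop("empty selection")
  total / n
}

# Build a nucleus_mask directly from a label array (bypasses segmentation)
make_mask <- function(labels, voxel_size = c(1, 0.3, 0.3),
                      threshold = NA_real_) {
  labs <- sort(unique(labels[labels > 0]))
  tab <- do.call(rbind, lapply(labs, function(l) {
    idx <- which(labels == l)
    zyx <- arrayInd(idx, dim(labels))
    data.frame(label = l, voxels = length(idx),
               centroid_z = mean(zyx[, 1]), centroid_y = mean(zyx[, 2]),
               centroid_x = mean(zyx[, 3]))
  }))
  if (is.null(tab))
    tab <- data.frame(label = integer(), voxels = integer(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric())
  structure(list(labels = labels, table = tab, threshold_used = threshold,
                 voxel_size = voxel_size),
            class = "nucleus_mask")
}

# Deterministic vectors whose sample Pearson correlation is exactly `r`
make_corr_data <- function(r, n) {
  x <- as.numeric(seq_len(n))
  v <- sin(seq_len(n))
  e <- stats::residuals(stats::lm(v ~ x))
  xs <- as.numeric(scale(x))
  es <- as.numeric(scale(e))
  list(x = x, y = r * xs + sqrt(1 - r^2) * es)
}

# Small, fast generator presets used across tests
small_params <- function(n_pl = 3, n_da = 0, seed = 1,
                         noise_model = "none", ...) {
  synthetic_params(stack_shape = c(12L, 48L, 160L),
                   voxel_size = c(1, 0.3, 0.3),
                   n_pl = n_pl, n_da = n_da,
                   nucleus_radius = c(2.0, 0.1),
                   red_level = 200, cyto_level = 100,
                   noise_model = noise_model, seed = seed, ...)
}

# Circle outline polygon (in voxel coordinates) around a point, radius in um
circle_outline <- function(label, z, cy, cx, radius_um,
                           voxel_size = c(1, 0.3, 0.3), n_vert = 32) {
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  cell_outline(label, z,
               cbind(cy + radius_um * sin(th) / voxel_size[2],
                     cx + radius_um * cos(th) / voxel_size[3]))
}

# Match mask labels to ground-truth rows by nearest centroid (in um)
match_truth <- function(mask, truth, voxel_size = c(1, 0.3, 0.3)) {
  tb <- mask$table
  vapply(seq_len(nrow(tb)), function(i) {
    d <- sqrt(((truth$z - tb$centroid_z[i]) * voxel_size[1])^2 +
              ((truth$y - tb$centroid_y[i]) * voxel_size[2])^2 +
              ((truth$x - tb$centroid_x[i]) * voxel_size[3])^2)
    which.min(d)
  }, 0L)
}
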