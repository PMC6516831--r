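#' Parameters for the synthetic embryo generator
#'
#' Describes a simulated two-channel trunk-imaging experiment: lymphatic
#' progenitor (PL) nuclei placed along a horizontal-myoseptum band and
#' dorsal-aorta (DA) reference nuclei in a ventral row. Each cell is a
#' spherical nucleus in micrometre space (an ellipsoid on the anisotropic
#' voxel grid) carrying uniform nuclear red marker, uniform nuclear green
#' reporter at concentration `c_nuc`, and a spherical-shell cytoplasm of
#' uniform green `c_cyto`. The nuclear partition `k = c_nuc / c_cyto` is
#' drawn per cell from `partition_range`.
#'
#' @param stack_shape Integer voxel counts `(z, y, x)`.
#' @param voxel_size Micrometres per voxel `(z, y, x)`.
#' @param n_pl,n_da Number of PL-class and DA-class nuclei (each `>= 0`).
#' @param nucleus_radius Mean and sd of the nuclear radius in micrometres.
#' @param red_level Mean nuclear mCherry intensity (arbitrary units; with
#'   Poisson noise this is the expected photon count per voxel).
#' @param partition_range `(k_min, k_max)`: the per-cell nuclear/cytoplasmic
#'   green concentration ratio is sampled uniformly on this interval.
#' @param cyto_level Cytoplasmic green concentration.
#' @param shell_um Cytoplasm shell thickness in micrometres.
#' @param noise_model `"none"` or `"poisson"` (shot noise on the noiseless
#'   expectation image; no read noise).
#' @param background Constant expectation added to both channels everywhere
#'   (autofluorescence floor). Default 0 so nuclear ratios recover the true
#'   `c_nuc / red_level` exactly; set a small positive value to give
#'   histogram-based thresholding a background mode to separate.
#' @param bleach_rate Per-frame exponential decay constant(s), `>= 0`.
#'   A scalar bleaches both channels equally; a length-2 vector
#'   `(green, red)` bleaches them separately.
#' @param drift Voxels per frame `(y, x)` of rigid frame-to-frame drift.
#' @param division_times Optional data.frame with columns `cell_id`,
#'   `frame`: at `frame` the named cell is replaced by two daughters.
#' @param n_frames Number of time points (`>= 1`; time-lapse requires 2).
#' @param seed Integer RNG seed; identical params + seed give bit-identical
#'   output.
#' @return An object of class `synthetic_params`.
#' @examples
#' p <- synthetic_params(n_pl = 5, n_da = 3, seed = 1)
#' @export
synthetic_params <- function(stack_shape = c(32L, 96L, 288L),
                             voxel_size = c(1.0, 0.3, 0.3),
                             n_pl = 8L, n_da = 6L,
                             nucleus_radius = c(3.0, 0.3),
                             red_level = 200,
                             partition_range = c(0.5, 3.0),
                             cyto_level = 100,
                             shell_um = 2.0,
                             noise_model = c("poisson", "none"),
                             background = 0,
                             bleach_rate = 0,
                             drift = c(0, 0),
                             division_times = NULL,
                             n_frames = 1L,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stack_shape <- as.integer(stack_shape)
  stopifnot(length(stack_shape) == 3L, all(stack_shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  n_pl <- as.integer(n_pl); n_da <- as.integer(n_da)
  if (n_pl < 0L || n_da < 0L) stop("cell counts must be >= 0")
  stopifnot(length(nucleus_radius) == 2L, nucleus_radius[1] > 0,
            nucleus_radius[2] >= 0)
  if (red_level <= 0) stop("`red_level` must be > 0")
  stopifnot(length(partition_range) == 2L)
  if (partition_range[1] > partition_range[2])
    stop("`partition_range` must satisfy k_min <= k_max")
  if (any(partition_range <= 0)) stop("partition ratios must be > 0")
  if (cyto_level <= 0) stop("`cyto_level` must be > 0")
  if (shell_um <= 0) stop("`shell_um` must be > 0")
  if (background < 0) stop("`background` must be >= 0")
  if (length(bleach_rate) == 1L) bleach_rate <- rep(bleach_rate, 2L)
  stopifnot(length(bleach_rate) == 2L, all(bleach_rate >= 0))
  drift <- as.numeric(drift)
  stopifnot(length(drift) == 2L)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("`n_frames` must be >= 1")
  if (!is.null(division_times)) {
    division_times <- as.data.frame(division_times)
    if (!all(c("cell_id", "frame") %in% names(division_times)))
      stop("`division_times` needs columns cell_id, frame")
    if (any(division_times$frame >= n_frames))
      stop("division time >= n_frames")
    if (any(division_times$frame < 1))
      stop("division frame must be >= 1 (frames are 0-based; parents must exist at frame 0)")
  }
  structure(
    list(stack_shape = stack_shape, voxel_size = voxel_size,
         n_pl = n_pl, n_da = n_da, nucleus_radius = nucleus_radius,
         red_level = red_level, partition_range = partition_range,
         cyto_level = cyto_level, shell_um = shell_um,
         noise_model = noise_model, background = background,
         bleach_rate = bleach_rate,
         drift = drift, division_times = division_times,
         n_frames = n_frames, seed = as.integer(seed)),
    class = "synthetic_params"
  )
}

# Run `expr` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sample non-overlapping cell positions and intensities in micrometre space.
# Shells are kept disjoint from every other cell's shell so the uniform
# cytoplasm value is never corrupted by a neighbour. RNG state is the
# caller's responsibility.
sample_cells <- function(params) {
  p <- params
  n_total <- p$n_pl + p$n_da
  if (n_total == 0L)
    return(data.frame(cell_id = integer(), class = character(),
                      z = numeric(), y = numeric(), x = numeric(),
                      radius_um = numeric(), c_nuc = numeric(),
                      c_cyto = numeric(), k = numeric(),
                      red_level = numeric(), parent_id = integer()))
  dimz <- p$stack_shape
  vs <- p$voxel_size
  # extent reserved per cell so nucleus + shell fit inside the stack
  classes <- c(rep("PL", p$n_pl), rep("DA", p$n_da))
  radius <- pmax(0.5, stats::rnorm(n_total, p$nucleus_radius[1],
                                   p$nucleus_radius[2]))
  k <- stats::runif(n_total, p$partition_range[1], p$partition_range[2])
  c_cyto <- rep(p$cyto_level, n_total)
  c_nuc <- k * c_cyto

  # PL band at ~35% of usable y, DA reference row at ~75%; x slots with
  # jitter, DA row staggered half a slot so the rows interleave. Margins
  # keep nucleus + shell inside the stack for typical radii.
  margin <- (p$nucleus_radius[1] + 2 * p$nucleus_radius[2]) / vs
  place_row <- function(n, y_frac, ids, phase) {
    if (n == 0L) return(NULL)
    usable_x <- dimz[3] - 1 - 2 * margin[3]
    usable_y <- dimz[2] - 1 - 2 * margin[2]
    if (usable_x <= 0 || usable_y <= 0)
      stop("stack too small for the requested nucleus radius")
    data.frame(
      idx = ids,
      z0 = (dimz[1] + 1) / 2,
      y0 = 1 + margin[2] + y_frac * usable_y,
      x0 = 1 + margin[3] + usable_x * (seq_len(n) - 0.5 + phase) / n
    )
  }
  anchors <- rbind(place_row(p$n_pl, 0.35, seq_len(p$n_pl), 0),
                   place_row(p$n_da, 0.75, p$n_pl + seq_len(p$n_da), 0.25))
  anchors <- anchors[order(anchors$idx), , drop = FALSE]

  pos <- matrix(NA_real_, n_total, 3)  # voxel coords (z, y, x)
  for (i in seq_len(n_total)) {
    r_i <- radius[i]   # the nucleus must not clip; the shell may
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      cand <- c(anchors$z0[i] + stats::rnorm(1, 0, 1.0 / vs[1]),
                anchors$y0[i] + stats::rnorm(1, 0, 1.5 / vs[2]),
                anchors$x0[i] + stats::rnorm(1, 0, 1.0 / vs[3]))
      # keep nucleus + shell fully inside the stack
      lo_um <- (cand - 1) * vs
      hi_um <- (dimz - cand) * vs
      if (any(lo_um < r_i) || any(hi_um < r_i)) next
      # a nucleus may not touch another nucleus or sit inside its shell
      clash <- FALSE
      for (j in seq_len(i - 1L)) {
        d_um <- sqrt(sum(((cand - pos[j, ]) * vs)^2))
        if (d_um <= radius[i] + radius[j] + p$shell_um) { clash <- TRUE; break }
      }
      if (!clash) { pos[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) {
      if (all((dimz - 1) * vs < 2 * r_i))
        stop(sprintf("stack too small to place cell %d (radius %.2f um)",
                     i, radius[i]))
      stop(sprintf(
        "could not place cell %d without overlap after 100 attempts (colliding with cells %s)",
        i, paste(seq_len(i - 1L), collapse = ",")))
    }
  }
  data.frame(
    cell_id = seq_len(n_total), class = classes,
    z = pos[, 1], y = pos[, 2], x = pos[, 3],
    radius_um = radius, c_nuc = c_nuc, c_cyto = c_cyto, k = k,
    red_level = rep(p$red_level, n_total),
    parent_id = rep(NA_integer_, n_total)
  )
}

# Render one frame from a cell table. `scale` is the per-channel bleach
# factor c(green, red). Returns a voxel_grid.
render_cells <- function(cells, params, frame_index = 0L,
                         scale = c(1, 1)) {
  dimz <- params$stack_shape
  vs <- params$voxel_size
  green <- array(0, dim = dimz)
  red <- array(0, dim = dimz)
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    r <- ce$radius_um
    rt <- r + params$shell_um
    zr <- max(1L, floor(ce$z - rt / vs[1])):min(dimz[1], ceiling(ce$z + rt / vs[1]))
    yr <- max(1L, floor(ce$y - rt / vs[2])):min(dimz[2], ceiling(ce$y + rt / vs[2]))
    xr <- max(1L, floor(ce$x - rt / vs[3])):min(dimz[3], ceiling(ce$x + rt / vs[3]))
    dz2 <- ((zr - ce$z) * vs[1])^2
    dy2 <- ((yr - ce$y) * vs[2])^2
    dx2 <- ((xr - ce$x) * vs[3])^2
    d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    nuc <- d2 <= r^2
    shell <- d2 > r^2 & d2 <= rt^2
    gbox <- green[zr, yr, xr, drop = FALSE]
    rbox <- red[zr, yr, xr, drop = FALSE]
    gbox[nuc] <- gbox[nuc] + ce$c_nuc
    gbox[shell] <- gbox[shell] + ce$c_cyto
    rbox[nuc] <- rbox[nuc] + ce$red_level
    green[zr, yr, xr] <- gbox
    red[zr, yr, xr] <- rbox
  }
  green <- green * scale[1] + params$background
  red <- red * scale[2] + params$background
  if (params$noise_model == "poisson") {
    green[] <- stats::rpois(length(green), green)
    red[] <- stats::rpois(length(red), red)
  }
  voxel_grid(green, red, voxel_size = vs, frame_index = frame_index)
}

#' Generate a synthetic two-channel stack with ground truth
#'
#' Renders the cell population described by `params` into a single-frame
#' `voxel_grid` and returns the per-cell ground truth alongside it.
#'
#' @param params A [synthetic_params()] object.
#' @return A list with elements `grid` (a [voxel_grid()]) and `truth`
#'   (data.frame: `cell_id`, `class`, `frame`, `z`, `y`, `x` voxel
#'   coordinates (1-based, possibly fractional), `radius_um`, `c_nuc`,
#'   `c_cyto`, `k`, `red_level`, `parent_id`).
#' @examples
#' sim <- generate_stack(synthetic_params(n_pl = 3, n_da = 2,
#'                                        noise_model = "none", seed = 7))
#' sim$truth$k
#' @export
generate_stack <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  with_seed(params$seed, {
    cells <- sample_cells(params)
    grid <- render_cells(cells, params, frame_index = 0L)
    truth <- cbind(cells[, "cell_id", drop = FALSE],
                   class = cells$class, frame = rep(0L, nrow(cells)),
                   cells[, c("z", "y", "x", "radius_um", "c_nuc",
                             "c_cyto", "k", "red_level", "parent_id")])
    list(grid = grid, truth = truth)
  })
}

#' Generate a synthetic time-lapse with drift, bleaching and divisions
#'
#' Frames share one cell population; per frame `f` (0-based) every centroid
#' is translated by `drift * f` voxels in `(y, x)` and intensities are
#' multiplied by `exp(-bleach_rate * f)` per channel. A division listed in
#' `division_times` removes the parent at its stated frame and renders two
#' daughter nuclei (displaced along x, radius reduced to conserve volume)
#' from that frame on.
#'
#' @param params A [synthetic_params()] with `n_frames >= 2`.
#' @return A list with `grids` (list of [voxel_grid()], one per frame) and
#'   `truth` (one row per cell per frame, with `parent_id` set on
#'   daughters).
#' @export
generate_timelapse <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  if (params$n_frames < 2L) stop("`n_frames` must be >= 2 for a time-lapse")
  with_seed(params$seed, {
    base <- sample_cells(params)
    div <- params$division_times
    if (!is.null(div) && !all(div$cell_id %in% base$cell_id))
      stop("division cell_id not present in the generated population")
    # daughters created once, reused from their birth frame on
    daughters <- NULL
    if (!is.null(div)) {
      rows <- lapply(seq_len(nrow(div)), function(i) {
        par <- base[base$cell_id == div$cell_id[i], ]
        off_vx <- 0.9 * par$radius_um / params$voxel_size[3]
        rd <- par$radius_um / 2^(1 / 3)
        ids <- max(base$cell_id) + 2L * (i - 1L) + 1:2
        d <- par[c(1, 1), ]
        d$cell_id <- ids
        d$x <- par$x + c(-off_vx, off_vx)
        d$radius_um <- rd
        d$parent_id <- par$cell_id
        d$birth <- div$frame[i]
        d
      })
      daughters <- do.call(rbind, rows)
    }
    grids <- vector("list", params$n_frames)
    truth_rows <- vector("list", params$n_frames)
    for (f in 0:(params$n_frames - 1L)) {
      alive <- base
      if (!is.null(div)) {
        gone <- div$cell_id[div$frame <= f]
        alive <- alive[!alive$cell_id %in% gone, , drop = FALSE]
        born <- daughters[daughters$birth <= f, , drop = FALSE]
        if (nrow(born) > 0)
          alive <- rbind(alive, born[, names(alive), drop = FALSE])
      }
      alive$y <- alive$y + params$drift[1] * f
      alive$x <- alive$x + params$drift[2] * f
      scale <- exp(-params$bleach_rate * f)
      grids[[f + 1L]] <- render_cells(alive, params, frame_index = f,
                                      scale = scale)
      truth_rows[[f + 1L]] <- cbind(
        alive[, "cell_id", drop = FALSE], class = alive$class,
        frame = rep(f, nrow(alive)),
        alive[, c("z", "y", "x", "radius_um", "c_nuc", "c_cyto", "k",
                  "red_level", "parent_id")])
    }
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(grids = grids, truth = truth)
  })
}

#' Simulate per-embryo cohort count tables
#'
#' Produces count tables shaped like per-embryo cell counts across somites,
#' for feeding the statistics layer with known group differences.
#'
#' @param group_specs A list of group specifications, each a list (or
#'   one-row data.frame) with `label`, `mean`, `sd` (ignored for Poisson),
#'   `n`, and `distribution` (`"normal-rounded-at-0"` or `"poisson"`).
#' @param seed Integer seed.
#' @return data.frame with columns `embryo_id`, `group`, `count`.
#' @examples
#' tab <- generate_cohort_counts(list(
#'   list(label = "sibling", mean = 37, sd = 6.3, n = 11,
#'        distribution = "normal-rounded-at-0"),
#'   list(label = "mutant", mean = 8, sd = 6.3, n = 11,
#'        distribution = "normal-rounded-at-0")), seed = 1)
#' aggregate(count ~ group, tab, mean)
#' @export
generate_cohort_counts <- function(group_specs, seed = 1L) {
  stopifnot(is.list(group_specs), length(group_specs) >= 1L)
  with_seed(seed, {
    rows <- lapply(group_specs, function(g) {
      g <- as.list(g)
      stopifnot(!is.null(g$label), !is.null(g$mean), !is.null(g$n))
      n <- as.integer(g$n)
      if (n < 2L) stop("each group needs n >= 2")
      dist <- if (is.null(g$distribution)) "normal-rounded-at-0"
              else as.character(g$distribution)
      counts <- switch(dist,
        "normal-rounded-at-0" = pmax(0, round(stats::rnorm(n, g$mean, g$sd))),
        "poisson" = stats::rpois(n, g$mean),
        stop(sprintf("unknown distribution '%s'", dist))
      )
      data.frame(embryo_id = paste0(g$label, "_", seq_len(n)),
                 group = g$label, count = counts)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
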