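toy_cube <- function() {
  # 2x2x2 nucleus with green {2,2,4,4,2,2,4,4} and red uniform 2
  lab <- array(0L, dim = c(4, 4, 4))
  lab[2:3, 2:3, 2:3] <- 1L
  green <- array(0, dim = c(4, 4, 4))
  green[2:3, 2:3, 2:3] <- c(2, 2, 4, 4, 2, 2, 4, 4)
  red <- array(0, dim = c(4, 4, 4))
  red[2:3, 2:3, 2:3] <- 2
  list(grid = voxel_grid(green, red), mask = make_mask(lab))
}

test_that("nuclear means match hand sums and the constant-field identity", {
  tc <- toy_cube()
  expect_equal(nuclear_mean_intensity(tc$grid, tc$mask, 1L, "green"), 3.0)
  expect_equal(nuclear_mean_intensity(tc$grid, tc$mask, 1L, "red"), 2.0)
  expect_equal(nuclear_ratio_3d(tc$grid, tc$mask, 1L), 1.5)
  # identical channels give exactly 1
  g2 <- voxel_grid(tc$grid$red, tc$grid$red)
  expect_equal(nuclear_ratio_3d(g2, tc$mask, 1L), 1.0)
})

test_that("3D mean equals the volume-weighted mean of per-plane means", {
  set.seed(7)
  sim <- generate_stack(small_params(n_pl = 2, seed = 3))
  grid <- voxel_grid(array(stats::runif(length(sim$grid$green), 0, 10),
                           dim(sim$grid$green)),
                     sim$grid$red)
  m <- segment_nuclei_3d(grid, method = "absolute", threshold = 100)
  for (l in m$table$label) {
    planes <- which(apply(m$labels == l, 1, any))
    per_plane <- vapply(planes, function(z)
      nuclear_mean_intensity(grid, m, l, "green", plane = z), 0)
    weights <- vapply(planes, function(z) sum(m$labels[z, , ] == l), 0)
    expect_equal(nuclear_mean_intensity(grid, m, l, "green"),
                 sum(per_plane * weights) / sum(weights),
                 tolerance = 1e-12)
  }
})

test_that("2D ratio equals 3D for uniform nuclei and scales with a plane gradient", {
  tc <- toy_cube()
  guni <- voxel_grid(array(5, dim = c(4, 4, 4)), array(2, dim = c(4, 4, 4)))
  expect_equal(nuclear_ratio_2d(guni, tc$mask, 1L),
               nuclear_ratio_3d(guni, tc$mask, 1L))

  # nucleus on planes 2..4, green doubled on the central plane (3)
  lab <- array(0L, dim = c(6, 5, 5))
  lab[2:4, 2:4, 2:4] <- 1L
  green <- array(0, dim = c(6, 5, 5))
  green[2:4, 2:4, 2:4] <- 1
  green[3, 2:4, 2:4] <- 2
  red <- array(0, dim = c(6, 5, 5)); red[2:4, 2:4, 2:4] <- 1
  g <- voxel_grid(green, red)
  m <- make_mask(lab)
  expect_equal(select_central_plane(m, 1L), 3L)
  r2d <- nuclear_ratio_2d(g, m, 1L)
  r_other <- nuclear_mean_intensity(g, m, 1L, "green", plane = 2) /
    nuclear_mean_intensity(g, m, 1L, "red", plane = 2)
  expect_equal(r2d, 2 * r_other)
})

test_that("empty central plane raises an empty-measurement error", {
  # pathological mask: centroid plane holds no voxels of the label
  lab <- array(0L, dim = c(7, 6, 6))
  lab[2, 2:4, 2:4] <- 1L
  lab[6, 2:4, 2:4] <- 1L   # two slabs, centroid z = 4 is empty
  m <- make_mask(lab)
  g <- voxel_grid(array(1, dim = c(7, 6, 6)), array(1, dim = c(7, 6, 6)))
  expect_error(nuclear_ratio_2d(g, m, 1L), "no voxels at plane")
})

test_that("undefined ratios error rather than returning infinity", {
  lab <- array(0L, dim = c(3, 3, 3)); lab[2, 2, 2] <- 1L
  g <- voxel_grid(array(1, dim = c(3, 3, 3)), array(0, dim = c(3, 3, 3)))
  expect_error(nuclear_ratio_3d(g, make_mask(lab), 1L), "undefined ratio")
})

test_that("nc_ratio recovers the true nuclear partition on a clean cell", {
  p <- small_params(n_pl = 1, seed = 21, partition_range = c(2.5, 2.5))
  sim <- generate_stack(p)
  m <- segment_nuclei_3d(sim$grid, method = "absolute", threshold = 100)
  tru <- sim$truth[1, ]
  zc <- select_central_plane(m, 1L)
  outl <- circle_outline(1L, zc, tru$y, tru$x,
                         tru$radius_um + 0.75 * p$shell_um)
  expect_equal(nc_ratio(sim$grid, m, outl), 2.5, tolerance = 1e-9)

  # uniform cell: nucleus and cytoplasm at the same level -> exactly 1
  pu <- small_params(n_pl = 1, seed = 21, partition_range = c(1, 1))
  simu <- generate_stack(pu)
  mu <- segment_nuclei_3d(simu$grid, method = "absolute", threshold = 100)
  outu <- circle_outline(1L, select_central_plane(mu, 1L),
                         simu$truth$y[1], simu$truth$x[1],
                         simu$truth$radius_um[1] + 0.75 * pu$shell_um)
  expect_equal(nc_ratio(simu$grid, mu, outu), 1.0, tolerance = 1e-9)
})

test_that("gain invariance: common gain cancels, green-only gain scales", {
  p <- small_params(n_pl = 1, n_da = 0, seed = 13,
                    partition_range = c(2, 2))
  sim <- generate_stack(p)
  m <- segment_nuclei_3d(sim$grid, method = "absolute", threshold = 100)
  tru <- sim$truth[1, ]
  outl <- circle_outline(1L, select_central_plane(m, 1L), tru$y, tru$x,
                         tru$radius_um + 0.75 * p$shell_um)
  base <- c(nuclear_ratio_3d(sim$grid, m, 1L),
            nuclear_ratio_2d(sim$grid, m, 1L),
            nc_ratio(sim$grid, m, outl))
  for (gain in c(0.5, 3)) {
    both <- voxel_grid(sim$grid$green * gain, sim$grid$red * gain)
    mb <- segment_nuclei_3d(both, method = "absolute",
                            threshold = 100 * gain)
    got_both <- c(nuclear_ratio_3d(both, mb, 1L),
                  nuclear_ratio_2d(both, mb, 1L),
                  nc_ratio(both, mb, outl))
    expect_equal(got_both, base, tolerance = 1e-12)
    # green-only gain scales the green/red ratios by g but cancels in the
    # N/C ratio, which is a green/green quotient
    green_only <- voxel_grid(sim$grid$green * gain, sim$grid$red)
    got_green <- c(nuclear_ratio_3d(green_only, m, 1L),
                   nuclear_ratio_2d(green_only, m, 1L),
                   nc_ratio(green_only, m, outl))
    expect_equal(got_green, c(base[1:2] * gain, base[3]),
                 tolerance = 1e-12)
  }
})

test_that("da_normalize divides by the reference average deterministically", {
  pl <- data.frame(embryo_id = "e1", cell_id = 1,
                   mean_green_nuc_3d = 30)
  da <- data.frame(embryo_id = "e1", cell_id = 2:7,
                   mean_green_nuc_3d = c(10, 20, 30, 20, 10, 30))
  out <- da_normalize(pl, da)
  expect_equal(out$da_norm, 1.5)
  expect_equal(attr(out, "da_reference_mean"), 20)
  expect_equal(attr(out, "da_cells"), 2:7)

  # PL equal to the reference average -> exactly 1
  pl2 <- data.frame(embryo_id = "e1", cell_id = 1,
                    mean_green_nuc_3d = 20)
  expect_equal(da_normalize(pl2, da)$da_norm, 1)

  # n_ref respects ascending cell_id order
  da_shuffled <- da[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(da_normalize(pl, da_shuffled, n_ref = 3)$da_norm,
               30 / mean(c(10, 20, 30)))

  expect_error(da_normalize(pl, da[1:2, ]), "insufficient reference")
  expect_error(da_normalize(pl, transform(da, embryo_id = "e2")),
               "mixed embryo ids")
  expect_error(da_normalize(pl, da, n_ref = 2), "n_ref")
})

test_that("heatmap is the masked maximum projection", {
  lab <- array(0L, dim = c(4, 8, 8))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[2:3, 6:7, 6:7] <- 2L
  green <- array(0, dim = c(4, 8, 8))
  green[2:3, 2:3, 2:3] <- 10
  green[2:3, 6:7, 6:7] <- 100
  green[1, , ] <- 500                       # outside any nucleus
  red <- array(0, dim = c(4, 8, 8)); red[lab > 0] <- 1
  g <- voxel_grid(green, red)
  hm <- render_heatmap(g, make_mask(lab))
  expect_equal(dim(hm$image), c(8, 8))
  expect_equal(hm$image[2, 2], 10)
  expect_equal(hm$image[6, 6], 100)
  expect_equal(hm$image[1, 1], 0)           # mask removed the bright plane
  expect_equal(hm$limits, c(0, 100))
  # masked projection never exceeds the unmasked one
  unmasked <- apply(green, c(2, 3), max)
  expect_true(all(hm$image <= unmasked))
  # empty mask warns and is blank
  expect_warning(
    hm0 <- render_heatmap(g, make_mask(array(0L, dim = c(4, 8, 8)))),
    "empty mask")
  expect_true(all(hm0$image == 0))
  # PNG writer produces the file and its colour-scale sidecar
  png_path <- tempfile(fileext = ".png")
  write_heatmap_png(hm, png_path)
  expect_true(file.exists(png_path))
  side <- jsonlite::read_json(paste0(png_path, ".json"),
                              simplifyVector = TRUE)
  expect_equal(side$limits, c(0, 100))
  unlink(c(png_path, paste0(png_path, ".json")))
})

test_that("measure_cells produces a tidy row per nucleus with NA for undefined", {
  sim <- generate_stack(small_params(n_pl = 3, seed = 14))
  m <- segment_nuclei_3d(sim$grid, method = "absolute", threshold = 100)
  meas <- measure_cells(sim$grid, m, embryo_id = "emb7")
  expect_equal(nrow(meas), 3L)
  expect_equal(meas$embryo_id, rep("emb7", 3))
  hit <- match_truth(m, sim$truth)
  expect_equal(meas$ratio_3d,
               sim$truth$c_nuc[hit] / sim$truth$red_level[hit],
               tolerance = 1e-12)
  expect_true(all(is.finite(meas$ratio_2d)))
})
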