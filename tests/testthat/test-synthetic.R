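test_that("empty population gives a background-only stack", {
  sim <- generate_stack(small_params(n_pl = 0, n_da = 0))
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(sim$grid$green == 0))
  expect_true(all(sim$grid$red == 0))
})

test_that("identical params and seed give bit-identical output", {
  p <- small_params(n_pl = 3, n_da = 2, seed = 11,
                    noise_model = "poisson")
  a <- generate_stack(p)
  b <- generate_stack(p)
  expect_identical(a$grid$green, b$grid$green)
  expect_identical(a$grid$red, b$grid$red)
  expect_identical(a$truth, b$truth)
})

test_that("noise-free rendering recovers per-cell truth by brute force", {
  sim <- generate_stack(small_params(n_pl = 5, seed = 4))
  fg <- sim$grid$red > 0
  lab <- oracle_components(fg)
  expect_equal(max(lab), 5L)
  mask <- make_mask(lab)
  hit <- match_truth(mask, sim$truth)
  expect_equal(sort(hit), 1:5)
  for (i in seq_len(5)) {
    tru <- sim$truth[hit[i], ]
    g <- oracle_masked_mean(sim$grid$green, lab, mask$table$label[i])
    r <- oracle_masked_mean(sim$grid$red, lab, mask$table$label[i])
    expect_equal(g / r, tru$c_nuc / tru$red_level, tolerance = 1e-12)
    expect_equal(tru$k, tru$c_nuc / tru$c_cyto, tolerance = 1e-12)
  }
})

test_that("parameter validation rejects bad inputs", {
  expect_error(synthetic_params(partition_range = c(3, 1)), "k_min <= k_max")
  expect_error(synthetic_params(bleach_rate = -1))
  expect_error(synthetic_params(n_frames = 2,
                                division_times = data.frame(cell_id = 1,
                                                            frame = 2)),
               ">= n_frames")
  expect_error(generate_stack(
    synthetic_params(stack_shape = c(4L, 8L, 8L), n_pl = 2, n_da = 0,
                     noise_model = "none")),
    "too small|overlap")
})

test_that("static movie repeats frame 0 exactly", {
  p <- small_params(n_pl = 2, seed = 6, n_frames = 4)
  tl <- generate_timelapse(p)
  for (f in 2:4) {
    expect_identical(tl$grids[[f]]$green, tl$grids[[1]]$green)
    expect_identical(tl$grids[[f]]$red, tl$grids[[1]]$red)
  }
})

test_that("bleaching follows the closed-form exponential", {
  b <- 0.25
  tl <- generate_timelapse(small_params(n_pl = 2, seed = 6, n_frames = 4,
                                        bleach_rate = b))
  lab0 <- oracle_components(tl$grids[[1]]$red > 0)
  for (f in 0:3) {
    for (l in 1:2) {
      m0 <- oracle_masked_mean(tl$grids[[1]]$green, lab0, l)
      mf <- oracle_masked_mean(tl$grids[[f + 1]]$green, lab0, l)
      expect_equal(mf, m0 * exp(-b * f), tolerance = 1e-12)
    }
  }
})

test_that("green/red ratio is invariant under equal bleaching, scales under green-only", {
  base <- small_params(n_pl = 2, seed = 6, n_frames = 3)
  equal_b <- generate_timelapse(small_params(n_pl = 2, seed = 6,
                                             n_frames = 3,
                                             bleach_rate = 0.3))
  green_b <- generate_timelapse(small_params(n_pl = 2, seed = 6,
                                             n_frames = 3,
                                             bleach_rate = c(0.3, 0)))
  lab <- oracle_components(generate_timelapse(base)$grids[[1]]$red > 0)
  for (f in 0:2) {
    for (l in 1:2) {
      ge <- oracle_masked_mean(equal_b$grids[[f + 1]]$green, lab, l)
      re <- oracle_masked_mean(equal_b$grids[[f + 1]]$red, lab, l)
      gg <- oracle_masked_mean(green_b$grids[[f + 1]]$green, lab, l)
      rg <- oracle_masked_mean(green_b$grids[[f + 1]]$red, lab, l)
      ratio0 <- oracle_masked_mean(equal_b$grids[[1]]$green, lab, l) /
        oracle_masked_mean(equal_b$grids[[1]]$red, lab, l)
      expect_equal(ge / re, ratio0, tolerance = 1e-12)
      expect_equal(gg / rg, ratio0 * exp(-0.3 * f), tolerance = 1e-12)
    }
  }
})

test_that("a division replaces one track by two daughters in the truth table", {
  tl <- generate_timelapse(small_params(
    n_pl = 2, seed = 8, n_frames = 6,
    division_times = data.frame(cell_id = 1, frame = 3)))
  tr <- tl$truth
  parent_frames <- tr$frame[tr$cell_id == 1]
  expect_equal(parent_frames, 0:2)
  daughters <- unique(tr$cell_id[!is.na(tr$parent_id)])
  expect_length(daughters, 2L)
  for (d in daughters) {
    expect_equal(tr$frame[tr$cell_id == d], 3:5)
    expect_equal(unique(tr$parent_id[tr$cell_id == d]), 1)
  }
  # the untouched cell persists through all frames
  expect_equal(tr$frame[tr$cell_id == 2], 0:5)
})

test_that("cohort count generator honours its distributions", {
  degenerate <- generate_cohort_counts(list(
    list(label = "g", mean = 5, sd = 0, n = 10,
         distribution = "normal-rounded-at-0")), seed = 1)
  expect_equal(degenerate$count, rep(5, 10))

  # group means as printed for the sibling/mutant EC counts; sd kept well
  # clear of the zero-truncation so the law-of-large-numbers check is clean
  big <- generate_cohort_counts(list(
    list(label = "sib", mean = 37, sd = 3, n = 1000,
         distribution = "normal-rounded-at-0"),
    list(label = "mut", mean = 8, sd = 2, n = 1000,
         distribution = "normal-rounded-at-0")), seed = 2)
  for (spec in list(list("sib", 37, 3), list("mut", 8, 2))) {
    v <- big$count[big$group == spec[[1]]]
    se <- spec[[3]] / sqrt(1000)
    expect_lt(abs(mean(v) - spec[[2]]), 3 * se + 0.15)
  }

  pois <- generate_cohort_counts(list(
    list(label = "p", mean = 4, n = 50, distribution = "poisson")),
    seed = 3)
  expect_true(all(pois$count >= 0))
  expect_true(all(pois$count == round(pois$count)))

  expect_error(generate_cohort_counts(list(
    list(label = "x", mean = 1, sd = 1, n = 5,
         distribution = "lognormal")), seed = 1),
    "unknown distribution")
  expect_identical(generate_cohort_counts(list(
    list(label = "p", mean = 4, n = 10, distribution = "poisson")),
    seed = 9),
    generate_cohort_counts(list(
      list(label = "p", mean = 4, n = 10, distribution = "poisson")),
      seed = 9))
})
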