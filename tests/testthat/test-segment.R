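test_that("high-pass filter removes constants, preserves linearity", {
  expect_equal(high_pass(matrix(7, 40, 40), 3), matrix(0, 40, 40))
  f <- matrix(0, 64, 64); f[32, 32] <- 10
  hp <- high_pass(f, 3)
  expect_gt(hp[32, 32], 0)
  expect_lt(min(hp), 0)               # small negative halo
  expect_equal(sum(hp), 0, tolerance = 1e-8)
  set.seed(11)
  g <- matrix(runif(64 * 64), 64, 64)
  expect_equal(high_pass(2 * g, 3), 2 * high_pass(g, 3))
})

test_that("filtered_stats gives the population mean and sd", {
  st <- filtered_stats(matrix(c(0, 0, 2, 2), 2, 2))
  expect_equal(unname(st["mu"]), 1)
  expect_equal(unname(st["sd"]), 1)
  st0 <- filtered_stats(matrix(0, 3, 3))
  expect_equal(unname(st0), c(0, 0))
  set.seed(12)
  g <- matrix(rnorm(100), 10, 10)
  s1 <- filtered_stats(g); s2 <- filtered_stats(g + 5)
  expect_equal(unname(s2["mu"]), unname(s1["mu"]) + 5)
  expect_equal(unname(s2["sd"]), unname(s1["sd"]))
})

test_that("seed detection applies threshold, size filter and connectivity", {
  f <- matrix(0, 20, 20)
  f[5:6, 5:9] <- 5                       # 10-px blob at 5 sd
  st <- list(mu = 0, sd = 1)
  seeds <- detect_seeds(f, 0, 1, k_seed = 3, min_seed_px = 6)
  expect_length(seeds, 1)
  expect_length(seeds[[1]], 10)
  # 5-px blob fails the min size
  f2 <- matrix(0, 20, 20); f2[5, 5:9] <- 5
  expect_length(detect_seeds(f2, 0, 1, 3, 6), 0)
  # separated blobs stay separate; agreement with the flood-fill oracle
  set.seed(13)
  for (i in 1:10) {
    g <- matrix(rnorm(30 * 30), 30, 30)
    mu <- mean(g); sd <- sqrt(mean((g - mu)^2))
    got <- detect_seeds(g, mu, sd, 1, 2)
    mask <- g > mu + sd
    want <- oracle_pixel_sets(oracle_label8(mask))
    want <- want[vapply(want, length, integer(1)) >= 2]
    expect_identical(lapply(got, as.integer), lapply(want, as.integer))
  }
})

test_that("seed expansion grows to the lower threshold and splits by nearest seed", {
  # seed with a ring at an intermediate level: region = seed + ring
  f <- matrix(0, 15, 15)
  f[7:9, 7:9] <- 5
  ring <- dilate_ring(which(f == 5), c(15, 15), 1)
  f[ring] <- 2
  seeds <- detect_seeds(f, 0, 1, 3, 1)
  regs <- expand_seeds(f, seeds, 0, 1, k_expand = 1.75)
  expect_setequal(regs[[1]], sort(c(which(f == 5), ring)))
  # k_expand = k_seed reproduces the seeds exactly
  regs2 <- expand_seeds(f, seeds, 0, 1, k_expand = 3)
  expect_identical(lapply(regs2, sort), lapply(seeds, sort))
})

test_that("two seeds in one expansion blob split by nearest-seed distance", {
  f <- matrix(0, 12, 30)
  f[5:7, 4:6] <- 5; f[5:7, 20:22] <- 5   # two seeds
  f[6, 3:23] <- pmax(f[6, 3:23], 2)      # bridge above expansion threshold
  seeds <- detect_seeds(f, 0, 1, 3, 6)
  expect_length(seeds, 2)
  regs <- expand_seeds(f, seeds, 0, 1, 1.75)
  expect_length(intersect(regs[[1]], regs[[2]]), 0)
  expect_setequal(c(regs[[1]], regs[[2]]), which(f > 1.75))
  expect_true(all(seeds[[1]] %in% regs[[1]]))
  expect_true(all(seeds[[2]] %in% regs[[2]]))
  # brute-force nearest-seed assignment over the blob
  dim <- c(12, 30)
  blob <- which(f > 1.75)
  co <- cbind((blob - 1) %% 12 + 1, (blob - 1) %/% 12 + 1)
  d_to <- function(px) {
    sco <- cbind((px - 1) %% 12 + 1, (px - 1) %/% 12 + 1)
    apply(co, 1, function(p) min(sqrt((sco[, 1] - p[1])^2 + (sco[, 2] - p[2])^2)))
  }
  nearest <- ifelse(d_to(seeds[[1]]) <= d_to(seeds[[2]]), 1, 2)
  expect_setequal(regs[[1]], blob[nearest == 1])
  expect_setequal(regs[[2]], blob[nearest == 2])
})

test_that("shape filter enforces area and axis-ratio bounds", {
  dim <- c(30, 30)
  sq <- px_index(rep(5:9, 5), rep(11:15, each = 5), dim)     # 5x5 square
  line <- px_index(rep(20L, 20), 1:20, dim)                  # 1x20 line
  tri <- px_index(c(1L, 1L, 2L), c(1L, 2L, 1L), dim)         # area 3
  expect_equal(axis_ratio(sq, dim), 1)
  expect_equal(axis_ratio(line, dim), Inf)
  expect_equal(axis_ratio(line, dim), oracle_axis_ratio(line, dim))
  set.seed(14)
  for (i in 1:10) {
    px <- sort(sample(prod(dim), sample(3:40, 1)))
    expect_equal(axis_ratio(px, dim), oracle_axis_ratio(px, dim),
                 tolerance = 1e-9)
  }
  kept <- shape_filter(list(sq, line, tri), dim,
                       area_bounds = c(4, 100), ratio_bounds = c(1, 4))
  expect_identical(kept, list(sq))
})

test_that("cell mask fills holes and drops small components", {
  blank <- matrix(5, 60, 60)
  expect_false(any(segment_cell_mask(blank)))
  f <- matrix(0, 60, 60)
  f[10:49, 10:49] <- 100
  f[25:29, 25:29] <- 0                  # interior hole
  mask <- segment_cell_mask(f, sigma = 1, k_cell = 1, min_size_px = 50)
  expect_true(all(mask[26:28, 26:28]))  # hole filled
  f2 <- matrix(0, 60, 60)
  f2[5:14, 5:14] <- 100                 # 100 px
  f2[40:45, 40:44] <- 100               # 30 px
  mask2 <- segment_cell_mask(f2, sigma = 0.5, k_cell = 1, min_size_px = 50)
  expect_true(any(mask2[5:14, 5:14]))
  expect_false(any(mask2[40:45, 40:44]))
})

test_that("edge distance measures to the nearest mask boundary", {
  dim <- c(41, 41)
  mask <- matrix(FALSE, dim[1], dim[2])
  ctr <- c(21, 21)
  for (r in 1:41) for (c in 1:41)
    if ((r - 21)^2 + (c - 21)^2 <= 100) mask[r, c] <- TRUE
  region <- px_index(21L, 21L, dim)
  d <- edge_distance(region, mask, pixel_size_um = 0.5)
  expect_equal(d, 5, tolerance = 0.5 * 0.5)   # radius 10 px at 0.5 um/px
  # centroid adjacent to the boundary
  region2 <- px_index(21L, 12L, dim)
  expect_lte(edge_distance(region2, mask, 1), 1.01)
  # centroid outside the mask is an inconsistency
  outside <- px_index(1L, 1L, dim)
  expect_error(edge_distance(outside, mask, 1), "outside")
})

test_that("seed counts fall as thresholds rise; expansion area falls with k_expand", {
  set.seed(15)
  f <- matrix(rnorm(80 * 80), 80, 80)
  for (i in 1:12) f <- invadotrack:::add_gaussian_spot(
    f, c(runif(1, 10, 70), runif(1, 10, 70)), 1.5, runif(1, 4, 9))
  st <- filtered_stats(f)
  seed_area <- vapply(c(1, 2, 3, 4, 5), function(k)
    sum(lengths(detect_seeds(f, st["mu"], st["sd"], k, 2))), integer(1))
  expect_true(all(diff(seed_area) <= 0))
  counts <- vapply(c(1, 2, 3, 4, 5), function(k)
    length(detect_seeds(f, st["mu"], st["sd"], k, 2)), integer(1))
  expect_lte(counts[5], counts[1])
  sizes <- vapply(c(2, 4, 6, 9), function(m)
    length(detect_seeds(f, st["mu"], st["sd"], 2, m)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  seeds <- detect_seeds(f, st["mu"], st["sd"], 3, 2)
  areas <- vapply(c(0.5, 1, 1.75, 2.5), function(k)
    sum(lengths(expand_seeds(f, seeds, st["mu"], st["sd"], k))), integer(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("segmentation is shift-invariant and scale-equivariant", {
  set.seed(16)
  f <- matrix(rnorm(50 * 50), 50, 50)
  for (i in 1:5) f <- invadotrack:::add_gaussian_spot(
    f, c(runif(1, 10, 40), runif(1, 10, 40)), 1.5, 8)
  run <- function(g) {
    st <- filtered_stats(g)
    seeds <- detect_seeds(g, st["mu"], st["sd"], 3, 3)
    expand_seeds(g, seeds, st["mu"], st["sd"], 1.75)
  }
  base <- run(f)
  expect_identical(run(f + 100), base)
  expect_identical(run(f * 3.7), base)
})

test_that("planted spots are recovered with high recall and low pixel FPR", {
  set.seed(17)
  dim <- c(128, 128)
  n_miss <- 0; n_tot <- 0; fp_px <- 0; tot_px <- 0
  for (trial in 1:3) {
    f <- matrix(rnorm(prod(dim), 0, 1), dim[1], dim[2])
    centers <- cbind(runif(12, 15, 113), runif(12, 15, 113))
    keep <- rep(TRUE, 12)
    for (i in 1:12) keep[i] <- all(sqrt((centers[-i, 1] - centers[i, 1])^2 +
                                        (centers[-i, 2] - centers[i, 2])^2) > 12)
    centers <- centers[keep, , drop = FALSE]
    for (i in seq_len(nrow(centers)))
      f <- invadotrack:::add_gaussian_spot(f, centers[i, ], 1.6, 8)  # SNR 8
    hp <- high_pass(f, 10)
    st <- filtered_stats(hp)
    seeds <- detect_seeds(hp, st["mu"], st["sd"], 3, 6)
    regs <- expand_seeds(hp, seeds, st["mu"], st["sd"], 1.75)
    lab <- matrix(0L, dim[1], dim[2])
    for (r in regs) lab[r] <- 1L
    hits <- vapply(seq_len(nrow(centers)), function(i)
      lab[round(centers[i, 1]), round(centers[i, 2])] > 0, logical(1))
    n_tot <- n_tot + nrow(centers); n_miss <- n_miss + sum(!hits)
    true_mask <- matrix(FALSE, dim[1], dim[2])
    for (i in seq_len(nrow(centers)))
      true_mask[invadotrack:::disk_pixels(centers[i, ], 6, dim)] <- TRUE
    fp_px <- fp_px + sum(lab > 0 & !true_mask)
    tot_px <- tot_px + sum(!true_mask)
  }
  expect_gte(1 - n_miss / n_tot, 0.95)
  expect_lte(fp_px / tot_px, 0.01)
})

test_that("shape bounds calibrate to the range of annotated puncta", {
  dim <- c(30, 30)
  sq <- px_index(rep(5:9, 5), rep(11:15, each = 5), dim)     # 25 px, ratio 1
  rect <- px_index(rep(20:22, 6), rep(5:10, each = 3), dim)  # 18 px, elongated
  line <- px_index(rep(28L, 10), 1:10, dim)                  # degenerate
  b <- calibrate_shape_bounds(list(sq, rect, line), dim)
  expect_equal(b$area_bounds, c(10, 25))
  expect_equal(b$ratio_bounds[1], 1)
  expect_true(is.finite(b$ratio_bounds[2]))
  expect_equal(b$ratio_bounds[2], axis_ratio(rect, dim))
  expect_error(calibrate_shape_bounds(list(line), dim), "degenerate")
})
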