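test_that("cell segmentation finds separated blobs, merges touching ones", {
  expect_length(segment_cells(matrix(5, 50, 50)), 0)
  f <- matrix(0, 60, 60)
  f[5:20, 5:20] <- 100
  f[35:55, 30:55] <- 100
  cells <- segment_cells(f, sigma = 1, k_cell = 1, min_size_px = 50)
  expect_length(cells, 2)
  # areas close to the painted blocks (smoothing moves the boundary < 2 px)
  expect_equal(length(cells[[1]]), 16 * 16, tolerance = 0.2)
  expect_equal(length(cells[[2]]), 21 * 26, tolerance = 0.2)
  f2 <- matrix(0, 60, 60)
  f2[5:30, 5:32] <- 100
  f2[28:55, 30:55] <- 100   # overlapping blocks form a single component
  expect_length(segment_cells(f2, sigma = 1, k_cell = 1, min_size_px = 50), 1)
})

test_that("cell size filter is inclusive at both bounds", {
  mk <- function(n) seq_len(n)
  regs <- list(mk(1499), mk(1500), mk(20000), mk(20001))
  kept <- size_filter_cells(regs)
  expect_identical(lengths(kept), c(1500L, 20000L))
})

test_that("cell borders match the distance oracle and exclude neighbours", {
  dim <- c(60, 60)
  cell <- px_index(rep(25:34, 10), rep(25:34, each = 10), dim)
  ring <- cell_border(cell, list(), dim, width = 8)
  expect_identical(as.integer(ring), as.integer(oracle_ring(cell, dim, 8)))
  other <- px_index(rep(25:34, 5), rep(37:41, each = 10), dim)
  ring2 <- cell_border(cell, list(other), dim, width = 8)
  expect_length(intersect(ring2, other), 0)
  expect_setequal(ring2, setdiff(ring, other))
  # edge cell: clipped ring
  corner_cell <- px_index(rep(1:6, 6), rep(1:6, each = 6), dim)
  expect_identical(as.integer(cell_border(corner_cell, list(), dim, 8)),
                   as.integer(oracle_ring(corner_cell, dim, 8)))
})

test_that("frame degradation percentage is background-corrected", {
  dim <- c(40, 40)
  under <- px_index(rep(15:24, 10), rep(15:24, each = 10), dim)
  border <- cell_border(under, list(), dim, 5)
  prev <- matrix(1000, dim[1], dim[2])
  curr <- matrix(1000, dim[1], dim[2])
  expect_equal(frame_degradation_pct(prev, curr, under, border), 0)
  curr2 <- curr; curr2[under] <- 950
  expect_equal(frame_degradation_pct(prev, curr2, under, border), 5)
  # a uniform 10% bleach cancels exactly
  expect_equal(frame_degradation_pct(prev, prev * 0.9, under, border), 0)
  # global rescaling of both frames leaves the percentage unchanged
  expect_equal(frame_degradation_pct(prev * 3, curr2 * 3, under, border),
               frame_degradation_pct(prev, curr2, under, border))
  expect_true(is.na(frame_degradation_pct(prev, curr, integer(0), border)))
})

test_that("area of influence applies the inclusive 2.5-h coverage rule", {
  dim <- c(30, 30)
  px5 <- invadotrack:::disk_pixels(c(10, 10), 3, dim)
  px4 <- invadotrack:::disk_pixels(c(10, 20), 3, dim)
  # one pixel set present 5 frames, another 4, at 30-min frames
  regs <- lapply(1:5, function(t)
    if (t <= 4) list(sort(union(px5, px4))) else list(px5))
  # hold them as one track via overlap
  track <- link_by_overlap(regs, dim)[[1]]
  infl <- area_of_influence(track, dim, 30, min_coverage_h = 2.5)
  expect_true(all(px5 %in% infl))          # 150 min: included (inclusive)
  expect_false(any(px4 %in% infl))         # 120 min: excluded
  # a static cell's influence is its full footprint
  regs2 <- replicate(20, list(px5), simplify = FALSE)
  tr2 <- link_by_overlap(regs2, dim)[[1]]
  expect_setequal(area_of_influence(tr2, dim, 30), px5)
})

test_that("overall degradation percentage mirrors the frame formula", {
  dim <- c(40, 40)
  infl <- px_index(rep(15:24, 10), rep(15:24, each = 10), dim)
  border <- cell_border(infl, list(), dim, 5)
  first <- matrix(1000, dim[1], dim[2])
  last <- first; last[infl] <- 700
  expect_equal(overall_degradation_pct(first, last, infl, border), 30)
  expect_equal(overall_degradation_pct(first, first, infl, border), 0)
  # bleach hitting both regions equally cancels
  expect_equal(overall_degradation_pct(first, first * 0.9, infl, border), 0)
})

test_that("cutoff calibration returns order statistics of the control", {
  ctrl <- tibble::tibble(D_tot = c(-1, 0, 2), max_D_t = c(-1, 0, 2))
  cut0 <- calibrate_degrader_cutoffs(ctrl, fp_budget = 0)
  expect_equal(cut0$c_tot, 2)
  cut1 <- calibrate_degrader_cutoffs(ctrl, fp_budget = 1)
  expect_equal(cut1$c_tot, 0)
  same <- tibble::tibble(D_tot = c(3, 3, 3), max_D_t = c(3, 3, 3))
  expect_equal(calibrate_degrader_cutoffs(same)$c_tot, 3)
  expect_error(calibrate_degrader_cutoffs(tibble::tibble(D_tot = numeric(),
                                                         max_D_t = numeric())),
               "control")
  # self-classification with budget-0 cutoffs flags nobody
  for (i in seq_len(nrow(ctrl))) {
    cls <- classify_degrader(ctrl$D_tot[i], ctrl$max_D_t[i], cut0)
    expect_false(cls$is_degrader)
  }
})

test_that("degrader rule combines overall and per-frame exceedances", {
  cut <- structure(list(c_tot = 5, c_frame = 3), class = "degrader_cutoffs")
  expect_true(classify_degrader(30, c(0, 1), cut)$is_degrader)
  expect_true(classify_degrader(0, c(0, 4), cut)$is_degrader)
  expect_false(classify_degrader(5, c(3, 3), cut)$is_degrader)  # strict
  expect_equal(classify_degrader(0, c(0, 4, 2), cut)$degrader_at_frame,
               c(FALSE, TRUE, FALSE))
})

test_that("degraded area uses the inclusive 20% per-pixel drop", {
  dim <- c(20, 20)
  infl <- px_index(rep(5:14, 10), rep(5:14, each = 10), dim)
  first <- matrix(1000, dim[1], dim[2])
  expect_setequal(degraded_area(first, first * 0.7, infl, 0.2, 1)$pixels, infl)
  expect_length(degraded_area(first, first * 0.9, infl, 0.2, 1)$pixels, 0)
  # exactly 20% decrease counts as degraded
  expect_setequal(degraded_area(first, first * 0.8, infl, 0.2, 1)$pixels, infl)
  # per-pixel oracle on a heterogeneous pair
  set.seed(51)
  f1 <- matrix(runif(prod(dim), 500, 1500), dim[1], dim[2])
  f2 <- f1 * matrix(runif(prod(dim), 0.6, 1.1), dim[1], dim[2])
  got <- degraded_area(f1, f2, infl, 0.2, 0.267)
  want <- infl[f2[infl] <= 0.8 * f1[infl]]
  expect_setequal(got$pixels, want)
  expect_equal(got$area_um2, length(want) * 0.267^2)
})

test_that("degradation rate is area over lifetime in hours", {
  expect_equal(degradation_rate(120, 24 * 60), 5)
  expect_equal(degradation_rate(0, 600), 0)
  expect_equal(degradation_rate(80, 300), 2 * degradation_rate(80, 600))
  expect_error(degradation_rate(10, 0), "positive")
})
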