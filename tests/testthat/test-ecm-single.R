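dim <- c(30, 30)

test_that("puncta border is the 5-px ring minus other puncta", {
  px <- px_index(15L, 15L, dim)
  b <- puncta_border(px, list(), dim, width = 1)
  expect_setequal(b, px_index(c(14L, 16L, 15L, 15L), c(15L, 15L, 14L, 16L), dim))
  # matches brute force at the default width
  region <- invadotrack:::disk_pixels(c(15, 15), 2, dim)
  expect_identical(as.integer(puncta_border(region, list(), dim, 5)),
                   as.integer(oracle_ring(region, dim, 5)))
  # a neighbouring puncta is excluded from the ring
  other <- invadotrack:::disk_pixels(c(15, 20), 2, dim)
  b2 <- puncta_border(region, list(other), dim, 5)
  expect_length(intersect(b2, other), 0)
  expect_setequal(b2, setdiff(oracle_ring(region, dim, 5), other))
})

test_that("local difference is border mean minus under mean", {
  ecm <- matrix(1000, dim[1], dim[2])
  under <- invadotrack:::disk_pixels(c(10, 10), 2, dim)
  border <- puncta_border(under, list(), dim, 5)
  expect_equal(local_difference(ecm, under, border), 0)
  ecm[under] <- 800
  expect_equal(local_difference(ecm, under, border), 200)
  ecm[under] <- 1200                   # accumulation artifact
  expect_lt(local_difference(ecm, under, border), 0)
  expect_true(is.na(local_difference(ecm, integer(0), border)))
})

test_that("pre-birth difference uses the image before track birth", {
  frames <- replicate(6, matrix(1000, dim[1], dim[2]), simplify = FALSE)
  under <- invadotrack:::disk_pixels(c(12, 12), 2, dim)
  border <- puncta_border(under, list(), dim, 5)
  # a pre-existing blemish under the future puncta
  for (t in 1:6) frames[[t]][under] <- 900
  ecm <- make_stack(frames)
  regs <- c(list(list()), list(list()), replicate(4, list(under), simplify = FALSE))
  track <- link_by_overlap(regs, dim)[[1]]
  expect_equal(track$start_frame, 3L)
  sets <- replicate(4, list(under = under, border = border), simplify = FALSE)
  P <- pre_birth_difference(ecm, track, sets)
  expect_equal(P, rep(100, 4))         # blemish: border 1000, under 900
  ser <- degradation_series(ecm, track, regs, width = 5)
  expect_equal(ser$data$L, rep(100, 4))
  expect_equal(ser$data$C, rep(0, 4))  # blemish removed by correction
  # track present from frame 1 uses the first ECM image
  regs1 <- replicate(6, list(under), simplify = FALSE)
  track1 <- link_by_overlap(regs1, dim)[[1]]
  P1 <- pre_birth_difference(ecm, track1,
                             replicate(6, list(under = under, border = border),
                                       simplify = FALSE))
  expect_equal(P1, rep(100, 6))
})

test_that("a deepening hole yields the planted ramp in C_t", {
  under <- invadotrack:::disk_pixels(c(15, 15), 2, dim)
  frames <- lapply(0:12, function(t) {
    f <- matrix(1000, dim[1], dim[2])
    f[under] <- 1000 - 20 * t
    f
  })
  ecm <- make_stack(frames)
  regs <- c(list(list()), replicate(12, list(under), simplify = FALSE))
  track <- link_by_overlap(regs, dim)[[1]]
  ser <- degradation_series(ecm, track, regs, width = 5)
  expect_equal(ser$data$C, 20 * (1:12))
  expect_equal(ser$mean_C, 20 * mean(1:12))   # = 130
  expect_equal(ser$mean_C, 130)
  expect_true(ser$usable)
})

test_that("C = L - P holds to machine precision and scales with the stack", {
  set.seed(31)
  frames <- replicate(8, matrix(runif(prod(dim), 800, 1200), dim[1], dim[2]),
                      simplify = FALSE)
  under <- invadotrack:::disk_pixels(c(20, 12), 2, dim)
  regs <- c(list(list()), replicate(7, list(under), simplify = FALSE))
  track <- link_by_overlap(regs, dim)[[1]]
  ecm <- make_stack(frames)
  ser <- degradation_series(ecm, track, regs)
  expect_identical(ser$data$C, ser$data$L - ser$data$P)
  # multiplying the stack multiplies L, P, C
  ecm2 <- make_stack(lapply(frames, function(f) f * 3))
  ser2 <- degradation_series(ecm2, track, regs)
  expect_equal(ser2$data$L, 3 * ser$data$L)
  expect_equal(ser2$data$P, 3 * ser$data$P)
  expect_equal(ser2$data$C, 3 * ser$data$C)
})

test_that("borders shrink monotonically under exclusions", {
  region <- invadotrack:::disk_pixels(c(15, 15), 2, dim)
  plain <- puncta_border(region, list(), dim, 5)
  other <- invadotrack:::disk_pixels(c(15, 19), 2, dim)
  excl <- puncta_border(region, list(other), dim, 5)
  expect_lte(length(excl), length(plain))
  expect_true(all(excl %in% plain))
})

test_that("an empty border marks the frame missing, not zero", {
  # puncta fully enclosed by another puncta's pixels
  inner <- px_index(15L, 15L, dim)
  shell <- setdiff(invadotrack:::disk_pixels(c(15, 15), 6, dim), inner)
  frames <- replicate(2, matrix(1000, dim[1], dim[2]), simplify = FALSE)
  regs <- replicate(2, list(inner, shell), simplify = FALSE)
  tracks <- link_by_overlap(regs, dim)
  ser <- degradation_series(make_stack(frames), tracks[[1]], regs, width = 5)
  expect_true(all(is.na(ser$data$L)))
  expect_false(ser$usable)
})
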