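make_stack <- function(vals, nr = 8, nc = 8, nt = 1,
                       channels = c("donor", "fret")) {
  d <- array(vals, c(nr, nc, length(channels), nt))
  raw_stack(d, channels)
}

test_that("dark subtraction clips at zero and identity holds for zero dark", {
  st <- make_stack(c(110, 5))
  st$data[, , "donor", 1] <- 110; st$data[, , "fret", 1] <- 5
  bundle <- correction_bundle(dark = list(donor = matrix(10, 8, 8),
                                          fret = matrix(10, 8, 8)))
  out <- subtract_dark(st, bundle)
  expect_true(all(out$data[, , "donor", 1] == 100))
  expect_true(all(out$data[, , "fret", 1] == 0))   # clipped
  zero <- correction_bundle(dark = list(donor = matrix(0, 8, 8),
                                        fret = matrix(0, 8, 8)))
  expect_equal(subtract_dark(st, zero)$data, st$data)
  expect_error(subtract_dark(st, correction_bundle(dark = list(donor = matrix(0, 8, 8)))),
               "no dark frame")
})

test_that("shading correction divides by the reference and self-corrects", {
  ref <- matrix(runif(64, 0.5, 1.5), 8, 8); ref <- ref / mean(ref)
  st <- make_stack(0, channels = "donor")
  st$data[, , 1, 1] <- ref
  bundle <- correction_bundle(shading = list(donor = ref))
  out <- shading_correct(st, bundle)
  expect_equal(out$data[, , 1, 1], matrix(1, 8, 8), tolerance = 1e-12)
  # uniform reference is the identity
  st2 <- make_stack(7, channels = "donor")
  uni <- correction_bundle(shading = list(donor = matrix(1, 8, 8)))
  expect_equal(shading_correct(st2, uni)$data, st2$data)
  # a non-unit-mean reference is rejected at bundle construction
  expect_error(correction_bundle(shading = list(donor = ref * 2)), "mean 1")
})

test_that("correction order is enforced and repeats are forbidden", {
  ref <- matrix(1, 8, 8)
  bundle <- correction_bundle(dark = list(donor = ref * 0),
                              shading = list(donor = ref),
                              background_region = list(rows = 1:5, cols = 1:5))
  st <- make_stack(5, channels = "donor")
  st <- shading_correct(st, bundle)
  expect_error(shading_correct(st, bundle), "already applied")
  expect_error(subtract_dark(st, bundle), "must be applied before")
})

test_that("affine estimation recovers exact and jittered transforms", {
  M <- rbind(c(1.01, 0.02, 1.5), c(-0.015, 0.99, -0.8))
  src <- cbind(c(10, 40, 25, 60), c(12, 15, 55, 40))
  dst <- t(M %*% t(cbind(src, 1)))
  tf <- estimate_affine_from_fiducials(src[1:3, ], dst[1:3, ])
  expect_equal(tf$matrix, M, tolerance = 1e-10)
  expect_lt(tf$residual, 1e-10)
  # identity correspondence
  tfi <- estimate_affine_from_fiducials(src, src)
  expect_equal(tfi$matrix, rbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-10)
  # Monte-Carlo: 10 points with 0.1 px jitter recover within 1e-2
  set.seed(1)
  err <- replicate(20, {
    s <- cbind(runif(10, 5, 90), runif(10, 5, 90))
    d <- t(M %*% t(cbind(s, 1))) + matrix(rnorm(20, 0, 0.1), 10, 2)
    Mh <- estimate_affine_from_fiducials(s, d)$matrix
    c(lin = max(abs(Mh[, 1:2] - M[, 1:2])), tr = max(abs(Mh[, 3] - M[, 3])))
  })
  # linear part to 1e-2; translation is limited by jitter/sqrt(n)
  expect_gt(mean(err["lin", ] < 1e-2), 0.85)
  expect_lt(max(err["tr", ]), 0.25)
  expect_error(estimate_affine_from_fiducials(src[1:2, ], dst[1:2, ]), "3")
  col <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_affine_from_fiducials(col, col + 1), "collinear")
})

test_that("affine resampling: identity, integer shift, and round trip", {
  img <- matrix(0, 32, 32)
  img[8:24, 8:24] <- outer(8:24, 8:24, function(a, b) sin(a / 4) + cos(b / 5))
  st <- make_stack(0, 32, 32, channels = "ex409")
  st$data[, , 1, 1] <- img
  idm <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(apply_affine(st, idm, "ex409")$data, st$data)
  # pure integer translation is exact where defined
  tr <- rbind(c(1, 0, 3), c(0, 1, -2))
  out <- apply_affine(st, tr, "ex409")$data[, , 1, 1]
  expect_equal(out[10:20, 10:20], img[(10:20) - 3, (10:20) + 2])
  expect_true(all(is.na(out[1:3, ])))  # out-of-bounds rows invalidated
  # T then T^-1 on a smooth image: small interpolation error
  M <- rbind(c(cos(0.03), -sin(0.03), 0.8), c(sin(0.03), cos(0.03), -0.5))
  Minv <- cbind(solve(M[, 1:2]), -solve(M[, 1:2]) %*% M[, 3])
  sm <- make_stack(0, 32, 32, channels = "ex409")
  sm$data[, , 1, 1] <- outer(1:32, 1:32, function(a, b) sin(a / 8) * cos(b / 9))
  one <- apply_affine(sm, M, "ex409")
  attr(one, "steps") <- character(0)      # allow second warp in this test
  two <- apply_affine(one, Minv, "ex409")$data[, , 1, 1]
  inner <- two[6:27, 6:27]
  expect_lt(max(abs(inner - sm$data[6:27, 6:27, 1, 1])), 0.01)
})

test_that("background subtraction removes per-frame scalar levels", {
  st <- make_stack(0, 16, 16, nt = 2, channels = "donor")
  st$data[, , 1, 1] <- 7.2; st$data[, , 1, 2] <- 3.1
  st$data[10:14, 10:14, 1, ] <- 100
  bundle <- correction_bundle(background_region = list(rows = 1:6, cols = 1:6))
  res <- subtract_background(st, bundle)
  expect_equal(res$levels$level, c(7.2, 3.1))
  expect_equal(unname(res$stack$data[1, 1, 1, 1]), 0)
  expect_equal(unname(res$stack$data[12, 12, 1, 2]), 100 - 3.1)
  # overlapping mask warns but proceeds
  mask <- matrix(TRUE, 16, 16)
  expect_warning(subtract_background(make_stack(1, 16, 16, channels = "donor"),
                                     bundle, mask = mask), "overlaps")
  small <- correction_bundle(background_region = list(rows = 1:4, cols = 1:4))
  expect_error(subtract_background(st, small), "25 pixels")
})

test_that("background residual stays below read noise on drifting scenes", {
  cfg <- tiny_config(seed = 21, background_level = 40, background_drift = 12,
                     shading_amplitude = 0, dark_offset = 0, misreg = NULL,
                     bleach = NULL)
  sc <- simulate_scene(cfg)
  res <- subtract_background(sc$stack, sc$bundle)
  outside <- !sc$truth$mask
  outside[sc$bundle$background_region$rows, sc$bundle$background_region$cols] <- FALSE
  for (t in c(1, 8)) {
    resid <- mean(res$stack$data[, , "donor", t][outside])
    expect_lt(abs(resid), cfg$read_sd)
  }
})

test_that("segmentation is exact on noise-free two-level frames", {
  st <- make_stack(10, 64, 64, channels = "donor")
  truth <- matrix(FALSE, 64, 64); truth[20:48, 16:50] <- TRUE
  st$data[, , 1, 1][truth] <- 100
  masks <- segment_cells(st)
  expect_identical(masks$mask[, , 1], truth)
})

test_that("segmentation reaches IoU >= 0.9 at SNR 5 across seeds", {
  ious <- sapply(1:20, function(s) {
    set.seed(s)
    truth <- make_cell_mask(72, 72)
    img <- matrix(10, 72, 72); img[truth] <- 60   # SNR 5 at sd 10
    img <- img + matrix(rnorm(72 * 72, 0, 10), 72, 72)
    st <- make_stack(0, 72, 72, channels = "donor")
    st$data[, , 1, 1] <- img
    m <- segment_cells(st)$mask[, , 1]
    sum(m & truth) / sum(m | truth)
  })
  expect_true(all(ious >= 0.9))
})

test_that("constant frames yield an empty mask with a warning", {
  st <- make_stack(5, 16, 16, channels = "donor")
  expect_warning(m <- segment_cells(st), "constant")
  expect_false(any(m$mask))
})

test_that("background-range mask excludes pixels failing in ANY channel", {
  st <- make_stack(0, 8, 8, channels = c("donor", "fret"))
  st$data[, , "donor", 1] <- 50
  st$data[, , "fret", 1] <- 50
  st$data[3, 3, "fret", 1] <- 0.5   # fails in one channel only
  levels <- data.frame(frame = 1, channel = c("donor", "fret"),
                       level = 0, sd = 1)
  v <- background_range_mask(st, levels, k = 2)
  expect_false(v[3, 3, 1])
  expect_true(v[4, 4, 1])
})

test_that("k=0 on a noiseless scene makes validity match the cell mask", {
  cfg <- clean_config(seed = 6)
  sc <- simulate_scene(cfg)
  res <- subtract_background(sc$stack, sc$bundle)
  v <- background_range_mask(res$stack, res$levels, k = 0)
  expect_identical(v[, , 1], sc$truth$mask)
})
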