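test_that("FRET index follows the bleed-through-corrected ratio formula", {
  f <- matrix(10, 12, 12); d <- matrix(5, 12, 12); a <- matrix(1, 12, 12)
  r0 <- compute_fret_index(f, d, a, alpha = 0, beta = 0)
  expect_equal(r0$index[1, 1, 1], 2)                 # reduces to FRET/Donor
  f2 <- matrix(100, 12, 12); d2 <- matrix(50, 12, 12); a2 <- matrix(40, 12, 12)
  r <- compute_fret_index(f2, d2, a2, alpha = 0.2, beta = 0.1)
  expect_equal(r$index[3, 3, 1], (100 - 0.2 * 50 - 0.1 * 40) / 50) # = 1.72
  expect_error(compute_fret_index(f, matrix(5, 3, 3), a), "dimensions")
})

test_that("near-zero donors are invalidated, not divided by", {
  f <- matrix(1, 10, 10); d <- matrix(100, 10, 10)
  d[2, 2] <- 1e-9
  r <- compute_fret_index(f, d, matrix(0, 10, 10))
  expect_false(r$valid[2, 2, 1])
  expect_true(is.na(r$index[2, 2, 1]))
})

test_that("GTP index is the 409/494 excitation ratio", {
  g <- compute_gtp_index(matrix(40, 8, 8), matrix(20, 8, 8))
  expect_equal(g$index[1, 1, 1], 2)
  e <- matrix(13, 8, 8)
  expect_equal(compute_gtp_index(e, e)$index[4, 4, 1], 1)
})

test_that("bleed-through coefficients are recovered from control stacks", {
  cfg <- tiny_config(alpha = 0.2, beta = 0.1, seed = 31, misreg = NULL)
  sc <- simulate_scene(cfg)
  opts <- analysis_options(registration = FALSE, bleedthrough = FALSE,
                           photobleach = FALSE)
  d_ctrl <- gtpcoupling:::preprocess_stack(sc$bundle$donor_only, sc$bundle, opts)$stack
  a_ctrl <- gtpcoupling:::preprocess_stack(sc$bundle$acceptor_only, sc$bundle, opts)$stack
  bt <- estimate_bleedthrough(d_ctrl, a_ctrl)
  expect_equal(bt$alpha, 0.2, tolerance = 0.005 / 0.2)
  expect_equal(bt$beta, 0.1, tolerance = 0.005 / 0.1)
  expect_gte(bt$n_alpha, 500)
})

test_that("zero bleed-through estimates as ~0 and cancels donor-only FRET", {
  cfg <- clean_config(seed = 32)
  sc <- simulate_scene(cfg)
  bt <- estimate_bleedthrough(sc$bundle$donor_only, sc$bundle$acceptor_only)
  expect_lt(abs(bt$alpha), 1e-10)
  # with the true alpha, a donor-only scene's index is ~0
  cfg2 <- clean_config(alpha = 0.25, seed = 33)
  sc2 <- simulate_scene(cfg2)
  ctrl <- sc2$bundle$donor_only
  r <- compute_fret_index(get_channel(ctrl, "fret"), get_channel(ctrl, "donor"),
                          get_channel(ctrl, "acceptor"), alpha = 0.25)
  expect_lt(max(abs(r$index[, , 1][sc2$truth$mask])), 1e-9)
})

test_that("photobleach correction flattens a double-exponential decay", {
  nr <- 24; nt <- 30
  tt <- 0:(nt - 1)
  decay <- 0.7 * exp(-0.05 * tt) + 0.3 * exp(-0.01 * tt)
  base <- matrix(runif(nr * nr, 1, 2), nr, nr)
  idx <- array(NA_real_, c(nr, nr, nt))
  for (t in seq_len(nt)) idx[, , t] <- base * decay[t]
  stk <- gtpcoupling:::new_index_stack(idx, array(TRUE, dim(idx)), "fret")
  out <- photobleach_correct(stk)
  m <- sapply(seq_len(nt), function(t) mean(out$index[, , t]))
  expect_lt(max(abs(m / m[1] - 1)), 0.01)
  expect_true(out$photobleach_corrected)
  expect_equal(unname(out$bleach_fit$pars["a1"] + out$bleach_fit$pars["a2"]),
               mean(base), tolerance = 0.05)
})

test_that("photobleach correction is a per-frame scalar (pattern preserved)", {
  set.seed(5)
  nt <- 10
  idx <- array(rexp(16 * 16 * nt) + 0.5, c(16, 16, nt))
  for (t in seq_len(nt)) idx[, , t] <- idx[, , t] * exp(-0.08 * t)
  stk <- gtpcoupling:::new_index_stack(idx, array(TRUE, dim(idx)), "gtp")
  out <- photobleach_correct(stk)
  for (t in c(2, 7)) {
    ratio <- out$index[, , t] / idx[, , t]
    expect_lt(diff(range(ratio)), 1e-12)
  }
})

test_that("constant series short-circuits to the identity correction", {
  idx <- array(1.5, c(12, 12, 8))
  stk <- gtpcoupling:::new_index_stack(idx, array(TRUE, dim(idx)), "fret")
  out <- photobleach_correct(stk)
  expect_identical(out$index, idx)
  expect_equal(out$bleach_fit$model, "constant")
})

test_that("photobleach fit requires at least 6 frames", {
  idx <- array(1, c(8, 8, 5))
  stk <- gtpcoupling:::new_index_stack(idx, array(TRUE, dim(idx)), "fret")
  expect_error(photobleach_correct(stk), "6 frames")
})

test_that("display scale matches linear-interpolation percentiles", {
  idx <- array(NA_real_, c(10, 10, 1)); idx[, , 1] <- 1:100
  stk <- gtpcoupling:::new_index_stack(idx, array(TRUE, dim(idx)), "gtp")
  ds <- display_scale(stk)
  expect_equal(ds$lo, 5.95)    # brute-force percentile of 1..100
  expect_equal(ds$hi, 95.05)
  expect_equal(ds$bounds[1], 1)
  # constant map flagged degenerate
  cst <- gtpcoupling:::new_index_stack(array(2, c(10, 10, 1)),
                                       array(TRUE, c(10, 10, 1)), "gtp")
  expect_true(display_scale(cst)$degenerate)
  # GEVAL mode: lower bound routed from the null-sensor stack
  nul <- gtpcoupling:::new_index_stack(array(rep(1:100 / 10, length.out = 100),
                                             c(10, 10, 1)),
                                       array(TRUE, c(10, 10, 1)), "gtp")
  ds2 <- display_scale(stk, null_stack = nul)
  expect_equal(ds2$lo, unname(quantile(1:100 / 10, 0.05)))
  expect_equal(ds2$hi, 95.05)
})

test_that("GTP index increases monotonically with latent GTP when noise-free", {
  cfg <- clean_config(seed = 35)
  sc <- simulate_scene(cfg)
  g <- compute_gtp_index(get_channel(sc$stack, "ex409"),
                         get_channel(sc$stack, "ex494"))
  sel <- sc$truth$mask
  ord <- order(sc$truth$gtp_field[, , 1][sel])
  vals <- g$index[, , 1][sel][ord]
  expect_true(all(diff(vals) >= -1e-12))
  # and equals the sensor response exactly (no bleach, equal excitations)
  expect_equal(g$index[, , 1][sel],
               sensor_response(sc$sensor, sc$truth$gtp_field[, , 1][sel]),
               tolerance = 1e-12)
})
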