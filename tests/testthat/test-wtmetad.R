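test_that("bias energy: empty state, peak value, periodic wrap", {
  b <- bias_state(20, 298)
  expect_equal(b$kB_deltaT, 0.0019872041 * 298 * 19, tolerance = 1e-12)
  expect_identical(bias_energy(b, c(1, 0.5, 0)), 0)
  b1 <- deposit_hill(b, c(3, 0.5, 1), t = 1, h0 = 0.287,
                     widths = c(1, 0.04, pi / 8))
  expect_equal(bias_energy(b1, c(3, 0.5, 1)), b1$hills$height[1],
               tolerance = 1e-12)
  # theta wraps: pi - 0.1 and -pi + 0.1 are 0.2 apart
  b2 <- deposit_hill(b, c(3, 0.5, pi - 0.1), t = 1, h0 = 0.287,
                     widths = c(1, 0.04, pi / 8))
  v_wrap <- bias_energy(b2, c(3, 0.5, -pi + 0.1))
  v_near <- bias_energy(b2, c(3, 0.5, pi - 0.1 - 0.2))
  expect_equal(v_wrap, v_near, tolerance = 1e-12)
  expect_error(bias_state(0.5, 298), "gamma")
})

test_that("well-tempered hill heights follow the scalar recursion", {
  # first hill at full height; the revisit is scaled by exp(-h0/kB dT)
  b <- bias_state(20, 298, cv_names = "rho", periodic = FALSE)
  expect_equal(next_hill_height(b, 0, 0.287), 0.287, tolerance = 1e-14)
  b <- deposit_hill(b, 0, 1, 0.287, 1)
  expect_equal(next_hill_height(b, 0, 0.287),
               0.287 * exp(-0.287 / 11.2515496), tolerance = 1e-7)
  # repeated deposition at a fixed point reproduces the closed recursion
  h0 <- 0.3; kbdT <- b$kB_deltaT
  V <- bias_energy(b, 0)   # the first 0.287 hill is already in the state
  for (k in 1:25) {
    h <- h0 * exp(-V / kbdT)
    b <- deposit_hill(b, 0, k + 1, h0, 1)
    V <- V + h
    expect_equal(bias_energy(b, 0), V, tolerance = 1e-10)
    expect_equal(b$hills$height[k + 1], h, tolerance = 1e-12)
  }
  # heights are non-increasing under repeated sampling and bounded by h0
  hh <- b$hills$height[-1]
  expect_true(all(diff(hh) <= 0))
  expect_true(all(hh > 0 & hh <= h0))
  # monotone decreasing in the accumulated bias
  expect_gt(next_hill_height(bias_state(20, 298, "rho", FALSE), 0, 1),
            next_hill_height(b, 0, 1))
  expect_error(deposit_hill(b, 0, t = b$hills$time[nrow(b$hills)], h0, 1),
               "sequencing error")
})

test_that("bias force is minus the gradient of the bias", {
  set.seed(4)
  b <- bias_state(10, 298)
  for (i in 1:30)
    b <- deposit_hill(b, c(runif(1, 1, 8), runif(1, 0, 1.2), runif(1, -pi, pi)),
                      t = i, h0 = 0.3, widths = c(0.4, 0.1, pi / 6))
  for (rep in 1:6) {
    s <- c(runif(1, 2, 7), runif(1, 0.1, 1), runif(1, -3, 3))
    g <- bias_gradient(b, s)
    h <- 1e-6
    fd <- vapply(1:3, function(j) {
      e <- rep(0, 3); e[j] <- h
      (bias_energy(b, s + e) - bias_energy(b, s - e)) / (2 * h)
    }, 1.0)
    expect_equal(as.numeric(g), fd, tolerance = 1e-6)
  }
})

test_that("zero hill height reproduces the unbiased trajectory bit for bit", {
  dw <- make_double_well(2 * kT(298), 0, 4)
  lp <- langevin_params(0.01, 3, 298, 40, seed = 9, n_steps = 20000)
  r1 <- run_lv_metad(dw, metad = metad_params(h0 = 0, stride = 1, widths = 1),
                     langevin = lp, out_stride = 0.5)
  r2 <- run_lv_metad(dw, metad = metad_params(h0 = 0, stride = 5, widths = 1),
                     langevin = lp, out_stride = 0.5)
  expect_identical(r1$trajectory$x1, r2$trajectory$x1)
  expect_true(all(r1$colvar$bias == 0))
  expect_identical(nrow(r1$hills), 0L)
})

test_that("the run loop books hills and frames consistently", {
  run <- dw_run(1)
  colvar <- run$res$colvar
  hills <- run$res$hills
  # every hill time appears in the COLVAR grid within one output stride
  out_dt <- diff(colvar$time[1:2])
  expect_true(all(vapply(hills$time, function(t)
    min(abs(colvar$time - t)) <= out_dt + 1e-9, TRUE)))
  expect_true(all(diff(hills$time) > 0))
  expect_true(all(hills$height > 0 & hills$height <= 0.06))
  expect_true(!is.unsorted(colvar$time, strictly = TRUE))
  # recorded bias matches an independent re-evaluation from the hill list
  i <- c(10, 5000, 20000, nrow(colvar))
  b <- run$res$bias
  for (k in i) {
    bk <- b
    bk$hills <- hills[hills$time <= colvar$time[k] + 1e-9, , drop = FALSE]
    expect_equal(bias_energy(bk, colvar$rho[k]), colvar$bias[k],
                 tolerance = 1e-9)
  }
  # the spatial range of the final bias is set by the sampled free-energy
  # range (the absolute offset grows slowly with time and is irrelevant)
  ktv <- kT(298)
  gmm <- run$res$meta$gamma
  sgrid <- seq(min(colvar$rho), max(colvar$rho), length.out = 300)
  f_range <- diff(range(run$fx$system$energy(sgrid)))
  v_range <- diff(range(bias_energy(b, matrix(sgrid, ncol = 1))))
  expect_lt(v_range, gmm / (gmm - 1) * f_range + 5 * ktv)
})

test_that("identical config and seed give identical outputs", {
  fx <- double_well_fixture(seed = 17, run_ps = 200, window_ps = 100)
  r1 <- run_lv_metad(fx$system, metad = fx$metad, langevin = fx$langevin,
                     out_stride = fx$out_stride)
  r2 <- run_lv_metad(fx$system, metad = fx$metad, langevin = fx$langevin,
                     out_stride = fx$out_stride)
  expect_identical(r1$colvar, r2$colvar)
  expect_identical(r1$hills, r2$hills)
})
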