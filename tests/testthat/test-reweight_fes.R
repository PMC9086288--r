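make_uniform_colvar <- function(rho, d = rho / 10, nhb = 0, bias = 0) {
  n <- length(rho)
  data.frame(time = seq_len(n) * 0.1, rho = rho, tau = 0, theta = 0,
             bias = rep(bias, length.out = n), d = d,
             nhb = rep(nhb, length.out = n))
}

test_that("c(t) identities: zero bias, constant bias, grid refinement", {
  b <- bias_state(10, 298, cv_names = "rho", periodic = FALSE)
  grid <- list(seq(-2, 2, by = 0.02))
  ct0 <- compute_ct(b, grid, eval_times = c(1, 5, 10))
  expect_equal(ct0$ct, c(0, 0, 0), tolerance = 1e-14)
  # a quasi-constant bias (hill much wider than the grid) gives c(t) = c0
  bc <- deposit_hill(b, 0, t = 1, h0 = 0.7, widths = 1e6)
  ctc <- compute_ct(bc, list(seq(-2, 2, by = 0.05)), eval_times = c(2, 5))
  expect_equal(ctc$ct, c(0.7, 0.7), tolerance = 1e-6)
  # refinement on a synthetic hill set
  set.seed(2)
  bs <- bias_state(10, 298, cv_names = "rho", periodic = FALSE)
  for (i in 1:40)
    bs <- deposit_hill(bs, runif(1, -1.5, 1.5), t = i, h0 = 0.3, widths = 0.2)
  tt <- c(10, 20, 40)
  c1 <- compute_ct(bs, list(seq(-2.5, 2.5, by = 0.05)), tt)
  c2 <- compute_ct(bs, list(seq(-2.5, 2.5, by = 0.025)), tt)
  expect_true(all(abs(c1$ct - c2$ct) < 0.01))
  expect_error(compute_ct(bs, list(seq(-2.5, 2.5, by = 0.2)), tt),
               "resolution error")
})

test_that("frame weights: uniform under zero or constant shifted bias", {
  cv <- make_uniform_colvar(rho = rnorm(50))
  ct <- data.frame(time = 0, ct = 0)
  w <- frame_weights(cv, ct, beta = 1 / kT(298), t_start = 0)
  expect_equal(w, rep(1 / 50, 50), tolerance = 1e-14)
  # same V - c everywhere: still uniform after normalisation
  cv2 <- make_uniform_colvar(rho = rnorm(50), bias = 3.3)
  ct2 <- data.frame(time = 0, ct = 1.1)
  w2 <- frame_weights(cv2, ct2, beta = 1 / kT(298), t_start = 0)
  expect_equal(w2, rep(1 / 50, 50), tolerance = 1e-14)
  # frames before t_start get zero weight
  w3 <- frame_weights(cv, ct, beta = 1 / kT(298), t_start = 2.05)
  expect_true(all(w3[cv$time < 2.05] == 0))
  expect_equal(sum(w3), 1, tolerance = 1e-14)
  expect_error(frame_weights(cv[, setdiff(names(cv), "bias")], ct, 1, 0),
               "schema error")
})

test_that("unbiased reweighted FES equals the histogram free energy exactly", {
  dw <- make_double_well(1.5 * kT(298), 0, 4)
  lp <- langevin_params(0.01, 3, 298, 40, seed = 21, n_steps = 100000)
  res <- run_lv_metad(dw, metad = metad_params(h0 = 0, widths = 1),
                      langevin = lp, out_stride = 1)
  ct <- data.frame(time = 0, ct = 0)
  ktv <- kT(298)
  w <- frame_weights(res$colvar, ct, beta = 1 / ktv, t_start = 0)
  xe <- seq(-3.5, 3.5, length.out = 15); ye <- c(-0.5, 0.5)
  fes <- project_fes(res$colvar, w, "rho", "nhb", xe, ye, kT = ktv)
  ib <- findInterval(res$colvar$rho, xe, rightmost.closed = TRUE)
  cnt <- tabulate(ib[ib >= 1 & ib <= 14], nbins = 14)
  Fh <- -ktv * log(cnt / sum(cnt))
  Fh <- Fh - min(Fh[is.finite(Fh)])
  samp <- fes$sampled[, 1]
  expect_equal(fes$F[samp, 1], Fh[samp], tolerance = 1e-12)
  expect_true(all(is.na(fes$F[!samp, 1])))
})

test_that("FES projection: single frame, flat case, marginalisation identity", {
  ktv <- kT(298)
  cv1 <- make_uniform_colvar(rho = 1.05)
  f1 <- project_fes(cv1, 1, "rho", "nhb", c(0, 1, 2), c(-1, 1), kT = ktv)
  expect_equal(f1$F[2, 1], 0)
  expect_true(is.na(f1$F[1, 1]))
  # uniform weights over two cells: dF = 0
  cv2 <- make_uniform_colvar(rho = rep(c(0.5, 1.5), 40))
  w2 <- rep(1 / 80, 80)
  f2 <- project_fes(cv2, w2, "rho", "nhb", c(0, 1, 2), c(-1, 1), kT = ktv)
  expect_equal(f2$F[1, 1], f2$F[2, 1], tolerance = 1e-12)
  # marginalising the 2D FES over y reproduces the direct 1D projection
  set.seed(6)
  cvr <- make_uniform_colvar(rho = runif(500, 0, 3), nhb = runif(500, 0, 2))
  wr <- runif(500); wr <- wr / sum(wr)
  xe <- seq(0, 3, by = 0.5); ye <- seq(0, 2, by = 0.25)
  f2d <- project_fes(cvr, wr, "rho", "nhb", xe, ye, kT = ktv)
  f1d <- project_fes(cvr, wr, "rho", "nhb", xe, c(0, 2), kT = ktv)
  marg <- -ktv * log(rowSums(f2d$W))
  expect_equal(marg - min(marg), as.numeric(f1d$F), tolerance = 1e-10)
  expect_error(project_fes(cvr, rep(0, 500), "rho", "nhb", xe, ye, kT = ktv),
               "empty-selection")
  expect_error(project_fes(cvr, wr, "rho", "nhb", c(1, 1), ye, kT = ktv),
               "parameter error")
})

test_that("block errors: duplicated blocks vanish, two-point SE is delta/2", {
  ktv <- kT(298)
  # duplicated data: every block identical, errors are zero
  base <- rep(c(0.5, 1.5, 1.5, 0.5), 10)
  cv <- make_uniform_colvar(rho = rep(base, 4))
  w <- rep(1 / 160, 160)
  err <- block_error(cv, w, "rho", "nhb", c(0, 1, 2), c(-1, 1), n_blocks = 4,
                     kT = ktv)
  expect_equal(max(err, na.rm = TRUE), 0, tolerance = 1e-12)
  # two equal-mass blocks whose F differs by delta in one cell -> err delta/2
  nb <- 40
  rho_b1 <- c(rep(0.5, 30), rep(1.5, 10))   # block 1
  rho_b2 <- c(rep(0.5, 20), rep(1.5, 20))   # block 2
  cv2 <- make_uniform_colvar(rho = c(rho_b1, rho_b2))
  w2 <- rep(1 / 80, 80)
  err2 <- block_error(cv2, w2, "rho", "nhb", c(0, 1, 2), c(-1, 1),
                      n_blocks = 2, kT = ktv)
  d_cell1 <- abs(-ktv * log(30 / 40) - (-ktv * log(20 / 40)))
  expect_equal(err2[1, 1], d_cell1 / 2, tolerance = 1e-10)
  expect_error(block_error(cv2, w2, "rho", "nhb", c(0, 1, 2), c(-1, 1),
                           n_blocks = 1, kT = ktv), "parameter error")
})

test_that("block error stabilises against the block count on the fixture run", {
  run <- dw_run(1)
  ktv <- kT(298)
  w <- run$analysis$weights
  xe <- seq(-3, 3, length.out = 25); ye <- c(-1, 1)
  e5 <- block_error(run$res$colvar, w, "rho", "nhb", xe, ye, n_blocks = 5,
                    kT = ktv)
  e10 <- block_error(run$res$colvar, w, "rho", "nhb", xe, ye, n_blocks = 10,
                     kT = ktv)
  # the typical (median) cell error has plateaued by 5 blocks
  common <- !is.na(e5) & !is.na(e10)
  m5 <- stats::median(e5[common]); m10 <- stats::median(e10[common])
  expect_lt(abs(m5 - m10) / m5, 0.2)
  expect_true(all(e5[common] >= 0))
})

test_that("watershed basins: counts, minima and shallow-basin merging", {
  ktv <- kT(298)
  xe <- seq(0, 1, length.out = 21); ye <- seq(0, 1, length.out = 21)
  xc <- (xe[-1] + xe[-21]) / 2; yc <- (ye[-1] + ye[-21]) / 2
  two_wells <- outer(xc, yc, function(x, y)
    -3 * exp(-((x - 0.25)^2 + (y - 0.5)^2) / 0.02) -
     2 * exp(-((x - 0.75)^2 + (y - 0.5)^2) / 0.02))
  fes <- list(x_edges = xe, y_edges = ye, F = two_wells - min(two_wells),
              err = NULL, sampled = matrix(TRUE, 20, 20), kT = ktv,
              x_col = "d", y_col = "nhb")
  class(fes) <- "fes2d"
  bs <- find_basins(fes, depth_cutoff = 2)
  expect_identical(nrow(bs$basins), 2L)
  expect_identical(bs$basins$label, c("I", "II"))
  # each basin contains its own minimum cell
  for (k in 1:2) {
    cells <- which(bs$assignment == k)
    expect_equal(min(fes$F[cells]), bs$basins$F_min[k])
  }
  expect_lt(bs$basins$x_hi[1], 0.6)   # deepest basin sits on the left
  expect_gt(bs$basins$x_lo[2], 0.4)
  # a cutoff below the depth difference leaves a single basin
  bs1 <- find_basins(fes, depth_cutoff = 0.5)
  expect_identical(nrow(bs1$basins), 1L)
  # single well: one basin
  one <- outer(xc, yc, function(x, y) 4 * ((x - 0.5)^2 + (y - 0.5)^2))
  fes1 <- fes; fes1$F <- one - min(one)
  expect_identical(nrow(find_basins(fes1, 2)$basins), 1L)
})

test_that("printed basin windows classify the bound-state frame", {
  win <- furosemide_basin_windows()
  expect_identical(assign_basin(0.85, 7, win), "I")
  expect_identical(assign_basin(1.25, 6, win), "II")
  expect_identical(assign_basin(1.6, 3, win), "III")
  expect_true(is.na(assign_basin(0.3, 1, win)))
})

test_that("delta_g: flat case, antisymmetry, degenerate inputs", {
  ktv <- kT(298)
  cv <- make_uniform_colvar(rho = rep(c(0.5, 1.5), 50))
  w <- rep(1 / 100, 100)
  bound <- list(rho = c(0, 1)); unbound <- list(rho = c(1.001, 2))
  dg <- delta_g(w, cv, bound, unbound, kT = ktv, n_blocks = 5)
  expect_equal(dg$delta_g, 0, tolerance = 1e-12)
  dg_swap <- delta_g(w, cv, unbound, bound, kT = ktv, n_blocks = 5)
  expect_equal(dg_swap$delta_g, -dg$delta_g, tolerance = 1e-14)
  expect_error(delta_g(w, cv, bound, list(rho = c(0.5, 2)), kT = ktv),
               "region error")
  expect_error(delta_g(w, cv, bound, list(rho = c(8, 9)), kT = ktv),
               "undefined-deltaG")
  # standard-state correction wiring
  vol <- test_vol()
  cv3 <- make_uniform_colvar(rho = rep(c(2, 8), 50))
  dg3 <- delta_g(rep(0.01, 100), cv3, list(rho = c(0, 4)),
                 list(rho = c(7, 8.5)), kT = ktv, vol = vol,
                 standard_volume = 1660, host_com = c(0, 0, 0))
  expect_true(is.finite(dg3$volume_correction))
  expect_equal(dg3$delta_g_std, dg3$delta_g + dg3$volume_correction)
  expect_gt(dg3$V_unbound, 0)
})

test_that("region volumes grow with the shell and respect the walls", {
  vol <- test_vol()
  v1 <- region_volume(vol, c(7, 8), spacing = 0.2)
  v2 <- region_volume(vol, c(7, 8.5), spacing = 0.2)
  expect_gt(v2, v1)
  # the restrained shell is much smaller than the free spherical shell
  free_shell <- 4 / 3 * pi * (8.5^3 - 7^3)
  expect_lt(v2, free_shell / 2)
})
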