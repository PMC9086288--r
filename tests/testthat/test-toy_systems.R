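test_that("double-well construction, symmetry and preconditions", {
  ktv <- kT(298)
  dw <- make_double_well(barrier = 5 * ktv, asymmetry = 0, separation = 4)
  # minima at +/- s/2 with equal energy, barrier at 0
  expect_equal(dw$energy(c(-2, 2)), c(0, 0), tolerance = 1e-12)
  expect_equal(dw$energy(0), 5 * ktv, tolerance = 1e-12)
  # symmetric wells: free-energy difference vanishes
  f <- reference_free_energy(dw, list(lo = -4, hi = 0), list(lo = 0, hi = 4), 298)
  expect_lt(abs(f), 1e-10)
  expect_error(make_double_well(-1, 0, 4), "parameter error")
  expect_error(make_double_well(3, 0, -2), "parameter error")
})

test_that("potential gradients match central finite differences", {
  set.seed(11)
  ktv <- kT(298)
  pots <- list(make_double_well(5 * ktv, ktv, 4),
               make_harmonic(2, 0.3, 1L),
               make_host_guest())
  for (pot in pots) {
    for (rep in 1:8) {
      x <- runif(pot$dim, pot$bounds[1, ] + 0.5, pot$bounds[2, ] - 0.5)
      g <- pot$gradient(x)
      h <- 1e-5
      fd <- vapply(seq_len(pot$dim), function(j) {
        e <- rep(0, pot$dim); e[j] <- h
        (pot$energy(x + e) - pot$energy(x - e)) / (2 * h)
      }, 1.0)
      expect_equal(g, fd, tolerance = 1e-5)
    }
    expect_true(all(is.finite(pot$energy(matrix(pot$bounds[1, ], nrow = 1)))))
  }
})

test_that("host-guest model validates its configuration", {
  hg <- make_host_guest()
  # potential minimum sits inside the binding region
  pocket <- as.numeric(hg$host_sites[1, c("x", "y", "z")])
  expect_lt(hg$energy(pocket), hg$energy(c(8, 0, 0)) - 3)
  rho_pocket <- sqrt(sum((pocket - hg$host_com)^2))
  expect_true(rho_pocket >= hg$binding_region$rho[1] &&
              rho_pocket <= hg$binding_region$rho[2])
  # zero well depths give a flat potential: equal-volume boxes have dF = 0
  cfg <- host_guest_config()
  cfg$sites$depth <- 0
  flat <- make_host_guest(cfg)
  f <- reference_free_energy(flat,
                             list(lo = c(1, -2, -2), hi = c(3, 2, 2)),
                             list(lo = c(5, -2, -2), hi = c(7, 2, 2)),
                             298, spacing = 0.2)
  expect_lt(abs(f), 1e-10)
  cfg2 <- host_guest_config()
  cfg2$sites$x[1] <- 99
  expect_error(make_host_guest(cfg2), "config error")
  cfg3 <- host_guest_config()
  cfg3$sites$type <- "apolar"
  expect_error(make_host_guest(cfg3), "polar")
})

test_that("langevin_step is deterministic and inert without forces", {
  flat <- make_flat(matrix(c(-5, 5), 2), dim = 1L)
  p <- langevin_params(0.01, 1e-12, 1e-12, 40, seed = 1, n_steps = 10)
  st <- list(position = 1.23, velocity = 0)
  for (i in 1:20) st <- langevin_step(st, flat, params = p)
  expect_equal(st$position, 1.23, tolerance = 1e-12)
  # identical seeds give bit-identical trajectories
  hp <- make_harmonic(2, 0, 1L)
  p2 <- langevin_params(0.01, 5, 298, 40, seed = 3, n_steps = 100)
  run_traj <- function() {
    set.seed(p2$seed)
    st <- list(position = 0.5, velocity = 0)
    xs <- numeric(100)
    for (i in 1:100) { st <- langevin_step(st, hp, params = p2); xs[i] <- st$position }
    xs
  }
  expect_identical(run_traj(), run_traj())
  # the external_force hook enters the total force
  pull <- function(x) 2 * 2 * x   # cancels the harmonic force exactly... plus kick
  st0 <- list(position = 1, velocity = 0)
  st1 <- langevin_step(st0, hp, external_force = function(x) 2 * x, params = p)
  expect_equal(st1$position, 1, tolerance = 1e-12)  # forces cancel at T = 0
  expect_error(
    langevin_step(st0, hp, external_force = function(x) NaN, params = p2),
    "integration error.*step")
})

test_that("harmonic sampling satisfies equipartition", {
  hp <- make_harmonic(2, 0, 1L)
  p <- langevin_params(0.01, 5, 298, 40, seed = 7, n_steps = 200000)
  set.seed(p$seed)
  st <- list(position = 0, velocity = 0)
  xs <- numeric(p$n_steps %/% 5)
  for (i in seq_len(p$n_steps %/% 5)) {
    for (k in 1:5) st <- langevin_step(st, hp, params = p)
    xs[i] <- st$position
  }
  expect_equal(var(xs), kT(298) / 2, tolerance = 0.05)
})

test_that("deterministic limit conserves energy", {
  hp <- make_harmonic(2, 0, 1L)
  p <- langevin_params(0.002, 1e-12, 1e-12, 40, seed = 1, n_steps = 1000)
  st <- list(position = 0.7, velocity = 0)
  e_of <- function(s) hp$energy(s$position) + 0.5 * 40 * s$velocity^2 / 418.4
  e0 <- e_of(st)
  for (i in 1:1000) st <- langevin_step(st, hp, params = p)
  expect_lt(abs(e_of(st) - e0), 1e-4)
})

test_that("unbiased double-well sampling reproduces the Boltzmann histogram", {
  ktv <- kT(298)
  dw <- make_double_well(barrier = 1 * ktv, asymmetry = 0.5 * ktv, separation = 4)
  lp <- langevin_params(0.01, 3, 298, 40, seed = 5, n_steps = 1000000)
  res <- run_lv_metad(dw, metad = metad_params(h0 = 0, widths = 1),
                      langevin = lp, out_stride = 5)
  x <- res$trajectory$x1[-(1:200)]   # drop the equilibration stretch
  edges <- seq(-3.2, 3.2, length.out = 13)
  x <- x[x >= -3.2 & x <= 3.2]
  obs <- table(cut(x, edges))
  # expected bin probabilities from quadrature of exp(-beta U)
  xg <- seq(-3.2, 3.2, length.out = 4001)
  pg <- exp(-dw$energy(xg) / ktv)
  bin <- cut(xg, edges)
  pexp <- tapply(pg, bin, sum); pexp <- pexp / sum(pexp)
  n <- sum(obs)
  chi2 <- sum((as.numeric(obs) - n * pexp)^2 / (n * pexp))
  # 99th percentile of the same-size multinomial chi^2
  set.seed(99)
  sims <- replicate(600, {
    o <- as.numeric(stats::rmultinom(1, n, pexp))
    sum((o - n * pexp)^2 / (n * pexp))
  })
  expect_lt(chi2, stats::quantile(sims, 0.99))
})

test_that("quadrature oracle: antisymmetry, volume ratios and refinement", {
  ktv <- kT(298)
  dw <- make_double_well(5 * ktv, ktv, 4)
  a <- list(lo = -4, hi = 0); b <- list(lo = 0, hi = 4)
  f_ab <- reference_free_energy(dw, a, b, 298)
  f_ba <- reference_free_energy(dw, b, a, 298)
  expect_equal(as.numeric(f_ab), -as.numeric(f_ba), tolerance = 1e-12)
  # flat potential: dF is set purely by the volume ratio
  fl <- make_flat(matrix(c(0, 3), 2), dim = 1L)
  f2 <- reference_free_energy(fl, list(lo = 0, hi = 2), list(lo = 2, hi = 3), 298)
  expect_equal(as.numeric(f2), -kT(298) * log(2), tolerance = 1e-12)
  # refinement: halving the grid spacing barely moves the result
  f_h <- reference_free_energy(dw, a, b, 298, spacing = 0.02)
  f_h2 <- reference_free_energy(dw, a, b, 298, spacing = 0.01)
  expect_lt(abs(as.numeric(f_h) - as.numeric(f_h2)), 0.01)
  expect_lt(attr(f_h2, "error"), 0.01)
  # overlapping regions are rejected
  expect_error(
    reference_free_energy(dw, list(lo = -4, hi = 1), list(lo = 0, hi = 4), 298),
    "region error")
})
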