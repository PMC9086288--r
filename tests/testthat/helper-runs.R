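# Memoised fixture runs shared across test files (testthat keeps helper state
# for the whole test_dir session, so each trajectory is generated once).
.run_cache <- new.env(parent = emptyenv())

dw_run <- function(seed) {
  key <- paste0("dw", seed)
  if (is.null(.run_cache[[key]])) {
    fx <- double_well_fixture(seed = seed)
    res <- run_lv_metad(fx$system, metad = fx$metad, langevin = fx$langevin,
                        out_stride = fx$out_stride)
    .run_cache[[key]] <- list(fx = fx, res = res,
                              analysis = reweight_run_1d(res, fx))
  }
  .run_cache[[key]]
}

hg_run <- function(seed = 1) {
  key <- paste0("hg", seed)
  if (is.null(.run_cache[[key]])) {
    fx <- host_guest_fixture(seed = seed)
    res <- run_lv_metad(fx$system, fx$vol, fx$metad, fx$langevin,
                        observables = fx$observables, out_stride = fx$out_stride)
    .run_cache[[key]] <- list(fx = fx, res = res,
                              analysis = analyze_host_guest(res, fx))
  }
  .run_cache[[key]]
}

test_vol <- function() {
  volume_spec(origin = c(0, 0, 0), axis = c(1, 0, 0), k = 2.5, a0 = -1,
              rho_max = 9, tau_max = 1.2, wall_k = 20, a_min = 0.5)
}

# random points strictly inside the parabolic volume (away from the axis and
# the walls)
random_interior_points <- function(n, vol, seed = 42) {
  set.seed(seed)
  a <- runif(n, vol$a_min + 0.3, 7)
  tau <- runif(n, 0.1, 0.9 * vol$tau_max)
  th <- runif(n, -pi + 0.05, pi - 0.05)
  t(vapply(seq_len(n), function(i) {
    rp <- tau[i] * sqrt(vol$k * (a[i] - vol$a0))
    c(a[i], rp * cos(th[i]), rp * sin(th[i]))
  }, numeric(3)))
}
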