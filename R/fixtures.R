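#' @title Fixture registry
#'
#' @description The toy study conditions are frozen here, in code, so every
#'   test, the demo and the acceptance analysis run the same systems.  The
#'   magnitudes (well depths, barriers, metadynamics hyper-parameters of the
#'   toy runs) are the package's own choices, recorded and motivated in the
#'   methods vignette; production LV-MetaD defaults (0.287 kcal/mol hills,
#'   widths 1 A / 0.04 / pi/8, bias factor 20) remain the defaults of
#'   [metad_params()] for real-system analyses.
#' @name fixtures
NULL

#' 1D double-well fixture
#'
#' Barrier and asymmetry are given in units of kT at the run temperature
#' (defaults: 5 kT barrier, 1 kT asymmetry, minima 4 A apart at 298 K).  The
#' toy metadynamics settings (h0 = 0.06 kcal/mol, gamma = 10, sigma = 0.2 A,
#' 1 ps stride over 8 ns) are scaled to the ~3 kcal/mol toy barrier: hills
#' narrow against the well width keep the O(sigma^2 F'') kernel-width bias of
#' the converged profile small, and late-stage hill heights an order of
#' magnitude below kT keep the residual ripple of V(s, t_end) well inside
#' the half-kT convergence band.
#'
#' @param seed RNG seed
#' @param barrier_kT,asymmetry_kT well parameters in units of kT
#' @param separation minima separation, A
#' @param temperature Kelvin
#' @param run_ps trajectory length, ps
#' @param window_ps reweighting window (taken from the end of the run)
#' @return a fixture list: system, langevin, metad, temperature, regions,
#'   t_start, n_blocks
#' @export
double_well_fixture <- function(seed = 1L, barrier_kT = 5, asymmetry_kT = 1,
                                separation = 4, temperature = 298,
                                run_ps = 8000, window_ps = 3000) {
  ktv <- kT(temperature)
  system <- make_double_well(barrier = barrier_kT * ktv,
                             asymmetry = asymmetry_kT * ktv,
                             separation = separation)
  timestep <- 0.01
  langevin <- langevin_params(timestep = timestep, friction = 3,
                              temperature = temperature, mass = 40,
                              seed = seed, n_steps = round(run_ps / timestep))
  metad <- metad_params(h0 = 0.06, stride = 1, widths = c(rho = 0.2),
                        gamma = 10, periodic_theta = FALSE)
  list(system = system, langevin = langevin, metad = metad,
       temperature = temperature, separation = separation,
       out_stride = 0.2,
       regions = list(left = list(rho = c(-separation, 0)),
                      right = list(rho = c(1e-9, separation))),
       t_start = run_ps - window_ps, n_blocks = 5)
}

#' Quadrature reference for the double-well fixture
#'
#' @param fx fixture from [double_well_fixture()]
#' @return F(left) - F(right) in kcal/mol (attribute "error": discretization)
#' @export
dw_reference_delta_f <- function(fx) {
  s <- fx$separation
  reference_free_energy(fx$system,
                        region_a = list(lo = -s, hi = 0),
                        region_b = list(lo = 0, hi = s),
                        temperature = fx$temperature)
}

#' Reweight a 1D double-well run
#'
#' Builds the c(t) series on a rho grid covering the sampled range, computes
#' frame weights over the fixture's reweighting window, and reads off the
#' left/right well free-energy difference.
#'
#' @param res an \code{lvmetad_run} from [run_lv_metad()]
#' @param fx the fixture used to produce it
#' @param ct_stride spacing of c(t) evaluation times, ps
#' @return list with \code{delta_f} (kcal/mol, left minus right),
#'   \code{delta_f_err} (block SE), \code{weights}, \code{ct}, \code{grid}
#' @export
reweight_run_1d <- function(res, fx, ct_stride = 5) {
  bias <- res$bias
  h <- bias$hills
  sig <- min(h$sigma_rho)
  grid <- list(seq(min(h$rho) - 3 * max(h$sigma_rho),
                   max(h$rho) + 3 * max(h$sigma_rho), by = sig / 4))
  tmax <- max(res$colvar$time)
  eval_times <- sort(unique(c(fx$t_start, seq(fx$t_start, tmax, by = ct_stride),
                              tmax)))
  ct <- compute_ct(bias, grid, eval_times)
  ktv <- kT(fx$temperature)
  w <- frame_weights(res$colvar, ct, beta = 1 / ktv, t_start = fx$t_start)
  dg <- delta_g(w, res$colvar, fx$regions$left, fx$regions$right, kT = ktv,
                n_blocks = fx$n_blocks)
  list(delta_f = dg$delta_g, delta_f_err = dg$err, weights = w, ct = ct,
       grid = grid[[1]])
}

#' Well-tempered convergence profile of a 1D run
#'
#' Returns \eqn{\gamma/(\gamma-1)\, V(s, t_{end}) + F_{ref}(s)} on a grid
#' restricted to the range where the reference free energy lies within
#' \code{level} of its minimum (for a 1D system, \eqn{F_{ref}(s) = U(s)} up
#' to a constant).  At convergence this combination is flat in s.
#'
#' @param res an \code{lvmetad_run}
#' @param fx the fixture
#' @param level kcal/mol window above the minimum defining the sampled range
#'   (default: the fixture's nominal barrier)
#' @return data.frame with s, V, F_ref and the combination \code{flat}
#' @export
wt_convergence_profile <- function(res, fx, level = NULL) {
  gamma <- res$meta$gamma
  if (is.null(level)) level <- fx$system$cpp$barrier
  s <- seq(-0.75 * fx$separation, 0.75 * fx$separation, length.out = 400)
  Fref <- fx$system$energy(s)
  keep <- Fref <= min(Fref) + level
  s <- s[keep]; Fref <- Fref[keep]
  V <- bias_energy(res$bias, matrix(s, ncol = 1))
  comb <- gamma / (gamma - 1) * V + Fref
  data.frame(s = s, V = V, F_ref = Fref, flat = comb - mean(comb))
}

#' 3D host-guest fixture
#'
#' The default [make_host_guest()] pocket inside a parabolic-solid volume
#' (k = 2.5 A, apex offset a0 = -1 A, rho wall at 9 A, tau wall at 1.2,
#' wall stiffness 20 kcal/mol, axial floor at 0.5 A).  Toy metadynamics:
#' h0 = 0.3 kcal/mol, stride 1 ps, widths (0.4 A, 0.1, pi/6), gamma = 10;
#' 12 ns runs reweighted over the final 6 ns, long enough that the block
#' length exceeds the slow bound/unbound drift time of the weighted ratio.
#' The d axis of the output map is referenced to the deep apolar pocket site
#' (the toy analogue of a cluster-site reference) and reported in nm.
#'
#' @param seed RNG seed
#' @param run_ps trajectory length, ps
#' @param window_ps reweighting window from the end of the run
#' @param temperature Kelvin
#' @return fixture list: system, vol, langevin, metad, observables, regions,
#'   t_start, n_blocks
#' @export
host_guest_fixture <- function(seed = 1L, run_ps = 12000, window_ps = 6000,
                               temperature = 298) {
  system <- make_host_guest()
  vol <- volume_spec(origin = c(0, 0, 0), axis = c(1, 0, 0), k = 2.5,
                     a0 = -1, rho_max = 9, tau_max = 1.2, wall_k = 20,
                     a_min = 0.5)
  timestep <- 0.005
  langevin <- langevin_params(timestep = timestep, friction = 2,
                              temperature = temperature, mass = system$guest_mass,
                              seed = seed, n_steps = round(run_ps / timestep))
  metad <- metad_params(h0 = 0.3, stride = 1,
                        widths = c(rho = 0.4, tau = 0.1, theta = pi / 6),
                        gamma = 10, periodic_theta = TRUE)
  apolar <- system$host_sites[system$host_sites$type == "apolar", ][1, ]
  observables <- list(d_ref = c(apolar$x, apolar$y, apolar$z), d_scale = 0.1)
  list(system = system, vol = vol, langevin = langevin, metad = metad,
       observables = observables, temperature = temperature,
       out_stride = 0.2,
       regions = list(bound = list(rho = c(0, 4)),
                      unbound = list(rho = c(7, 8.5))),
       t_start = run_ps - window_ps, n_blocks = 5)
}

#' Reweight a 3D host-guest run and estimate the binding free energy
#'
#' @param res an \code{lvmetad_run} from the host-guest fixture
#' @param fx the fixture
#' @param ct_stride spacing of c(t) evaluation times, ps
#' @return list with \code{delta_g} (bound minus unbound, kcal/mol),
#'   \code{err} (block SE), \code{weights}, \code{ct}
#' @export
analyze_host_guest <- function(res, fx, ct_stride = 10) {
  bias <- res$bias
  h <- bias$hills
  # integrate c(t) over the interior of the restraint volume, where the bias
  # converges to -(1 - 1/gamma) F; cells beyond the walls carry wall energy
  # the (confined) bias never compensates and would distort the estimator
  grid <- list(
    rho   = seq(max(0.2, min(h$rho) - 1), fx$vol$rho_max, by = 0.4 / 4),
    tau   = seq(0, fx$vol$tau_max, by = 0.1 / 4),
    theta = seq(-pi, pi - pi / 24, by = pi / 24)
  )
  tmax <- max(res$colvar$time)
  eval_times <- sort(unique(c(fx$t_start, seq(fx$t_start, tmax, by = ct_stride),
                              tmax)))
  ct <- compute_ct(bias, grid, eval_times)
  ktv <- kT(fx$temperature)
  w <- frame_weights(res$colvar, ct, beta = 1 / ktv, t_start = fx$t_start)
  dg <- delta_g(w, res$colvar, fx$regions$bound, fx$regions$unbound, kT = ktv,
                n_blocks = fx$n_blocks)
  list(delta_g = dg$delta_g, err = dg$err, weights = w, ct = ct)
}

#' Quadrature reference binding free energy for the host-guest fixture
#'
#' Integrates the restrained potential (pocket plus walls) over the bound and
#' unbound rho shells: the same regions, and the same restrained Boltzmann
#' measure, that the biased simulation samples.
#'
#' @param fx fixture from [host_guest_fixture()]
#' @param spacing quadrature grid spacing, A
#' @return Delta G (bound minus unbound) in kcal/mol, attribute "error"
#' @export
hg_reference_delta_g <- function(fx, spacing = 0.1) {
  pot <- restrain_potential(fx$system, fx$vol)
  host <- fx$system$host_com
  rho_of <- function(X) sqrt(rowSums(sweep(X, 2, host)^2))
  rb <- fx$regions$bound$rho; ru <- fx$regions$unbound$rho
  bound <- list(lo = c(-0.6, -rb[2] - 0.2, -rb[2] - 0.2),
                hi = c(rb[2], rb[2] + 0.2, rb[2] + 0.2),
                predicate = function(X) {
                  r <- rho_of(X); r >= rb[1] & r <= rb[2]
                })
  rmax <- ru[2]
  unbound <- list(lo = c(1.5, -7, -7), hi = c(rmax, 7, 7),
                  predicate = function(X) {
                    r <- rho_of(X); r >= ru[1] & r <= ru[2]
                  })
  reference_free_energy(pot, bound, unbound, fx$temperature, spacing = spacing)
}
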