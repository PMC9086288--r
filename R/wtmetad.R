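#' @title Well-tempered metadynamics bias
#'
#' @description Gaussian hills are deposited along the collective variables at
#'   a fixed time stride; in the well-tempered protocol each new hill is
#'   scaled by \eqn{\exp(-V(s,t)/k_B \Delta T)} with
#'   \eqn{k_B \Delta T = k_B T (\gamma - 1)}, so the bias converges to
#'   \eqn{-(1 - 1/\gamma) F(s)} up to a constant.  Defaults mirror the
#'   production LV-MetaD protocol for solvated protein-ligand systems: initial
#'   height 0.287 kcal/mol, deposition every 1 ps, widths (1 A, 0.04, pi/8)
#'   on (rho, tau, theta), bias factor 20 at 298 K.  Toy runs override these
#'   (documented in the fixture registry) because toy barriers are not at the
#'   all-atom scale.
#' @name wtmetad
NULL

#' Empty well-tempered bias state
#'
#' @param gamma bias factor (> 1); \eqn{\gamma = (T + \Delta T)/T}
#' @param temperature Kelvin
#' @param cv_names names of the biased CVs, e.g. \code{c("rho","tau","theta")}
#'   or just \code{"rho"} for 1D runs
#' @param periodic logical per CV; defaults to TRUE for a CV named "theta"
#' @return a \code{bias_state} with an empty hill list and the derived
#'   \eqn{k_B \Delta T}
#' @examples
#' b <- bias_state(gamma = 20, temperature = 298)
#' b$kB_deltaT  # 0.0019872041 * 298 * 19
#' @export
bias_state <- function(gamma, temperature,
                       cv_names = c("rho", "tau", "theta"),
                       periodic = cv_names == "theta") {
  if (gamma <= 1) stop("parameter error: gamma must exceed 1", call. = FALSE)
  ncv <- length(cv_names)
  hills <- as.data.frame(setNames(
    c(list(numeric(0)), rep(list(numeric(0)), 2 * ncv), list(numeric(0))),
    c("time", cv_names, paste0("sigma_", cv_names), "height")))
  b <- list(hills = hills, gamma = gamma, temperature = temperature,
            kB_deltaT = kB_KCAL * temperature * (gamma - 1),
            cv_names = cv_names, periodic = periodic)
  class(b) <- "bias_state"
  b
}

hills_matrices <- function(bias) {
  h <- bias$hills
  cvn <- bias$cv_names
  list(times = h$time,
       centers = as.matrix(h[, cvn, drop = FALSE]),
       sigmas = as.matrix(h[, paste0("sigma_", cvn), drop = FALSE]),
       heights = h$height,
       periodic = bias$periodic)
}

#' Bias potential at a point in CV space
#'
#' \deqn{V(s) = \sum_i h_i \prod_j \exp(-\Delta s_{ij}^2 / 2\sigma_{ij}^2)}
#' with the theta difference wrapped into \eqn{(-\pi, \pi]}.
#'
#' @param bias a [bias_state()]
#' @param s CV point (vector of length ncv) or an n x ncv matrix
#' @return bias energy in kcal/mol (vector for matrix input)
#' @export
bias_energy <- function(bias, s) {
  m <- hills_matrices(bias)
  S <- if (is.matrix(s)) s else matrix(as.numeric(s), nrow = 1)
  if (nrow(m$centers) == 0) return(rep(0, nrow(S)))
  v <- cpp_bias_energy(m$centers, m$sigmas, m$heights, S, m$periodic)
  if (is.matrix(s)) v else v[[1]]
}

#' Gradient of the bias with respect to the CVs
#'
#' @inheritParams bias_energy
#' @param s CV point (vector of length ncv)
#' @return named gradient vector, kcal/mol per CV unit
#' @export
bias_gradient <- function(bias, s) {
  m <- hills_matrices(bias)
  if (nrow(m$centers) == 0) return(setNames(rep(0, length(s)), bias$cv_names))
  g <- cpp_bias_gradient(m$centers, m$sigmas, m$heights, as.numeric(s),
                         m$periodic)
  setNames(g, bias$cv_names)
}

#' Height of the next well-tempered hill
#'
#' \eqn{h = h_0 \exp(-V(s)/k_B\Delta T)}: heights decay where the bias has
#' already accumulated, which is what makes the scheme convergent.
#'
#' @param bias a [bias_state()]
#' @param s_now current CV point
#' @param h0 initial hill height, kcal/mol (> 0)
#' @return height in kcal/mol (in (0, h0])
#' @export
next_hill_height <- function(bias, s_now, h0) {
  if (h0 <= 0) stop("parameter error: h0 must be > 0", call. = FALSE)
  h0 * exp(-bias_energy(bias, s_now) / bias$kB_deltaT)
}

#' Deposit one hill
#'
#' @param bias a [bias_state()]
#' @param s_now current CV point
#' @param t deposition time, ps (strictly after the last hill)
#' @param h0 initial hill height, kcal/mol
#' @param widths Gaussian widths per CV
#' @return the updated \code{bias_state}
#' @export
deposit_hill <- function(bias, s_now, t, h0, widths) {
  nh <- nrow(bias$hills)
  if (nh > 0 && t <= bias$hills$time[nh])
    stop("sequencing error: hill time must strictly increase", call. = FALSE)
  h <- next_hill_height(bias, s_now, h0)
  row <- as.data.frame(as.list(setNames(
    c(t, as.numeric(s_now), as.numeric(widths), h),
    names(bias$hills))))
  bias$hills <- rbind(bias$hills, row)
  bias
}

#' Metadynamics parameter set
#'
#' @param h0 initial hill height, kcal/mol (0 disables deposition, giving an
#'   unbiased run)
#' @param stride hill deposition stride, ps
#' @param widths Gaussian widths: (rho A, tau, theta rad) for 3D, a single
#'   rho width for 1D
#' @param gamma bias factor
#' @param periodic_theta treat theta as periodic in the hills (default TRUE:
#'   an azimuth about an axis is periodic by construction)
#' @param confine skip hill deposition while the walker is beyond a
#'   restraining wall (rho or tau), keeping the bias inside the localized
#'   volume so the walls retain their nominal stiffness (default TRUE;
#'   ignored for 1D systems)
#' @return a validated \code{metad_params} list
#' @export
metad_params <- function(h0 = 0.287, stride = 1,
                         widths = c(rho = 1, tau = 0.04, theta = pi / 8),
                         gamma = 20, periodic_theta = TRUE, confine = TRUE) {
  if (h0 < 0) stop("parameter error: h0 must be >= 0", call. = FALSE)
  if (stride <= 0) stop("parameter error: stride must be > 0", call. = FALSE)
  if (any(widths <= 0)) stop("parameter error: widths must be > 0", call. = FALSE)
  if (gamma <= 1) stop("parameter error: gamma must exceed 1", call. = FALSE)
  p <- list(h0 = h0, stride = stride, widths = widths, gamma = gamma,
            periodic_theta = periodic_theta, confine = isTRUE(confine))
  class(p) <- "metad_params"
  p
}

#' Run a localized-volume well-tempered metadynamics simulation
#'
#' The main loop advances BAOAB Langevin dynamics under the total force
#' \eqn{-\nabla U + F_{bias} + F_{wall}}, where the bias force is chained
#' through the CV gradients; every \code{stride} a hill is deposited at the
#' current CV point, and every output stride a frame (time, rho, tau, theta,
#' bias, d, N) is appended to the COLVAR table.  1D systems collapse the CVs
#' to rho alone and use no volume restraint (the quartic confines the
#' particle), which enables the analytic/quadrature cross-checks.
#'
#' @param system a \code{model_potential}: 1D (e.g. [make_double_well()]) or a
#'   3D [make_host_guest()] model
#' @param vol a [volume_spec()] (required for 3D systems, ignored for 1D)
#' @param metad a [metad_params()]
#' @param langevin a [langevin_params()]
#' @param observables list with \code{d_ref} (reference point of the d axis,
#'   defaults to the host COM), \code{d_scale} (0.1: Angstrom to nm) and
#'   optionally \code{contacts} (list with \code{sites}, an n x 3 matrix of
#'   H-bond partner positions, and \code{switching}, a [switching_params()]).
#'   For a \code{host_guest} system the polar sites are used by default.
#' @param x0,v0 initial position and velocity (defaults: 1D at the left
#'   minimum; 3D at the binding-region centre on the axis)
#' @param out_stride output stride in ps (default: the hill stride)
#' @return an \code{lvmetad_run}: list with \code{colvar} (ColvarTable
#'   data.frame), \code{hills} (data.frame), \code{trajectory} (data.frame of
#'   time, position, velocity, potential energy), \code{bias} (final
#'   [bias_state()]) and \code{meta} (seed, config hash)
#' @export
run_lv_metad <- function(system, vol = NULL, metad = metad_params(),
                         langevin, observables = NULL, x0 = NULL, v0 = NULL,
                         out_stride = NULL) {
  stopifnot(inherits(system, "model_potential"),
            inherits(metad, "metad_params"),
            inherits(langevin, "langevin_params"))
  dim <- system$dim
  ncv <- if (dim == 1) 1L else 3L
  dt <- langevin$timestep
  to_steps <- function(interval, what) {
    k <- round(interval / dt)
    if (k < 1 || abs(interval - k * dt) > 1e-9 * max(1, abs(interval)))
      stop(sprintf("parameter error: %s must be a positive integer multiple of the timestep",
                   what), call. = FALSE)
    as.integer(k)
  }
  stride_steps <- if (metad$h0 > 0) to_steps(metad$stride, "hill stride") else 0L
  if (is.null(out_stride)) out_stride <- metad$stride
  out_steps <- to_steps(out_stride, "output stride")

  host_com <- if (dim == 3) system$host_com else c(0, 0, 0)
  if (dim == 3 && is.null(vol))
    stop("parameter error: 3D systems require a volume spec", call. = FALSE)
  if (is.null(x0)) {
    x0 <- if (dim == 1) {
      if (!is.null(system$cpp$separation)) -system$cpp$separation / 2 else 0
    } else {
      mid <- mean(system$binding_region$rho)
      host_com + mid * system$axis
    }
  }
  if (is.null(v0)) v0 <- rep(0, dim)

  widths <- if (dim == 1) metad$widths[1] else metad$widths
  if (length(widths) != ncv)
    stop("parameter error: widths must match the number of CVs", call. = FALSE)
  periodic <- if (dim == 1) FALSE else c(FALSE, FALSE, metad$periodic_theta)

  obs <- list(d_scale = 0.1)
  if (!is.null(observables)) obs[names(observables)] <- observables
  if (is.null(obs$d_ref)) obs$d_ref <- host_com
  if (is.null(obs$contacts) && inherits(system, "host_guest")) {
    pol <- system$host_sites[system$host_sites$type == "polar", , drop = FALSE]
    obs$contacts <- list(sites = as.matrix(pol[, c("x", "y", "z")]),
                         switching = switching_params())
  }
  cobs <- list(d_ref = as.numeric(obs$d_ref), d_scale = obs$d_scale)
  if (!is.null(obs$contacts) && dim == 3) {
    cobs$contact_sites <- unname(as.matrix(obs$contacts$sites))
    cobs$switching <- unclass(obs$contacts$switching %||% switching_params())
  }

  lang <- list(timestep = dt, friction = langevin$friction,
               temperature = langevin$temperature, mass = langevin$mass,
               n_steps = langevin$n_steps, out_stride = out_steps,
               x0 = as.numeric(x0), v0 = as.numeric(v0))
  met <- list(h0 = metad$h0, stride_steps = stride_steps, gamma = metad$gamma,
              widths = as.numeric(widths), periodic = periodic,
              confine = isTRUE(metad$confine))

  cfg <- list(system = system$cpp, vol = if (is.null(vol)) NULL else unclass(vol),
              lang = lang, met = met, obs = cobs, seed = langevin$seed)
  set.seed(langevin$seed)
  res <- cpp_run_lv_metad(system$cpp,
                          if (is.null(vol)) NULL else unclass(vol),
                          host_com, lang, met, cobs)

  colvar <- as.data.frame(res$colvar)
  attr(colvar, "seed") <- langevin$seed
  attr(colvar, "config_hash") <- config_hash(cfg)
  class(colvar) <- c("colvar_table", "data.frame")

  cvn <- if (ncv == 1) "rho" else c("rho", "tau", "theta")
  hills <- as.data.frame(res$hills)
  names(hills) <- c("time", cvn, paste0("sigma_", cvn), "height")

  bias <- bias_state(metad$gamma, langevin$temperature, cv_names = cvn,
                     periodic = periodic)
  bias$hills <- hills

  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("time", paste0("x", seq_len(dim)), paste0("v", seq_len(dim)),
                   "epot")

  out <- list(colvar = colvar, hills = hills, trajectory = traj, bias = bias,
              meta = list(seed = langevin$seed, config_hash = attr(colvar, "config_hash"),
                          gamma = metad$gamma, temperature = langevin$temperature,
                          ncv = ncv))
  class(out) <- "lvmetad_run"
  out
}
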