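#' @title Model potentials and Langevin dynamics
#'
#' @description Toy energy surfaces (1D double well, 3D host-guest pocket)
#'   with analytic gradients, a BAOAB Langevin integrator, and a brute-force
#'   quadrature oracle for free-energy differences.  These stand in for the
#'   solvated all-atom system a production LV-MetaD run would sample.
#' @name toy_systems
NULL

as_pos_matrix <- function(x, dim) {
  if (is.matrix(x)) {
    if (ncol(x) != dim) stop(sprintf("expected %d columns, got %d", dim, ncol(x)),
                             call. = FALSE)
    return(x)
  }
  if (dim == 1) return(matrix(as.numeric(x), ncol = 1))
  if (length(x) %% dim != 0) stop("position length not a multiple of dimension",
                                  call. = FALSE)
  matrix(as.numeric(x), ncol = dim, byrow = TRUE)
}

new_model_potential <- function(name, dim, cpp, bounds) {
  pot <- list(
    name = name, dim = dim, cpp = cpp, bounds = bounds,
    energy = function(x) cpp_potential_energy(cpp, as_pos_matrix(x, dim)),
    gradient = function(x) cpp_potential_gradient(cpp, as.numeric(x))
  )
  class(pot) <- "model_potential"
  pot
}

#' Quartic 1D double-well potential
#'
#' \eqn{U(x) = B (z^2 - 1)^2 + (A/2)(z + 1)} with \eqn{z = 2x/s}: two minima
#' near \eqn{x = \pm s/2}, a barrier of height \code{barrier} at the origin and
#' the right minimum raised by \code{asymmetry} relative to the left.  For
#' \code{asymmetry > 0} the linear tilt also raises the realized barrier above
#' the lower minimum by about \code{asymmetry/2}; fixture truths are therefore
#' always taken from [reference_free_energy()], not from the nominal inputs.
#'
#' @param barrier barrier height in kcal/mol (must be > 0)
#' @param asymmetry energy offset of the right minimum, kcal/mol (>= 0 typical)
#' @param separation distance between the two minima in Angstrom (must be > 0)
#' @return a \code{model_potential} (1D) with fields \code{energy},
#'   \code{gradient} and \code{bounds}
#' @examples
#' dw <- make_double_well(barrier = 3, asymmetry = 0, separation = 4)
#' dw$energy(c(-2, 0, 2))  # 0, 3, 0
#' @export
make_double_well <- function(barrier, asymmetry = 0, separation = 4) {
  if (!is.numeric(barrier) || length(barrier) != 1 || !is.finite(barrier) ||
      barrier <= 0)
    stop("parameter error: barrier must be a positive number", call. = FALSE)
  if (!is.numeric(separation) || length(separation) != 1 ||
      !is.finite(separation) || separation <= 0)
    stop("parameter error: separation must be a positive number", call. = FALSE)
  if (!is.numeric(asymmetry) || length(asymmetry) != 1 || !is.finite(asymmetry))
    stop("parameter error: asymmetry must be a finite number", call. = FALSE)
  cpp <- list(tag = "double_well", dim = 1L, barrier = barrier,
              separation = separation, asymmetry = asymmetry)
  new_model_potential("double_well", 1L, cpp,
                      bounds = matrix(c(-separation, separation), nrow = 2))
}

#' Harmonic test potential
#'
#' @param k_spring spring constant, kcal/mol/A^2
#' @param x0 minimum position (length = \code{dim})
#' @param dim dimensionality (1 or 3)
#' @return a \code{model_potential}
#' @export
make_harmonic <- function(k_spring, x0 = 0, dim = 1L) {
  stopifnot(k_spring > 0, dim %in% c(1L, 3L), length(x0) == dim)
  cpp <- list(tag = "harmonic", dim = as.integer(dim), k_spring = k_spring,
              x0 = as.numeric(x0))
  span <- 6 * sqrt(1 / k_spring)
  new_model_potential("harmonic", as.integer(dim), cpp,
                      bounds = rbind(x0 - span, x0 + span))
}

#' Flat test potential
#'
#' @param bounds 2 x dim matrix of box bounds (rows: lo, hi)
#' @param dim dimensionality
#' @return a \code{model_potential} with identically zero energy
#' @export
make_flat <- function(bounds, dim = 1L) {
  cpp <- list(tag = "flat", dim = as.integer(dim))
  new_model_potential("flat", as.integer(dim), cpp, bounds = bounds)
}

#' Default host-guest configuration
#'
#' A shallow surface pocket: one deep apolar site flanked by two polar sites
#' that act as hydrogen-bond partners for the guest, all placed near the apex
#' of the parabolic restraint volume on the +x ("protein-ligand") axis.  Well
#' depths and ranges are the package's frozen fixture choices (see the
#' methods vignette).
#'
#' @param com reference point for the host centre of mass (the rho reference
#'   group), Angstrom
#' @return a config list for [make_host_guest()]
#' @export
host_guest_config <- function(com = c(0, 0, 0)) {
  list(
    sites = data.frame(
      x     = c(2.5,  2.0,  2.8),
      y     = c(0.0,  1.2, -1.0),
      z     = c(0.0,  0.5,  0.8),
      type  = c("apolar", "polar", "polar"),
      depth = c(3.0,  1.0,  1.0),    # kcal/mol
      range = c(1.6,  1.2,  1.2),    # A
      stringsAsFactors = FALSE
    ),
    guest_mass = 50,                  # amu
    axis = c(1, 0, 0),
    com = com,
    binding_region = list(rho = c(0, 4)),     # bound pocket, A
    solvated_region = list(rho = c(7, 8.5)),  # flat outer shell, A
    bounds = rbind(lo = c(0, -7, -7), hi = c(10, 7, 7))
  )
}

#' Build a 3D host-guest model
#'
#' The composite potential is a sum of isotropic Gaussian wells, one per host
#' site: \eqn{U(r) = -\sum_i \epsilon_i \exp(-|r - r_i|^2 / 2 w_i^2)}.  The
#' host is rigid; the energy is asymptotically flat far from the sites, which
#' defines the "solvated" outer shell.
#'
#' @param config a list as returned by [host_guest_config()]
#' @return a \code{host_guest} model (also a \code{model_potential}, dim 3)
#'   with fields \code{host_sites}, \code{guest_mass}, \code{axis},
#'   \code{host_com}, \code{binding_region}, \code{solvated_region},
#'   \code{bounds}
#' @examples
#' hg <- make_host_guest()
#' hg$energy(c(2.5, 0, 0))   # deep inside the pocket
#' @export
make_host_guest <- function(config = host_guest_config()) {
  s <- config$sites
  need <- c("x", "y", "z", "type", "depth", "range")
  if (!all(need %in% names(s)))
    stop("config error: sites must have columns x, y, z, type, depth, range",
         call. = FALSE)
  if (!any(s$type == "polar"))
    stop("config error: at least one polar site is required (H-bond counting)",
         call. = FALSE)
  if (is.null(config$binding_region) || is.null(config$solvated_region))
    stop("config error: binding_region and solvated_region must be named",
         call. = FALSE)
  b <- config$bounds
  pos <- as.matrix(s[, c("x", "y", "z")])
  inside <- pos[, 1] >= b[1, 1] & pos[, 1] <= b[2, 1] &
            pos[, 2] >= b[1, 2] & pos[, 2] <= b[2, 2] &
            pos[, 3] >= b[1, 3] & pos[, 3] <= b[2, 3]
  if (!all(inside))
    stop("config error: host sites outside the declared bounds", call. = FALSE)
  cpp <- list(tag = "host_guest", dim = 3L,
              sites = cbind(pos, depth = s$depth, range = s$range))
  pot <- new_model_potential("host_guest", 3L, cpp, bounds = b)
  pot$host_sites <- s
  pot$guest_mass <- config$guest_mass
  pot$axis <- config$axis / sqrt(sum(config$axis^2))
  pot$host_com <- as.numeric(config$com)
  pot$binding_region <- config$binding_region
  pot$solvated_region <- config$solvated_region
  class(pot) <- c("host_guest", "model_potential")
  pot
}

#' Add the localized-volume restraint walls to a potential
#'
#' Returns a new \code{model_potential} whose energy is the original energy
#' plus the half-harmonic walls of the parabolic-solid volume (on rho, tau and
#' the axial coordinate).  This is the potential the biased simulation
#' actually samples, and the one the quadrature oracle must integrate when
#' comparing against simulated binding free energies.
#'
#' @param potential a 3D \code{model_potential}
#' @param vol a [volume_spec()]
#' @param host_com rho reference point (defaults to the model's
#'   \code{host_com})
#' @return a \code{model_potential} with walls included
#' @export
restrain_potential <- function(potential, vol, host_com = potential$host_com) {
  stopifnot(inherits(potential, "model_potential"), potential$dim == 3L)
  cpp <- potential$cpp
  vl <- unclass(vol)
  pot <- list(
    name = paste0(potential$name, "+walls"), dim = 3L, cpp = cpp,
    bounds = potential$bounds,
    energy = function(x) {
      X <- as_pos_matrix(x, 3L)
      cpp_potential_energy(cpp, X) + cpp_restraint_energy(X, host_com, vl)
    },
    gradient = function(x) {
      cpp_potential_gradient(cpp, as.numeric(x)) -
        cpp_restraint_force(as.numeric(x), host_com, vl)
    }
  )
  class(pot) <- "model_potential"
  pot
}

#' Langevin parameter set
#'
#' @param timestep integration step, ps
#' @param friction friction coefficient, 1/ps
#' @param temperature Kelvin
#' @param mass particle mass, amu
#' @param seed RNG seed (integer); identical seeds give bit-identical runs
#' @param n_steps number of steps
#' @return a validated \code{langevin_params} list
#' @export
langevin_params <- function(timestep, friction, temperature, mass,
                            seed = 1L, n_steps = 1000L) {
  if (!is.numeric(timestep) || timestep <= 0)
    stop("parameter error: timestep must be > 0", call. = FALSE)
  if (!is.numeric(friction) || friction <= 0)
    stop("parameter error: friction must be > 0", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("parameter error: temperature must be > 0", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0)
    stop("parameter error: mass must be > 0", call. = FALSE)
  p <- list(timestep = timestep, friction = friction,
            temperature = temperature, mass = mass,
            seed = as.integer(seed), n_steps = as.integer(n_steps))
  class(p) <- "langevin_params"
  p
}

#' One BAOAB step of underdamped Langevin dynamics
#'
#' Splitting scheme B-A-O-A-B with exact Ornstein-Uhlenbeck treatment of the
#' friction (O step): \deqn{v \leftarrow c_1 v + \sqrt{1 - c_1^2}\,
#' \sqrt{k_B T/m}\; \xi, \quad c_1 = e^{-\gamma\,\Delta t}.}
#' Forces are in kcal/mol/A and converted to accelerations with
#' 1 kcal/mol = 418.4 amu A^2/ps^2.  The Gaussian draws come from R's RNG, so
#' \code{set.seed()} makes trajectories bit-reproducible.
#'
#' @param state list with \code{position}, \code{velocity} and optionally a
#'   cached \code{force} and a \code{step} counter
#' @param potential a \code{model_potential}
#' @param external_force optional \code{function(x)} returning a force vector
#'   (kcal/mol/A) added to \eqn{-\nabla U}; the hook for bias and wall forces
#' @param params a [langevin_params()]
#' @return the advanced state (with cached \code{force} and incremented
#'   \code{step})
#' @export
langevin_step <- function(state, potential, external_force = NULL, params) {
  dim <- potential$dim
  x <- as.numeric(state$position)
  v <- as.numeric(state$velocity)
  step <- if (is.null(state$step)) 0L else state$step
  akma <- 418.4
  total_force <- function(x) {
    f <- -potential$gradient(x)
    if (!is.null(external_force)) f <- f + external_force(x)
    if (any(!is.finite(f)))
      stop(sprintf("integration error: non-finite force at step %d", step + 1L),
           call. = FALSE)
    f
  }
  f <- if (is.null(state$force)) total_force(x) else as.numeric(state$force)
  dt <- params$timestep
  c1 <- exp(-params$friction * dt)
  c2 <- sqrt(max(0, 1 - c1^2))
  sigv <- sqrt(akma * kB_KCAL * params$temperature / params$mass)
  facc <- akma / params$mass
  v <- v + 0.5 * dt * f * facc
  x <- x + 0.5 * dt * v
  v <- c1 * v + c2 * sigv * rnorm(dim)
  x <- x + 0.5 * dt * v
  f <- total_force(x)
  v <- v + 0.5 * dt * f * facc
  list(position = x, velocity = v, force = f, step = step + 1L)
}

region_mask <- function(region, pts) {
  lo <- region$lo; hi <- region$hi
  m <- rep(TRUE, nrow(pts))
  for (j in seq_len(ncol(pts))) m <- m & pts[, j] >= lo[j] & pts[, j] <= hi[j]
  if (!is.null(region$predicate)) m <- m & region$predicate(pts)
  m
}

region_grid <- function(region, spacing) {
  lo <- region$lo; hi <- region$hi
  axes <- lapply(seq_along(lo), function(j) {
    n <- max(2L, ceiling((hi[j] - lo[j]) / spacing))
    lo[j] + (seq_len(n) - 0.5) * (hi[j] - lo[j]) / n
  })
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  cellvol <- prod(vapply(axes, function(a) a[2] - a[1], 1.0))
  list(pts = pts, cellvol = cellvol)
}

#' Brute-force free-energy difference between two regions
#'
#' Deterministic midpoint-rule quadrature of the configurational integrals:
#' \deqn{\Delta F = -k_B T \ln \frac{\int_a e^{-\beta U}}{\int_b e^{-\beta U}}.}
#' Serves as the independent oracle for everything the sampler and the
#' reweighting machinery estimate.  A region is a list with \code{lo},
#' \code{hi} (box bounds per dimension) and an optional \code{predicate}
#' (function of a position matrix returning a logical mask).
#'
#' @param potential a \code{model_potential} (walls included if the comparison
#'   is against a restrained simulation; see [restrain_potential()])
#' @param region_a,region_b region descriptors (must not overlap)
#' @param temperature Kelvin
#' @param spacing grid spacing in Angstrom (default: 1/400 of the widest box
#'   side in 1D, 0.1 A in 3D)
#' @return \eqn{\Delta F} in kcal/mol (= F_a - F_b), with attribute
#'   \code{"error"} holding a Richardson estimate of the discretization error
#'   (recomputation at double spacing)
#' @export
reference_free_energy <- function(potential, region_a, region_b, temperature,
                                  spacing = NULL) {
  dim <- potential$dim
  if (is.null(spacing))
    spacing <- if (dim == 1) max(region_a$hi - region_a$lo,
                                 region_b$hi - region_b$lo) / 400 else 0.1
  # overlap check on the coarse common grid
  ilo <- pmax(region_a$lo, region_b$lo)
  ihi <- pmin(region_a$hi, region_b$hi)
  if (all(ihi > ilo)) {
    g <- region_grid(list(lo = ilo, hi = ihi), spacing * 2)
    both <- region_mask(region_a, g$pts) & region_mask(region_b, g$pts)
    if (any(both))
      stop("region error: regions a and b overlap", call. = FALSE)
  }
  beta <- 1 / kT(temperature)
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  logz <- function(region, h) {
    g <- region_grid(region, h)
    keep <- region_mask(region, g$pts)
    if (!any(keep)) stop("region error: empty region after masking", call. = FALSE)
    u <- potential$energy(g$pts[keep, , drop = FALSE])
    lse(-beta * u) + log(g$cellvol)
  }
  val <- function(h) -kT(temperature) * (logz(region_a, h) - logz(region_b, h))
  f1 <- val(spacing)
  f2 <- val(spacing * 2)
  structure(f1, error = abs(f1 - f2) / 3)
}
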