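#' @title Parabolic-solid collective variables
#'
#' @description The localized restraint volume is a solid of revolution about
#'   the host-ligand axis: the surface satisfies
#'   \eqn{r_\perp^2 = k (a - a_0)} with \eqn{a} the axial coordinate measured
#'   from the volume origin.  The three collective variables of the method
#'   are: \eqn{\rho}, the guest-host centre-of-mass distance; \eqn{\tau =
#'   r_\perp / \sqrt{k (a - a_0)}}, the dimensionless transverse coordinate
#'   (\eqn{\tau = 1} on the paraboloid surface); and \eqn{\theta}, the azimuth
#'   of the transverse projection about the axis, measured in the plane
#'   perpendicular to the axis from a fixed reference direction (the
#'   projection of +y, or of +z when the axis is nearly parallel to y).
#'   The functional form of \eqn{\tau} is this package's documented
#'   interpretation of the parabolic-solid coordinate: it is dimensionless,
#'   equals 1 on the volume boundary, and has O(0.1) fluctuations consistent
#'   with the customary Gaussian width of 0.04 used on \eqn{\tau}.
#' @name cv_geometry
NULL

#' Parabolic-solid volume specification
#'
#' @param origin paraboloid apex reference point, Angstrom
#' @param axis volume axis (normalized internally); the host-ligand axis
#' @param k paraboloid steepness, Angstrom: the surface is
#'   \eqn{r_\perp^2 = k (a - a_0)}
#' @param a0 apex offset along the axis, Angstrom
#' @param rho_max upper wall position on rho, Angstrom
#' @param tau_max upper wall position on tau (dimensionless, 1 = the surface)
#' @param wall_k wall stiffness, kcal/mol per squared CV unit
#' @param a_min axial lower wall (keeps the guest strictly above the apex
#'   offset so tau stays defined); defaults to \code{a0 + 0.5}
#' @return a \code{volume_spec}
#' @examples
#' vol <- volume_spec(k = 2.5, a0 = -1, rho_max = 9, tau_max = 1.2, wall_k = 20)
#' @export
volume_spec <- function(origin = c(0, 0, 0), axis = c(1, 0, 0), k, a0,
                        rho_max, tau_max, wall_k, a_min = a0 + 0.5) {
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm <= 0)
    stop("parameter error: axis must be a nonzero vector", call. = FALSE)
  if (k <= 0 || rho_max <= 0 || tau_max <= 0 || wall_k <= 0)
    stop("parameter error: k, rho_max, tau_max and wall_k must be > 0",
         call. = FALSE)
  if (a_min <= a0)
    stop("parameter error: a_min must exceed a0", call. = FALSE)
  v <- list(origin = as.numeric(origin), axis = as.numeric(axis) / nrm,
            k = k, a0 = a0, rho_max = rho_max, tau_max = tau_max,
            wall_k = wall_k, a_min = a_min)
  class(v) <- "volume_spec"
  v
}

# Orthonormal frame (axis, e1, e2) matching the C++ convention.
vol_frame <- function(vol) {
  u <- vol$axis
  ref <- if (abs(u[2]) > 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Compute the (rho, tau, theta) collective variables
#'
#' @param guest_com guest centre of mass, Angstrom (length 3, or an n x 3
#'   matrix for vectorized evaluation)
#' @param host_com rho reference point, Angstrom.  The reference group is
#'   configurable because the distance axis of the final free-energy map may
#'   use a sub-group (e.g. a cluster site) rather than the whole-host COM.
#' @param vol a [volume_spec()]
#' @return for a single point, a \code{cv_triple} list (rho, tau, theta); for
#'   a matrix, an n x 3 matrix
#' @examples
#' vol <- volume_spec(k = 2.5, a0 = -1, rho_max = 9, tau_max = 1.2, wall_k = 20)
#' compute_cvs(c(3, 0, 0), c(0, 0, 0), vol)  # on-axis: tau = 0, theta = 0
#' @export
compute_cvs <- function(guest_com, host_com, vol) {
  X <- as_pos_matrix(guest_com, 3L)
  cv <- cpp_cvs_matrix(X, as.numeric(host_com), unclass(vol))
  if (any(!is.finite(cv[, "tau"])))
    stop("degenerate-geometry error: axial coordinate at or below a0 (wall misconfigured?)",
         call. = FALSE)
  if (is.matrix(guest_com) && nrow(guest_com) > 1) return(cv)
  out <- list(rho = as.numeric(cv[1, 1]), tau = as.numeric(cv[1, 2]),
              theta = as.numeric(cv[1, 3]))
  class(out) <- "cv_triple"
  out
}

#' Invert (rho, tau, theta) back to a Cartesian point
#'
#' The (tau, theta) pair fixes a ray leaving the apex region; the point is the
#' intersection of that ray with the sphere \eqn{|r - \mathrm{host}| = \rho}.
#' The intersection is found by root bracketing on the axial coordinate over
#' \code{(a0 + eps, a_hi]}; the distance along the ray grows monotonically
#' with the axial coordinate for the supported geometries (host reference on
#' or behind the apex), so the root is unique.
#'
#' @param cvs a \code{cv_triple} or a list/vector with rho, tau, theta
#' @param host_com rho reference point
#' @param vol a [volume_spec()]
#' @param a_hi upper bracket for the axial coordinate (default
#'   \code{vol$rho_max + 5})
#' @return a length-3 Cartesian position, Angstrom
#' @export
invert_cvs <- function(cvs, host_com, vol, a_hi = vol$rho_max + 5) {
  rho <- cvs$rho %||% cvs[[1]]
  tau <- cvs$tau %||% cvs[[2]]
  theta <- cvs$theta %||% cvs[[3]]
  if (tau < 0 || tau > vol$tau_max)
    stop("geometry error: tau outside [0, tau_max]", call. = FALSE)
  if (rho < 0 || rho > vol$rho_max)
    stop("geometry error: rho outside [0, rho_max]", call. = FALSE)
  fr <- vol_frame(vol)
  tdir <- cos(theta) * fr$e1 + sin(theta) * fr$e2
  point_at <- function(a) {
    rp <- tau * sqrt(vol$k * (a - vol$a0))
    vol$origin + a * fr$u + rp * tdir
  }
  dist_at <- function(a) sqrt(sum((point_at(a) - host_com)^2)) - rho
  lo <- vol$a0 + 1e-7
  if (dist_at(lo) > 0 || dist_at(a_hi) < 0)
    stop("geometry error: no intersection with the (tau, theta) ray inside bounds",
         call. = FALSE)
  a <- stats::uniroot(dist_at, c(lo, a_hi), tol = 1e-13)$root
  point_at(a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic gradients of the collective variables
#'
#' Returns \eqn{\partial\rho/\partial r}, \eqn{\partial\tau/\partial r} and
#' \eqn{\partial\theta/\partial r} as rows of a 3 x 3 matrix.  On the axis the
#' azimuth is degenerate: \eqn{\partial\theta/\partial r} is regularised by
#' flooring the transverse distance at 0.01 A (capping the gradient magnitude
#' at 100 / A) and set to zero exactly on the axis; the transverse direction
#' entering \eqn{\partial\tau/\partial r} falls back to the theta reference
#' direction there.
#'
#' @inheritParams compute_cvs
#' @return 3 x 3 numeric matrix with rows rho, tau, theta
#' @export
cv_gradients <- function(guest_com, host_com, vol) {
  res <- cpp_cv_gradients(as.numeric(guest_com), as.numeric(host_com),
                          unclass(vol))
  res$gradients
}

#' Restraining wall energy of the localized volume
#'
#' Half-harmonic walls: \eqn{k_w (\rho - \rho_{max})^2} for
#' \eqn{\rho > \rho_{max}} and \eqn{k_w (\tau - \tau_{max})^2} for
#' \eqn{\tau > \tau_{max}}; zero inside.  Theta is periodic and unbounded.
#' (The axial lower wall at \code{a_min} acts on the Cartesian coordinate and
#' is handled by the run loop and [restrain_potential()], not here.)
#'
#' @param cvs a \code{cv_triple} (or list with rho, tau)
#' @param vol a [volume_spec()]
#' @return energy in kcal/mol
#' @export
wall_energy <- function(cvs, vol) {
  rho <- cvs$rho %||% cvs[[1]]
  tau <- cvs$tau %||% cvs[[2]]
  e <- 0
  if (rho > vol$rho_max) e <- e + vol$wall_k * (rho - vol$rho_max)^2
  if (tau > vol$tau_max) e <- e + vol$wall_k * (tau - vol$tau_max)^2
  e
}

#' Gradient of the wall energy with respect to the CVs
#'
#' @inheritParams wall_energy
#' @return named vector d(wall)/d(rho, tau, theta), kcal/mol per CV unit
#' @export
wall_gradient_cv <- function(cvs, vol) {
  rho <- cvs$rho %||% cvs[[1]]
  tau <- cvs$tau %||% cvs[[2]]
  g <- c(rho = 0, tau = 0, theta = 0)
  if (rho > vol$rho_max) g["rho"] <- 2 * vol$wall_k * (rho - vol$rho_max)
  if (tau > vol$tau_max) g["tau"] <- 2 * vol$wall_k * (tau - vol$tau_max)
  g
}
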