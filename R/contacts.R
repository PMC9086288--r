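#' @title Contact counting via the rational switching function
#'
#' @description The number of hydrogen bonds / salt bridges N between the
#'   guest and the host sites inside the volume is a smooth sum of per-pair
#'   occupancies \eqn{s_{ij}} given by the rational switching function
#'   \deqn{s_{ij} = \frac{1 - ((r_{ij} - d_0)/r_0)^n}{1 - ((r_{ij} - d_0)/r_0)^m}}
#'   with the standard parameters n = 8, m = 12, d0 = 0, r0 = 2.5 A.
#' @name contacts
NULL

#' Switching-function parameters
#'
#' @param n numerator exponent (integer, 0 < n < m)
#' @param m denominator exponent
#' @param d0 distance offset, Angstrom (>= 0)
#' @param r0 switching radius, Angstrom (> 0)
#' @return a validated \code{switching_params} list
#' @export
switching_params <- function(n = 8, m = 12, d0 = 0, r0 = 2.5) {
  if (!(m > n && n > 0)) stop("parameter error: need m > n > 0", call. = FALSE)
  if (r0 <= 0) stop("parameter error: r0 must be > 0", call. = FALSE)
  if (d0 < 0) stop("parameter error: d0 must be >= 0", call. = FALSE)
  p <- list(n = n, m = m, d0 = d0, r0 = r0)
  class(p) <- "switching_params"
  p
}

#' Rational switching function
#'
#' Maps a distance to a contact occupancy in [0, 1].  The printed formula is
#' 0/0 at \eqn{x = (r - d_0)/r_0 = 1}; there the analytic (L'Hopital) limit
#' \eqn{n/m} is returned, and the function is smooth across the point.
#' Distances below \eqn{d_0} are clamped to full occupancy (s = 1).
#'
#' @param r distance(s), Angstrom (>= 0); vectorized
#' @param params a [switching_params()]
#' @return occupancy value(s) in [0, 1]
#' @examples
#' switch_rational(c(0, 2.5, 5))  # 1, 2/3, 255/4095
#' @export
switch_rational <- function(r, params = switching_params()) {
  stopifnot(all(r >= 0))
  x <- pmax((r - params$d0) / params$r0, 0)
  xn <- x^params$n
  xm <- x^params$m
  s <- ifelse(abs(1 - xm) < 1e-12, params$n / params$m, (1 - xn) / (1 - xm))
  as.numeric(s)
}

#' Contact set: donor-acceptor pair list plus switching parameters
#'
#' The pairs defining N are configuration input: for toy systems they are the
#' guest against the polar host sites; for real structures they must be
#' supplied explicitly.
#'
#' @param pairs data.frame with columns \code{guest} and \code{host} (site
#'   ids resolving to coordinates in every frame); duplicates rejected
#' @param params a [switching_params()]
#' @return a \code{contact_set}
#' @export
contact_set <- function(pairs, params = switching_params()) {
  stopifnot(is.data.frame(pairs), all(c("guest", "host") %in% names(pairs)))
  key <- paste(pairs$guest, pairs$host)
  if (anyDuplicated(key))
    stop("parameter error: duplicate pairs in contact set", call. = FALSE)
  cs <- list(pairs = pairs, params = params)
  class(cs) <- "contact_set"
  cs
}

pair_distances <- function(frame, contacts) {
  get_site <- function(id, pair_idx) {
    pos <- frame[[id]]
    if (is.null(pos))
      stop(sprintf("lookup error: site '%s' missing in frame (pair %d)",
                   id, pair_idx), call. = FALSE)
    as.numeric(pos)
  }
  vapply(seq_len(nrow(contacts$pairs)), function(i) {
    g <- get_site(contacts$pairs$guest[i], i)
    h <- get_site(contacts$pairs$host[i], i)
    sqrt(sum((g - h)^2))
  }, 1.0)
}

#' Hydrogen-bond count N of one frame
#'
#' \eqn{N = \sum_{pairs} s(r_{ij})}; bounded by the number of pairs.
#'
#' @param frame named list of site coordinates (each a length-3 vector)
#' @param contacts a [contact_set()]
#' @return N (dimensionless, in [0, n_pairs])
#' @export
hbond_count <- function(frame, contacts) {
  sum(switch_rational(pair_distances(frame, contacts), contacts$params))
}

#' Leader clustering of contact fingerprints into poses
#'
#' Each frame is fingerprinted by its vector of per-pair occupancies
#' \eqn{(s_{ij})}; frames are scanned in order and join the first existing
#' cluster whose leader fingerprint is within \code{cutoff} (Euclidean
#' distance), otherwise they found a new cluster.  Deterministic given the
#' frame order.
#'
#' @param frames list of frames (named lists of site coordinates)
#' @param contacts a [contact_set()]
#' @param cutoff fingerprint distance threshold (> 0)
#' @return list with \code{labels} (integer per frame), \code{sizes},
#'   \code{medoids} (index of the frame minimising the total intra-cluster
#'   distance) and the \code{fingerprints} matrix
#' @export
cluster_poses <- function(frames, contacts, cutoff) {
  if (length(frames) == 0) stop("input error: no frames", call. = FALSE)
  if (cutoff <= 0) stop("parameter error: cutoff must be > 0", call. = FALSE)
  fp <- t(vapply(frames, function(fr)
    switch_rational(pair_distances(fr, contacts), contacts$params),
    numeric(nrow(contacts$pairs))))
  leaders <- integer(0)
  labels <- integer(length(frames))
  for (i in seq_along(frames)) {
    assigned <- FALSE
    for (li in seq_along(leaders)) {
      if (sqrt(sum((fp[i, ] - fp[leaders[li], ])^2)) <= cutoff) {
        labels[i] <- li
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      leaders <- c(leaders, i)
      labels[i] <- length(leaders)
    }
  }
  medoids <- vapply(seq_along(leaders), function(li) {
    idx <- which(labels == li)
    if (length(idx) == 1) return(idx)
    sub <- fp[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(sub))
    idx[which.min(rowSums(d2))]
  }, 1L)
  list(labels = labels, sizes = tabulate(labels, nbins = length(leaders)),
       medoids = medoids, fingerprints = fp)
}
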