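#' @title Reweighting, free-energy projection, block errors and basins
#'
#' @description The biased trajectory is turned into equilibrium expectations
#'   with the time-dependent bias-offset estimator
#'   \deqn{c(t) = \frac{1}{\beta}\ln
#'     \frac{\sum_s e^{\beta\gamma V(s,t)/(\gamma-1)}}
#'          {\sum_s e^{\beta V(s,t)/(\gamma-1)}},}
#'   giving frame weights \eqn{w_i \propto e^{\beta(V(s_i,t_i) - c(t_i))}}.
#'   The free energy is then projected onto a (d, N) grid, its cell errors
#'   estimated by contiguous-block averaging, basins detected by watershed
#'   descent, and the bound/unbound free-energy difference read off the
#'   weights.
#' @name reweight_fes
NULL

#' Tiwary-Parrinello bias offset c(t)
#'
#' V(s, t) includes hills with deposition time <= t, matching the run loop's
#' convention that a frame written at a hill time already feels that hill.
#' The sums run over a uniform grid of CV-space points (cell volumes cancel);
#' the grid must resolve the hill widths (at least 4 cells per smallest
#' sigma in every dimension).  Numerically stabilised by max subtraction.
#'
#' @param bias a [bias_state()] holding the hills (e.g. from [run_lv_metad()]
#'   or [read_hills()])
#' @param grid list of per-CV uniform cell-centre vectors (one per CV, in the
#'   order of \code{bias$cv_names}), or an already-expanded points matrix
#' @param eval_times sorted times (ps) at which to evaluate c(t)
#' @param beta inverse temperature 1/(kcal/mol); default from the bias state
#' @return data.frame with columns \code{time} and \code{ct} (kcal/mol)
#' @export
compute_ct <- function(bias, grid, eval_times,
                       beta = 1 / kT(bias$temperature)) {
  m <- hills_matrices(bias)
  if (is.list(grid) && !is.matrix(grid)) {
    spac <- vapply(grid, function(g) if (length(g) > 1) g[2] - g[1] else Inf, 1.0)
    if (nrow(m$sigmas) > 0) {
      minsig <- apply(m$sigmas, 2, min)
      if (any(spac > minsig / 4 + 1e-12))
        stop("resolution error: grid must have >= 4 cells per hill sigma in every dimension",
             call. = FALSE)
    }
    grid <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
    dimnames(grid) <- NULL
  }
  ct <- cpp_compute_ct(m$centers, m$sigmas, m$heights, m$times, grid,
                       m$periodic, bias$gamma, beta, as.numeric(eval_times))
  data.frame(time = as.numeric(eval_times), ct = ct)
}

#' Frame weights from the recorded bias and c(t)
#'
#' \eqn{w_i \propto \exp(\beta (V_i - c(t_i)))}, normalised to sum to 1 over
#' frames with \eqn{t \ge t_{start}}; earlier frames get weight 0.  c(t) is
#' matched to frames by nearest-preceding interpolation.
#'
#' @param colvar a ColvarTable data.frame with columns \code{time} and
#'   \code{bias}
#' @param ct data.frame from [compute_ct()]
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param t_start start of the reweighting window, ps.  The production
#'   default mirrors reweighting the final 100 ns of a 650 ns run, i.e. the
#'   last 2/13 of the trajectory.
#' @return numeric weight per frame (sums to 1 over the window)
#' @export
frame_weights <- function(colvar, ct, beta,
                          t_start = max(colvar$time) * (1 - 2 / 13)) {
  if (!all(c("time", "bias") %in% names(colvar)))
    stop("schema error: colvar must have 'time' and 'bias' columns", call. = FALSE)
  w <- numeric(nrow(colvar))
  sel <- colvar$time >= t_start
  if (!any(sel)) stop("empty-selection error: no frames at or after t_start",
                      call. = FALSE)
  idx <- findInterval(colvar$time[sel], ct$time)
  if (any(idx == 0))
    stop("schema error: frames in the window precede the first c(t) value",
         call. = FALSE)
  arg <- beta * (colvar$bias[sel] - ct$ct[idx])
  arg <- arg - max(arg)
  ww <- exp(arg)
  w[sel] <- ww / sum(ww)
  w
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

cell_weights <- function(colvar, weights, x_col, y_col, x_edges, y_edges) {
  ix <- bin_index(colvar[[x_col]], x_edges)
  iy <- bin_index(colvar[[y_col]], y_edges)
  keep <- !is.na(ix) & !is.na(iy) & weights > 0
  W <- matrix(0, length(x_edges) - 1, length(y_edges) - 1)
  if (any(keep)) {
    tw <- tapply(weights[keep], list(ix[keep], iy[keep]), sum)
    W[cbind(as.integer(rownames(tw)[row(tw)]),
            as.integer(colnames(tw)[col(tw)]))] <-
      ifelse(is.na(tw), 0, tw)
  }
  W
}

#' Project the reweighted free energy onto a 2D grid
#'
#' \eqn{F(\mathrm{cell}) = -k_B T \ln \sum_{i \in \mathrm{cell}} w_i},
#' shifted so the sampled minimum is 0.  Unsampled cells are NA and flagged
#' in the \code{sampled} mask, never zero.
#'
#' @param colvar ColvarTable data.frame
#' @param weights frame weights from [frame_weights()]
#' @param x_col,y_col column names to project onto (defaults \code{"d"} nm
#'   and \code{"nhb"})
#' @param x_edges,y_edges strictly increasing bin edges
#' @param kT thermal energy, kcal/mol
#' @param n_blocks if not NULL, also fill the \code{err} grid via
#'   [block_error()]
#' @return an \code{fes2d}: list with \code{x_edges}, \code{y_edges},
#'   \code{F}, \code{err}, \code{W} (cell weight mass), \code{n_eff},
#'   \code{sampled}, \code{kT}, \code{x_col}, \code{y_col}
#' @export
project_fes <- function(colvar, weights, x_col = "d", y_col = "nhb",
                        x_edges, y_edges, kT, n_blocks = NULL) {
  for (cn in c(x_col, y_col))
    if (!cn %in% names(colvar))
      stop(sprintf("schema error: column '%s' not in colvar", cn), call. = FALSE)
  if (any(diff(x_edges) <= 0) || any(diff(y_edges) <= 0))
    stop("parameter error: edges must be strictly increasing", call. = FALSE)
  if (all(weights == 0))
    stop("empty-selection error: all weights are zero", call. = FALSE)
  W <- cell_weights(colvar, weights, x_col, y_col, x_edges, y_edges)
  sampled <- W > 0
  F <- matrix(NA_real_, nrow(W), ncol(W))
  F[sampled] <- -kT * log(W[sampled])
  F <- F - min(F[sampled])
  # effective sample size per cell: (sum w)^2 / sum w^2
  ix <- bin_index(colvar[[x_col]], x_edges)
  iy <- bin_index(colvar[[y_col]], y_edges)
  keep <- !is.na(ix) & !is.na(iy) & weights > 0
  n_eff <- matrix(0, nrow(W), ncol(W))
  if (any(keep)) {
    w2 <- tapply(weights[keep]^2, list(ix[keep], iy[keep]), sum)
    idx <- cbind(as.integer(rownames(w2)[row(w2)]), as.integer(colnames(w2)[col(w2)]))
    vals <- ifelse(is.na(w2), 0, w2)
    n_eff[idx] <- vals
    n_eff[sampled] <- W[sampled]^2 / pmax(n_eff[sampled], .Machine$double.xmin)
  }
  fes <- list(x_edges = x_edges, y_edges = y_edges, F = F,
              err = matrix(NA_real_, nrow(W), ncol(W)), W = W, n_eff = n_eff,
              sampled = sampled, kT = kT, x_col = x_col, y_col = y_col)
  class(fes) <- "fes2d"
  if (!is.null(n_blocks))
    fes$err <- block_error(colvar, weights, x_col, y_col, x_edges, y_edges,
                           n_blocks = n_blocks, kT = kT)
  fes
}

block_split <- function(idx, n_blocks) {
  # contiguous-in-time blocks with (near-)equal frame counts
  split(idx, ceiling(seq_along(idx) / (length(idx) / n_blocks)))
}

#' Block-average errors of the projected free energy
#'
#' The reweighting window is split into \code{n_blocks} contiguous time
#' blocks; each block's weights are renormalised within the block and turned
#' into a per-block free energy \eqn{F_b}.  The cell error is the
#' block-mass-weighted standard error across blocks:
#' \deqn{\mathrm{err}^2 = \frac{1}{B_{cell}}\,\frac{B_{cell}}{B_{cell}-1}
#'   \sum_b \hat m_b (F_b - \bar F)^2,}
#' with \eqn{\hat m_b} the normalised block weight masses in the cell and
#' \eqn{B_{cell}} the number of blocks sampling it.  Cells sampled by fewer
#' than two blocks are flagged NA.
#'
#' @inheritParams project_fes
#' @param n_blocks number of blocks (>= 2)
#' @return error grid (kcal/mol), NA where flagged
#' @export
block_error <- function(colvar, weights, x_col = "d", y_col = "nhb",
                        x_edges, y_edges, n_blocks = 5, kT) {
  if (n_blocks < 2) stop("parameter error: n_blocks must be >= 2", call. = FALSE)
  if (is.unsorted(colvar$time)) stop("schema error: frames must be time-ordered",
                                     call. = FALSE)
  idx <- which(weights > 0)
  blocks <- block_split(idx, n_blocks)
  nb <- length(blocks)
  Fb <- list(); Mb <- list()
  for (b in seq_len(nb)) {
    ib <- blocks[[b]]
    wb <- weights[ib] / sum(weights[ib])
    Wb <- cell_weights(colvar[ib, , drop = FALSE], wb, x_col, y_col,
                       x_edges, y_edges)
    Fbm <- matrix(NA_real_, nrow(Wb), ncol(Wb))
    Fbm[Wb > 0] <- -kT * log(Wb[Wb > 0])
    Fb[[b]] <- Fbm
    Mb[[b]] <- sum(weights[ib])
  }
  err <- matrix(NA_real_, length(x_edges) - 1, length(y_edges) - 1)
  for (i in seq_len(nrow(err))) for (j in seq_len(ncol(err))) {
    fv <- vapply(Fb, function(m) m[i, j], 1.0)
    mv <- unlist(Mb)
    ok <- !is.na(fv)
    if (sum(ok) < 2) next
    fv <- fv[ok]; mv <- mv[ok] / sum(mv[ok])
    B <- length(fv)
    fbar <- sum(mv * fv)
    s2 <- sum(mv * (fv - fbar)^2) * B / (B - 1)
    err[i, j] <- sqrt(s2 / B)
  }
  err
}

#' Watershed basin detection on a 2D free-energy grid
#'
#' Local minima below \code{global_min + depth_cutoff} seed basins; every
#' sampled cell is assigned by steepest-descent on the 8-neighbourhood (ties
#' broken toward the lower linear cell index).  Catchments whose minimum is
#' too shallow to seed a basin are merged into the neighbouring catchment
#' across their lowest boundary saddle.  Basins are labelled by increasing
#' minimum free energy (Roman numerals, the deepest first).
#'
#' @param fes an \code{fes2d}
#' @param depth_cutoff kcal/mol: seed threshold above the global minimum
#' @return a \code{basin_set}: list with \code{basins} (data.frame: label,
#'   F_min, cell ranges on both axes, n_cells) and \code{assignment} (integer
#'   matrix, NA for unsampled cells; value k = k-th basin)
#' @export
find_basins <- function(fes, depth_cutoff = 2) {
  F <- fes$F
  if (!any(fes$sampled)) stop("input error: FES has no sampled cells", call. = FALSE)
  nr <- nrow(F); nc <- ncol(F)
  lin <- function(i, j) (j - 1L) * nr + i
  # steepest-descent pointer per sampled cell
  ptr <- rep(NA_integer_, nr * nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (is.na(F[i, j])) next
    best <- lin(i, j); bestF <- F[i, j]
    for (dj in -1:1) for (di in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(F[ii, jj])) next
      l <- lin(ii, jj)
      if (F[ii, jj] < bestF - 1e-15 ||
          (abs(F[ii, jj] - bestF) <= 1e-15 && l < best)) {
        best <- l; bestF <- F[ii, jj]
      }
    }
    ptr[lin(i, j)] <- best
  }
  sampled_lin <- which(!is.na(ptr))
  root <- function(l) { while (ptr[l] != l) l <- ptr[l]; l }
  minima <- sort(unique(vapply(sampled_lin, root, 1L)))
  catch <- rep(NA_integer_, nr * nc)
  for (l in sampled_lin) catch[l] <- root(l)
  Fmin_global <- min(F, na.rm = TRUE)
  is_seed <- F[minima] <= Fmin_global + depth_cutoff
  # merge shallow catchments across their lowest boundary saddle
  while (any(!is_seed)) {
    shallow <- minima[!is_seed]
    m <- shallow[which.max(F[shallow])]
    cells <- which(catch == m)
    best_sad <- Inf; best_target <- NA_integer_
    for (l in cells) {
      i <- (l - 1L) %% nr + 1L; j <- (l - 1L) %/% nr + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        l2 <- lin(ii, jj)
        if (is.na(catch[l2]) || catch[l2] == m) next
        sad <- max(F[l], F[l2])
        if (sad < best_sad - 1e-15 ||
            (abs(sad - best_sad) <= 1e-15 && catch[l2] < best_target)) {
          best_sad <- sad; best_target <- catch[l2]
        }
      }
    }
    if (is.na(best_target)) { # isolated shallow catchment: promote it
      is_seed[minima == m] <- TRUE
      next
    }
    catch[cells] <- best_target
    keep <- minima != m
    minima <- minima[keep]; is_seed <- is_seed[keep]
  }
  ord <- order(F[minima])
  minima <- minima[ord]
  assignment <- matrix(NA_integer_, nr, nc)
  for (k in seq_along(minima)) assignment[catch == minima[k]] <- k
  xc <- (fes$x_edges[-1] + fes$x_edges[-length(fes$x_edges)]) / 2
  yc <- (fes$y_edges[-1] + fes$y_edges[-length(fes$y_edges)]) / 2
  basins <- do.call(rbind, lapply(seq_along(minima), function(k) {
    cells <- which(assignment == k, arr.ind = TRUE)
    data.frame(label = as.character(utils::as.roman(k)),
               F_min = F[minima[k]],
               x_lo = fes$x_edges[min(cells[, 1])],
               x_hi = fes$x_edges[max(cells[, 1]) + 1],
               y_lo = fes$y_edges[min(cells[, 2])],
               y_hi = fes$y_edges[max(cells[, 2]) + 1],
               n_cells = nrow(cells),
               stringsAsFactors = FALSE)
  }))
  out <- list(basins = basins, assignment = assignment,
              x_centers = xc, y_centers = yc)
  class(out) <- "basin_set"
  out
}

#' Classify a (d, N) point against named basin windows
#'
#' @param d distance value(s), nm
#' @param nhb H-bond count(s)
#' @param windows named list of windows, each a list with \code{d = c(lo, hi)}
#'   and \code{N = c(lo, hi)}; see [furosemide_basin_windows()]
#' @return character vector of window names (NA where no window matches)
#' @export
assign_basin <- function(d, nhb, windows) {
  vapply(seq_along(d), function(i) {
    for (nm in names(windows)) {
      w <- windows[[nm]]
      if (d[i] > w$d[1] && d[i] < w$d[2] && nhb[i] > w$N[1] && nhb[i] < w$N[2])
        return(nm)
    }
    NA_character_
  }, "")
}

#' Reference basin windows for furosemide unbinding from mitoNEET
#'
#' The (d, N) windows of the three basins of the furosemide-mitoNEET
#' unbinding map (d in nm to the Fe-S cluster, N the switching-function
#' H-bond/salt-bridge count): the bound basin I, the intermediate II and the
#' largely solvated III.
#'
#' @return named list of windows for [assign_basin()]
#' @export
furosemide_basin_windows <- function() {
  list(I   = list(d = c(0.77, 0.95), N = c(5, 9)),
       II  = list(d = c(1.1, 1.4),  N = c(5.2, 6.7)),
       III = list(d = c(1.5, 1.8),  N = c(2.3, 3.5)))
}

region_mask_colvar <- function(colvar, region) {
  m <- rep(TRUE, nrow(colvar))
  for (cn in names(region)) {
    if (!cn %in% names(colvar))
      stop(sprintf("schema error: region column '%s' not in colvar", cn),
           call. = FALSE)
    m <- m & colvar[[cn]] >= region[[cn]][1] & colvar[[cn]] <= region[[cn]][2]
  }
  m
}

#' Binding free energy between two regions of the reweighted ensemble
#'
#' \eqn{\Delta G = -k_B T \ln(W_{bound}/W_{unbound})}, with the error taken
#' from a block analysis of the same ratio (contiguous blocks, standard error
#' across blocks).  If \code{standard_volume} is given, the geometric volume
#' of the unbound region inside the restraint is computed by grid quadrature
#' and \eqn{k_B T \ln(V_{unbound}/V^0)} is added, referencing the unbound
#' state to the standard concentration (1 M: 1660 A^3).  Off by default.
#'
#' @param weights frame weights
#' @param colvar ColvarTable data.frame
#' @param bound_region,unbound_region named lists of column ranges, e.g.
#'   \code{list(rho = c(0, 4))}; regions must be disjoint on the frames
#' @param kT thermal energy, kcal/mol
#' @param n_blocks blocks for the error estimate
#' @param standard_volume standard-state volume in A^3 (e.g. 1660), or NULL
#' @param vol,host_com the restraint geometry, required with
#'   \code{standard_volume}; the unbound region must then be a \code{rho}
#'   range
#' @return list with \code{delta_g} (kcal/mol), \code{err}, \code{W_bound},
#'   \code{W_unbound} and (when requested) \code{volume_correction}
#' @export
delta_g <- function(weights, colvar, bound_region, unbound_region, kT,
                    n_blocks = 5, standard_volume = NULL, vol = NULL,
                    host_com = c(0, 0, 0)) {
  mb <- region_mask_colvar(colvar, bound_region)
  mu <- region_mask_colvar(colvar, unbound_region)
  if (any(mb & mu & weights > 0))
    stop("region error: bound and unbound regions overlap", call. = FALSE)
  Wb <- sum(weights[mb]); Wu <- sum(weights[mu])
  if (Wb <= 0 || Wu <= 0)
    stop("undefined-deltaG error: zero weight in the bound or unbound region",
         call. = FALSE)
  dg <- -kT * log(Wb / Wu)
  idx <- which(weights > 0)
  blocks <- block_split(idx, n_blocks)
  dgb <- vapply(blocks, function(ib) {
    wb <- sum(weights[intersect(ib, which(mb))])
    wu <- sum(weights[intersect(ib, which(mu))])
    if (wb <= 0 || wu <= 0) return(NA_real_)
    -kT * log(wb / wu)
  }, 1.0)
  dgb <- dgb[!is.na(dgb)]
  err <- if (length(dgb) >= 2) stats::sd(dgb) / sqrt(length(dgb)) else NA_real_
  out <- list(delta_g = dg, err = err, W_bound = Wb, W_unbound = Wu,
              n_blocks_used = length(dgb))
  if (!is.null(standard_volume)) {
    if (is.null(vol) || is.null(unbound_region$rho))
      stop("parameter error: standard-state correction needs vol and a rho-range unbound region",
           call. = FALSE)
    Vu <- region_volume(vol, unbound_region$rho, host_com)
    out$volume_correction <- kT * log(Vu / standard_volume)
    out$delta_g_std <- dg + out$volume_correction
    out$V_unbound <- Vu
  }
  out
}

#' Geometric volume of a rho shell inside the restraint volume
#'
#' Grid quadrature of the indicator of \{rho in range, tau <= tau_max,
#' a >= a_min\}.
#'
#' @param vol a [volume_spec()]
#' @param rho_range c(lo, hi) in Angstrom
#' @param host_com rho reference point
#' @param spacing grid spacing, Angstrom
#' @return volume in A^3
#' @export
region_volume <- function(vol, rho_range, host_com = c(0, 0, 0),
                          spacing = 0.15) {
  hi <- rho_range[2]
  lo3 <- host_com - hi; hi3 <- host_com + hi
  g <- region_grid(list(lo = lo3, hi = hi3), spacing)
  cv <- cpp_cvs_matrix(g$pts, as.numeric(host_com), unclass(vol))
  a <- (g$pts - matrix(vol$origin, nrow(g$pts), 3, byrow = TRUE)) %*% vol$axis
  keep <- cv[, "rho"] >= rho_range[1] & cv[, "rho"] <= rho_range[2] &
    is.finite(cv[, "tau"]) & cv[, "tau"] <= vol$tau_max & a[, 1] >= vol$a_min
  sum(keep) * g$cellvol
}

#' Minimal FES heat map
#'
#' @param fes an \code{fes2d}
#' @param ... passed to [graphics::image()]
#' @return invisibly, the fes
#' @export
plot_fes <- function(fes, ...) {
  xc <- (fes$x_edges[-1] + head(fes$x_edges, -1)) / 2
  yc <- (fes$y_edges[-1] + head(fes$y_edges, -1)) / 2
  graphics::image(xc, yc, fes$F, xlab = fes$x_col, ylab = fes$y_col,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(fes)
}
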