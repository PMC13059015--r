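#' Cumulative reaction coordinate
#'
#' The standard scalar reaction coordinate: s_i = sum_j |R_j - R_{j-1}|
#' with Euclidean (Frobenius) distances between consecutive full coordinate
#' vectors, s_0 = 0. No alignment is applied; this is the conventional
#' path-geometry-dependent measure the 2D projection is designed to
#' complement.
#'
#' @param frames list of [AtomicConfiguration-class] objects (>= 2, equal
#'   atom counts) or a list of N x 3 matrices.
#' @return numeric vector of cumulative distances (Angstrom).
#' @export
cumulativeReactionCoordinate <- function(frames) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  P <- lapply(frames, .coords)
  n <- vapply(P, nrow, 1L)
  if (length(unique(n)) != 1L) stop("frames must have equal atom counts")
  inc <- vapply(seq_len(length(P) - 1L), function(i)
    sqrt(sum((P[[i + 1L]] - P[[i]])^2)), numeric(1))
  c(0, cumsum(inc))
}

#' Force-constrained 1D energy profile
#'
#' Builds the piecewise cubic Hermite interpolant E(s) through the per-image
#' energies with node derivatives prescribed by the tangential forces,
#' dE/ds|_{s_i} = -F_par,i. Unlike generic monotone PCHIP fits, the node
#' derivatives here are data, not estimates: the interpolant reproduces both
#' the energies and the prescribed slopes exactly at every node.
#'
#' @param sNodes strictly increasing cumulative reaction coordinate
#'   (Angstrom).
#' @param energies per-image energies (eV).
#' @param parallelForces per-image tangential force components (eV/Angstrom).
#' @return a [Profile1D-class]; evaluate with [profileEnergy()].
#' @export
buildProfile <- function(sNodes, energies, parallelForces) {
  n <- length(sNodes)
  if (length(energies) != n || length(parallelForces) != n)
    stop("sNodes, energies and parallelForces must have equal length")
  if (n < 2L) stop("need at least 2 nodes")
  if (any(diff(sNodes) <= 0)) stop("sNodes must be strictly increasing")
  new("Profile1D", sNodes = as.numeric(sNodes),
      energies = as.numeric(energies),
      parallelForces = as.numeric(parallelForces))
}

#' Evaluate a 1D profile
#'
#' Evaluates the cubic Hermite interpolant (and optionally its derivative)
#' of a [Profile1D-class]. Queries outside the node range extrapolate with
#' the boundary cubic piece.
#'
#' @param profile a [Profile1D-class].
#' @param s query coordinates (Angstrom).
#' @param deriv 0 for energy, 1 for dE/ds.
#' @return numeric vector of interpolated values.
#' @export
profileEnergy <- function(profile, s, deriv = 0L) {
  x <- profile@sNodes
  y <- profile@energies
  m <- -profile@parallelForces          # prescribed node slopes
  i <- findInterval(s, x, all.inside = TRUE)
  h <- x[i + 1L] - x[i]
  t <- (s - x[i]) / h
  # Hermite basis
  h00 <- 2 * t^3 - 3 * t^2 + 1
  h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2
  h11 <- t^3 - t^2
  if (deriv == 0L)
    return(h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1L] + h11 * h * m[i + 1L])
  d00 <- (6 * t^2 - 6 * t) / h
  d10 <- 3 * t^2 - 4 * t + 1
  d01 <- (-6 * t^2 + 6 * t) / h
  d11 <- 3 * t^2 - 2 * t
  d00 * y[i] + d10 * m[i] + d01 * y[i + 1L] + d11 * m[i + 1L]
}

#' Savitzky-Golay smoothing of projected coordinates
#'
#' Stabilizes the discrete tangent estimate by replacing each projected
#' coordinate series with its local least-squares polynomial fit
#' (Savitzky-Golay; defaults window 5, polynomial order 2). Smoothing acts
#' on the RMSD coordinates only, never on energies. A series shorter than
#' the window passes through unsmoothed with a warning, so short toy paths
#' still work.
#'
#' @param points data.frame with columns `r`, `p` (a single path's images,
#'   in order).
#' @param window odd filter length.
#' @param polyorder polynomial order, less than `window`.
#' @return `points` with `r`, `p` replaced by their smoothed values.
#' @export
smoothCoordinates <- function(points, window = 5L, polyorder = 2L) {
  if (window %% 2L == 0L || polyorder >= window)
    stop("window must be odd and polyorder < window")
  n <- nrow(points)
  if (n < window) {
    warning("series shorter than the smoothing window; passing through")
    return(points)
  }
  points$r <- as.numeric(signal::sgolayfilt(points$r, p = polyorder, n = window))
  points$p <- as.numeric(signal::sgolayfilt(points$p, p = polyorder, n = window))
  points
}

#' Unit path tangents in the projected plane
#'
#' Finite-difference derivatives of the (smoothed) coordinates with respect
#' to the cumulative planar arc length: central differences at interior
#' points, one-sided at the ends, normalized to unit length. A zero-length
#' tangent at a repeated point reuses the previous point's tangent (or the
#' next nonzero one at the start), preserving continuity without inventing
#' directions.
#'
#' @param points data.frame with columns `r`, `p` (one path, in order,
#'   typically smoothed by [smoothCoordinates()]).
#' @return matrix with columns `tau_r`, `tau_p`, unit rows.
#' @export
pathTangents <- function(points) {
  r <- points$r; p <- points$p
  n <- length(r)
  if (n < 2L) stop("need at least 2 points")
  ds <- sqrt(diff(r)^2 + diff(p)^2)
  t <- c(0, cumsum(ds))                       # arc parameter
  dr <- dp <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) { j <- 1L; k <- 2L }
    else if (i == n) { j <- n - 1L; k <- n }
    else { j <- i - 1L; k <- i + 1L }
    dt <- t[k] - t[j]
    if (dt > 0) { dr[i] <- (r[k] - r[j]) / dt; dp[i] <- (p[k] - p[j]) / dt }
  }
  tau <- cbind(tau_r = dr, tau_p = dp)
  norms <- sqrt(rowSums(tau^2))
  # fill degenerate tangents from neighbors
  good <- which(norms > 1e-12)
  if (!length(good)) stop("all tangents degenerate (path has zero length)")
  for (i in seq_len(n)) {
    if (norms[i] > 1e-12) { tau[i, ] <- tau[i, ] / norms[i]; next }
    src <- if (any(good < i)) max(good[good < i]) else min(good[good > i])
    tau[i, ] <- tau[src, ] / norms[src]
  }
  tau
}

#' Synthetic 2D gradients from tangential forces
#'
#' Combines the unit path tangent with the tangential force component to
#' build projected gradients, grad_r = -F_par * tau_r and
#' grad_p = -F_par * tau_p. Because the tangent has unit length, the
#' projected gradient magnitude equals |F_par|. Only the tangential force
#' enters: the Jacobian needed to project full Cartesian forces through the
#' permutation-invariant RMSD is not analytically available.
#'
#' @param tangents matrix from [pathTangents()].
#' @param parallelForces tangential force per point (eV/Angstrom).
#' @return matrix with columns `grad_r`, `grad_p`.
#' @export
projectGradients <- function(tangents, parallelForces) {
  if (nrow(tangents) != length(parallelForces))
    stop("tangents and parallelForces must have equal length")
  cbind(grad_r = -parallelForces * tangents[, 1L],
        grad_p = -parallelForces * tangents[, 2L])
}

#' Attach projected gradients to a whole history
#'
#' Applies smoothing, tangent estimation and gradient projection snapshot by
#' snapshot (tangents are meaningful along one path, not across optimizer
#' steps) and returns the history points with `grad_r`, `grad_p` columns
#' filled.
#'
#' @param points data.frame from [projectHistory()] (must carry `iteration`
#'   and `parallel_force`).
#' @inheritParams smoothCoordinates
#' @return `points` with gradient columns added.
#' @export
addGradients <- function(points, window = 5L, polyorder = 2L) {
  points$grad_r <- NA_real_
  points$grad_p <- NA_real_
  for (it in unique(points$iteration)) {
    sel <- which(points$iteration == it)
    sub <- points[sel, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sm <- suppressWarnings(smoothCoordinates(sub, window, polyorder))
    tau <- pathTangents(sm)
    g <- projectGradients(tau, sub$parallel_force)
    points$grad_r[sel] <- g[, 1L]
    points$grad_p[sel] <- g[, 2L]
  }
  points
}
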