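#' Project an optimization history onto (r, p) coordinates
#'
#' Maps every sampled geometry to its permutation-invariant RMSD distances
#' from the reactant and product references: (r, p) = (d(X, R), d(X, P)).
#' Energies (and bookkeeping columns) are copied from the history records.
#'
#' @param history a [PathHistory-class].
#' @param reactant,product reference [AtomicConfiguration-class] objects
#'   whose element multisets match every frame.
#' @param kmax adjacency cutoff passed to [matchStructures()].
#' @param nStarts rotation starts passed to [matchStructures()].
#' @return data.frame with one row per frame: columns `r`, `p`, `energy`,
#'   `parallel_force`, `image_index`, `iteration`, `final`.
#' @export
projectHistory <- function(history, reactant, product, kmax = 3.5,
                           nStarts = 64L) {
  fr <- frames(history)
  rec <- records(history)
  r <- p <- numeric(length(fr))
  for (i in seq_along(fr)) {
    res <- tryCatch(
      c(rmsd(fr[[i]], reactant, kmax = kmax, nStarts = nStarts),
        rmsd(fr[[i]], product, kmax = kmax, nStarts = nStarts)),
      error = function(e)
        stop("frame ", i, ": ", conditionMessage(e), call. = FALSE))
    r[i] <- res[1L]; p[i] <- res[2L]
  }
  data.frame(
    r = r, p = p,
    energy = rec$energy,
    parallel_force = rec$parallel_force,
    reaction_coordinate = rec$reaction_coordinate,
    image_index = rec$image_index,
    iteration = rec$iteration,
    final = finalPathMask(history)
  )
}

#' Build the reaction-progress frame
#'
#' Defines the rotated (s, d) frame from the projected coordinates of the
#' first and last images of the converged path: the unit tangent points
#' along the projected path direction and the normal is (-s_p, s_r).
#'
#' @param first,last projected endpoints; either single-row data.frames with
#'   columns `r`, `p` or length-2 numerics (r, p).
#' @return a [ProgressFrame-class].
#' @export
buildFrame <- function(first, last) {
  a <- .rp(first); b <- .rp(last)
  v <- b - a
  L <- sqrt(sum(v^2))
  if (L < 1e-12)
    stop("degenerate frame: first and last path images project to the same ",
         "(r, p) point; no progress direction exists")
  t <- v / L
  new("ProgressFrame", origin = a, tangent = t,
      normal = c(-t[2L], t[1L]), length = L)
}

.rp <- function(x) {
  if (is.data.frame(x)) return(as.numeric(c(x$r[1L], x$p[1L])))
  as.numeric(x[1:2])
}

#' Frame from a projected history
#'
#' Convenience: builds the progress frame from the first and last rows of
#' the final converged path of a projected history (the NEB endpoints,
#' which are fixed during optimization).
#'
#' @param points data.frame from [projectHistory()].
#' @return a [ProgressFrame-class].
#' @export
frameFromHistory <- function(points) {
  fp <- points[points$final, , drop = FALSE]
  if (nrow(fp) < 2L) stop("need at least 2 final-path points")
  buildFrame(fp[1L, ], fp[nrow(fp), ])
}

#' Rotate projected points into the (s, d) frame
#'
#' Applies the rigid rotation s = (r - r0) s_r + (p - p0) s_p,
#' d = (r - r0) d_r + (p - p0) d_p. The first path endpoint maps exactly to
#' (0, 0) and the last to (L, 0); the map is an isometry and directly
#' invertible (see [rotateFromProgress()]).
#'
#' @param points data.frame with columns `r`, `p` (other columns pass
#'   through).
#' @param frame a [ProgressFrame-class].
#' @return `points` with columns `s`, `d` filled.
#' @export
rotateToProgress <- function(points, frame) {
  dr <- points$r - frame@origin[1L]
  dp <- points$p - frame@origin[2L]
  points$s <- dr * frame@tangent[1L] + dp * frame@tangent[2L]
  points$d <- dr * frame@normal[1L] + dp * frame@normal[2L]
  points
}

#' @rdname rotateToProgress
#' @param sd data.frame with columns `s`, `d` (or length-2 numeric).
#' @return `rotateFromProgress`: data.frame with columns `r`, `p` recovered
#'   by the inverse rotation.
#' @export
rotateFromProgress <- function(sd, frame) {
  if (!is.data.frame(sd)) sd <- data.frame(s = sd[1L], d = sd[2L])
  data.frame(
    r = frame@origin[1L] + sd$s * frame@tangent[1L] + sd$d * frame@normal[1L],
    p = frame@origin[2L] + sd$s * frame@tangent[2L] + sd$d * frame@normal[2L]
  )
}
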