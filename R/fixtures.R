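# run expr with a private RNG state, restoring the caller's
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Analytic double-well model landscape
#'
#' A 2D toy potential with reactant and product minima at (-1, 0) and
#' (1, 0) and a single saddle at the origin. Along x the profile is the
#' polynomial with E'(x) = (x^3 - x)(alpha x + beta); choosing
#' alpha = -15 a / 4 and beta = 4 b - 2 a makes the stationary values
#' exactly E(reactant) = 0, E(saddle) = `barrier` (= b) and E(product) =
#' `asymmetry` (= a). A harmonic term 0.5 kappa y^2 closes the second
#' dimension. The default barrier/asymmetry scales (0.4 eV barrier, product
#' 0.8 eV below the reactant) mirror a typical exothermic cycloaddition.
#'
#' @param barrier saddle energy above the reactant (eV), > 0.
#' @param asymmetry product energy relative to the reactant (eV); negative
#'   for exothermic.
#' @param kappa transverse harmonic stiffness (eV per Angstrom^2).
#' @return a [ToyLandscape-class].
#' @examples
#' lw <- doubleWellLandscape(0.4, -0.8)
#' lw@energyFn(lw@saddle)   # 0.4
#' @export
doubleWellLandscape <- function(barrier = 0.4, asymmetry = -0.8,
                                kappa = 2) {
  if (barrier <= 0) stop("barrier must be positive")
  a <- asymmetry; b <- barrier
  alpha <- -15 * a / 4
  beta <- 4 * b - 2 * a
  e1 <- function(x)
    alpha * x^5 / 5 + beta * x^4 / 4 - alpha * x^3 / 3 - beta * x^2 / 2 + b
  d1 <- function(x) (x^3 - x) * (alpha * x + beta)
  energyFn <- function(xy) e1(xy[1L]) + 0.5 * kappa * xy[2L]^2
  gradientFn <- function(xy) c(d1(xy[1L]), kappa * xy[2L])
  new("ToyLandscape", energyFn = energyFn, gradientFn = gradientFn,
      minima = rbind(c(-1, 0), c(1, 0)), saddle = c(0, 0))
}

#' Deterministic 2D-to-3N embedding
#'
#' Builds the shared machinery behind [liftTo3N()]: a seeded base geometry
#' of `nAtoms` well-separated atoms and two displacement modes that are
#' (a) Frobenius-orthonormal, (b) free of net translation and rotation
#' about the base geometry, and (c) mutually compatible (their 3 x 3 cross
#' products are symmetric). Those constraints make the optimal
#' superposition between any two lifted frames the identity, so the RMSD
#' between lifted points equals the planar Euclidean distance.
#'
#' @param nAtoms number of atoms (>= 4 recommended).
#' @param seed integer seed fixing the base geometry and modes.
#' @return list with `symbols`, `base` (n x 3, centered), `modes` (list of
#'   two n x 3 matrices) and `scale` (sqrt(n)).
#' @export
makeEmbedding <- function(nAtoms = 8L, seed = 1L) {
  if (nAtoms < 2L) stop("nAtoms must be >= 2")
  .withSeed(seed, {
    # well-separated seeded base geometry in a +-5 A box
    base <- matrix(NA_real_, nAtoms, 3L)
    placed <- 0L
    while (placed < nAtoms) {
      cand <- stats::runif(3, -5, 5)
      if (placed == 0L ||
          min(sqrt(colSums((t(base[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) > 2.5) {
        placed <- placed + 1L
        base[placed, ] <- cand
      }
    }
    base <- sweep(base, 2, colMeans(base))
    symbols <- rep(c("C", "C", "O", "H"), length.out = nAtoms)

    # constraint matrices: translations, infinitesimal rotations
    gens <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
                 rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
                 rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
    tran <- lapply(1:3, function(k) {
      M <- matrix(0, nAtoms, 3L); M[, k] <- 1; M })
    rota <- lapply(gens, function(A) base %*% t(A))
    projOut <- function(U, basis) {
      # orthonormalize the constraint basis first (it is not orthogonal)
      ortho <- list()
      for (Bm in basis) {
        for (Om in ortho) Bm <- Bm - sum(Bm * Om) * Om
        nb <- sqrt(sum(Bm * Bm))
        if (nb > 1e-10) ortho[[length(ortho) + 1L]] <- Bm / nb
      }
      for (Om in ortho) U <- U - sum(U * Om) * Om
      U
    }
    U1 <- projOut(matrix(stats::rnorm(3 * nAtoms), nAtoms, 3L),
                  c(tran, rota))
    U1 <- U1 / sqrt(sum(U1^2))
    # U2 also orthogonal to U1 and with symmetric t(U1) %*% U2
    comp <- lapply(gens, function(A) U1 %*% t(A))
    U2 <- projOut(matrix(stats::rnorm(3 * nAtoms), nAtoms, 3L),
                  c(tran, rota, list(U1), comp))
    U2 <- U2 / sqrt(sum(U2^2))
    list(symbols = symbols, base = base, modes = list(U1, U2),
         scale = sqrt(nAtoms))
  })
}

#' Lift a planar point into molecular coordinates
#'
#' Embeds a 2D point as a fake molecular geometry: the seeded base geometry
#' plus the two fixed orthonormal displacement modes scaled so that the
#' permutation-invariant RMSD between lifted points equals the planar
#' Euclidean distance (isometry to well below 1e-8 for displacements small
#' against the base-geometry scale). Optionally decorates the frame with a
#' seeded rigid transform and within-element permutation, which exercises
#' the invariance of the downstream projection.
#'
#' @param planar length-2 numeric, the 2D point.
#' @param nAtoms number of atoms when `embedding` is built on the fly.
#' @param seed seed for the embedding (and the decoration, offset).
#' @param energy optional energy to attach (eV).
#' @param decorate apply a random rigid transform + within-element
#'   permutation.
#' @param decorSeed seed for the decoration draw.
#' @param embedding optionally a precomputed [makeEmbedding()] result
#'   (recommended inside loops).
#' @return an [AtomicConfiguration-class].
#' @export
liftTo3N <- function(planar, nAtoms = 8L, seed = 1L, energy = NA_real_,
                     decorate = FALSE, decorSeed = seed + 1L,
                     embedding = NULL) {
  if (is.null(embedding)) embedding <- makeEmbedding(nAtoms, seed)
  disp <- embedding$scale *
    (planar[1L] * embedding$modes[[1L]] + planar[2L] * embedding$modes[[2L]])
  pos <- embedding$base + disp
  sym <- embedding$symbols
  if (decorate) {
    .withSeed(decorSeed, {
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      Q <- .quatRotation(q)
      pos <- pos %*% t(Q) + matrix(stats::runif(3, -3, 3),
                                   nrow(pos), 3L, byrow = TRUE)
      perm <- seq_along(sym)
      for (el in unique(sym)) {
        i <- which(sym == el)
        perm[i] <- i[sample(length(i))]
      }
      pos <- pos[perm, , drop = FALSE]
      sym <- sym[perm]
    })
  }
  atomicConfiguration(sym, pos, energy = energy)
}

.quatRotation <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Synthesize a toy optimization history
#'
#' Emulates a double-ended path optimization on an analytic landscape:
#' images start on the straight line between the two minima and relax
#' toward the minimum-energy path by projected gradient descent (the
#' gradient component perpendicular to the discrete tangent), with an
#' equal-arc-length redistribution each sweep so images stay spread. This
#' is deliberately not a faithful NEB (no springs); it only produces
#' plausible histories with known ground truth. Positional jitter of
#' standard deviation `noise` is injected during the first 80% of the
#' iterations and then switched off so the recorded final path is
#' converged. Energies come from the landscape, tangential forces from the
#' analytic gradient projected on the discrete tangent, and every recorded
#' 2D state is lifted to molecular coordinates through a fixed embedding.
#'
#' @param landscape a [ToyLandscape-class].
#' @param nImages images per path (>= 3).
#' @param nIterations relaxation sweeps.
#' @param noise positional jitter standard deviation (Angstrom).
#' @param seed integer seed (embedding, jitter, decorations).
#' @param nAtoms atoms in the lifted geometries.
#' @param recordEvery record every k-th sweep (iteration 0 and the final
#'   sweep are always recorded).
#' @param decorate decorate lifted frames with rigid transforms and
#'   within-element permutations.
#' @param stepSize descent step (Angstrom^2 per eV).
#' @param forceConvention unit of path length for the recorded tangential
#'   force and reaction coordinate. The endpoint-distance projection
#'   stretches path arc anisotropically (a straight segment between the
#'   references stretches by sqrt(2); real RMSD coordinates shrink it by
#'   about sqrt(N)), so a force recorded per unit of one arc is
#'   inconsistent with slopes measured in the other. `"projected"`
#'   (default) records dE per unit of (r, p)-plane arc, making the
#'   downstream synthetic-gradient construction exact so end-to-end checks
#'   probe the implementation, not the projection bias;
#'   `"configuration"` records dE per unit of 3N Frobenius arc, the
#'   convention of a real NEB driver, and exposes that bias for study.
#' @return a [SyntheticHistory-class].
#' @export
synthesizeNebHistory <- function(landscape, nImages = 15L,
                                 nIterations = 200L, noise = 0.02,
                                 seed = 1L, nAtoms = 8L, recordEvery = 10L,
                                 decorate = FALSE, stepSize = 0.05,
                                 forceConvention = c("projected",
                                                     "configuration")) {
  forceConvention <- match.arg(forceConvention)
  if (nImages < 3L) stop("nImages must be >= 3")
  emb <- makeEmbedding(nAtoms, seed)
  A <- landscape@minima[1L, ]; B <- landscape@minima[2L, ]
  w <- seq(0, 1, length.out = nImages)
  path <- cbind(A[1L] + w * (B[1L] - A[1L]), A[2L] + w * (B[2L] - A[2L]))
  recorded <- list()
  recIds <- integer()
  record <- function(P, it) {
    recorded[[length(recorded) + 1L]] <<- P
    recIds[length(recIds) + 1L] <<- it
  }
  .withSeed(seed + 1000L, {
    record(path, 0L)
    if (nIterations > 0L) for (it in seq_len(nIterations)) {
      tau <- .discreteTangents(path)
      for (i in seq(2L, nImages - 1L)) {
        g <- landscape@gradientFn(path[i, ])
        gperp <- g - sum(g * tau[i, ]) * tau[i, ]
        path[i, ] <- path[i, ] - stepSize * gperp
        if (noise > 0 && it <= 0.8 * nIterations)
          path[i, ] <- path[i, ] + stats::rnorm(2, sd = noise * stepSize * 10)
      }
      path <- .redistribute(path)
      if (it %% recordEvery == 0L || it == nIterations) record(path, it)
    }
  })
  framesList <- list(); rows <- list(); truth <- list()
  decorCounter <- 0L
  for (k in seq_along(recorded)) {
    P <- recorded[[k]]
    tau <- .discreteTangents(P)
    e <- apply(P, 1L, landscape@energyFn)
    fpar <- vapply(seq_len(nrow(P)), function(i)
      -sum(landscape@gradientFn(P[i, ]) * tau[i, ]), numeric(1))
    sArc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))   # planar arc
    if (forceConvention == "projected") {
      # rescale dE/d(planar arc) into dE/d((r,p) arc) using the analytic
      # (r, p) coordinates of the planar samples
      rp <- cbind(sqrt(rowSums(sweep(P, 2, A)^2)),
                  sqrt(rowSums(sweep(P, 2, B)^2)))
      sRP <- c(0, cumsum(sqrt(rowSums(diff(rp)^2))))
      stretch <- .centralRatio(sArc, sRP)
      fpar <- fpar * stretch
      sArc <- sRP
    } else {
      # 3N Frobenius arc: the isometric lift scales planar distances by
      # sqrt(nAtoms), forces by its inverse
      sArc <- sArc * emb$scale
      fpar <- fpar / emb$scale
    }
    for (i in seq_len(nrow(P))) {
      decorCounter <- decorCounter + 1L
      framesList[[length(framesList) + 1L]] <-
        liftTo3N(P[i, ], energy = e[i], decorate = decorate,
                 decorSeed = seed + 5000L + decorCounter, embedding = emb)
    }
    rows[[k]] <- data.frame(
      image_index = seq_len(nrow(P)),
      reaction_coordinate = sArc,
      energy = e, parallel_force = fpar,
      iteration = recIds[k])
    truth[[k]] <- data.frame(x = P[, 1L], y = P[, 2L], energy = e,
                             iteration = recIds[k])
  }
  rec <- do.call(rbind, rows)
  hist <- pathHistory(framesList, rec,
                      finalPathMask = rec$iteration == max(rec$iteration))
  new("SyntheticHistory", history = hist, truth = do.call(rbind, truth),
      embedding = emb)
}

#' Write a synthetic history as standard fixture files
#'
#' Dumps a [SyntheticHistory-class] in the formats the command-line
#' interface consumes: a multi-frame XYZ trajectory, a whitespace `.dat`
#' table with columns (image index, reaction coordinate, energy, parallel
#' force), and single-frame XYZ reference files for the reactant, product
#' and true saddle.
#'
#' @param synth a [SyntheticHistory-class].
#' @param dir output directory (created if needed).
#' @param landscape the generating [ToyLandscape-class] (for the reference
#'   geometries).
#' @param prefix file name prefix.
#' @return named list of the files written.
#' @export
writeHistoryFixture <- function(synth, dir, landscape, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- synth@embedding
  paths <- list(
    trajectory = file.path(dir, paste0(prefix, "_traj.xyz")),
    pathTable = file.path(dir, paste0(prefix, "_path.dat")),
    reactant = file.path(dir, paste0(prefix, "_reactant.xyz")),
    product = file.path(dir, paste0(prefix, "_product.xyz")),
    saddle = file.path(dir, paste0(prefix, "_saddle.xyz")))
  writeXYZTrajectory(frames(synth@history), paths$trajectory)
  rec <- records(synth@history)
  lines <- sprintf("%d %.12g %.12g %.12g", rec$image_index,
                   rec$reaction_coordinate, rec$energy, rec$parallel_force)
  writeLines(c("# image reaction_coordinate energy parallel_force", lines),
             paths$pathTable)
  writeXYZTrajectory(liftTo3N(landscape@minima[1, ], embedding = emb,
                              energy = landscape@energyFn(landscape@minima[1, ])),
                     paths$reactant)
  writeXYZTrajectory(liftTo3N(landscape@minima[2, ], embedding = emb,
                              energy = landscape@energyFn(landscape@minima[2, ])),
                     paths$product)
  writeXYZTrajectory(liftTo3N(landscape@saddle, embedding = emb,
                              energy = landscape@energyFn(landscape@saddle)),
                     paths$saddle)
  paths
}

# ratio of central-difference increments of arc a w.r.t. arc b, guarded
.centralRatio <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(i - 1L, 1L); k <- min(i + 1L, n)
    db <- b[k] - b[j]
    out[i] <- if (db > 1e-12) (a[k] - a[j]) / db else 1
  }
  out
}

.discreteTangents <- function(P) {
  n <- nrow(P)
  tau <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    j <- max(i - 1L, 1L); k <- min(i + 1L, n)
    v <- P[k, ] - P[j, ]
    nv <- sqrt(sum(v^2))
    tau[i, ] <- if (nv > 1e-12) v / nv else c(1, 0)
  }
  tau
}

# equal-arc-length resampling along the piecewise-linear path
.redistribute <- function(P) {
  seg <- sqrt(rowSums(diff(P)^2))
  t <- c(0, cumsum(seg))
  tt <- seq(0, t[length(t)], length.out = nrow(P))
  cbind(stats::approx(t, P[, 1L], xout = tt)$y,
        stats::approx(t, P[, 2L], xout = tt)$y)
}
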