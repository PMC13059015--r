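# shared helpers: oracles and generators used across the suite

# random single-element configuration with atoms kept apart
randomConfiguration <- function(n, spread = 3, element = "C") {
  pos <- matrix(runif(3 * n, -spread, spread), n, 3)
  atomicConfiguration(rep(element, n), pos)
}

# random proper rotation from a quaternion draw
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# apply a random rigid transform (and optional within-element permutation)
rigidTransform <- function(conf, permute = FALSE) {
  pos <- positions(conf) %*% t(randomRotation()) +
    matrix(runif(3, -5, 5), nAtoms(conf), 3, byrow = TRUE)
  sym <- elementSymbols(conf)
  if (permute) {
    perm <- seq_along(sym)
    for (el in unique(sym)) {
      i <- which(sym == el)
      perm[i] <- i[sample(length(i))]
    }
    pos <- pos[perm, , drop = FALSE]
    sym <- sym[perm]
  }
  atomicConfiguration(sym, pos, potentialEnergy(conf))
}

# exhaustive oracle: minimum over all permutations of Kabsch RMSD
allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in allPermutations(n - 1)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[rest])
    }
  }
  out
}

bruteForceRmsd <- function(X, Y) {
  PX <- positions(X); PY <- positions(Y)
  best <- Inf
  for (perm in allPermutations(nrow(PX))) {
    d <- kabschAlign(PX, PY[perm, , drop = FALSE])@distance
    if (d < best) best <- d
  }
  best
}

# independent dense GP oracle: explicit inverse, loop-built covariance
denseGPOracle <- function(pts, spec, noise, query) {
  n <- nrow(pts)
  x <- cbind(pts$s, pts$d)
  K <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    k <- kernelValue(x[i, ], x[j, ], spec)
    g <- kernelGrad(x[i, ], x[j, ], spec)
    H <- kernelHess(x[i, ], x[j, ], spec)
    K[bi, bj] <- rbind(c(k, -g), cbind(g, H))
  }
  K <- K + noise * diag(3 * n)
  y <- as.numeric(t(cbind(pts$energy, pts$grad_s, pts$grad_d)))
  w <- solve(K) %*% y
  vapply(seq_len(nrow(query)), function(m) {
    ks <- numeric(3 * n)
    for (j in seq_len(n)) {
      ks[(3 * j - 2):(3 * j)] <- c(
        kernelValue(query[m, ], x[j, ], spec),
        -kernelGrad(query[m, ], x[j, ], spec))
    }
    sum(ks * w)
  }, numeric(1))
}

# draw an observation vector from the gradient-augmented GP prior
samplePriorPoints <- function(n, spec, noise, lim = 2) {
  x <- cbind(runif(n, -lim, lim), runif(n, -lim, lim))
  K <- assembleAugmentedCovariance(x, spec, noise = noise)
  y <- as.numeric(t(chol(K)) %*% rnorm(3 * n))
  data.frame(s = x[, 1], d = x[, 2],
             energy = y[seq(1, 3 * n, 3)],
             grad_s = y[seq(2, 3 * n, 3)],
             grad_d = y[seq(3, 3 * n, 3)],
             final = TRUE)
}

# smooth analytic test surface with exact gradients, sampled along a band
smoothSurfacePoints <- function(n, seedWiggle = 0.3) {
  t <- seq(0, 1, length.out = n)
  s <- 3 * t
  d <- seedWiggle * sin(2 * pi * t)
  data.frame(
    s = s, d = d,
    energy = 0.5 * sin(2 * s) + 0.3 * (d - 0.1)^2,
    grad_s = cos(2 * s),
    grad_d = 0.6 * (d - 0.1),
    final = TRUE)
}

# tiny projected double-well history for end-to-end style checks
projectedDoubleWell <- function(seed = 1, nStarts = 4) {
  lw <- doubleWellLandscape(0.4, -0.8)
  sh <- synthesizeNebHistory(lw, seed = seed)
  R <- liftTo3N(lw@minima[1, ], embedding = sh@embedding)
  P <- liftTo3N(lw@minima[2, ], embedding = sh@embedding)
  pts <- addGradients(projectHistory(sh@history, R, P, nStarts = nStarts))
  fr <- frameFromHistory(pts)
  pts <- rotateGradients(rotateToProgress(pts, fr), fr)
  list(landscape = lw, synth = sh, reactant = R, product = P,
       points = pts, frame = fr)
}
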