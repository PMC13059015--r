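test_that("IMQ kernel value, gradient and Hessian match the closed forms", {
  sp <- kernelSpec("imq", c = 1, amplitude = 1)
  expect_equal(kernelValue(c(0, 0), c(0, 0), sp), 1)
  expect_equal(kernelValue(c(0, 0), c(1, sqrt(2)), sp), 0.5)  # (1+3)^(-1/2)
  expect_equal(kernelGrad(c(0.3, 0.4), c(0.3, 0.4), sp), c(0, 0))
  expect_equal(kernelHess(c(1, 2), c(1, 2), sp), diag(2))
  # symmetry in the arguments
  set.seed(1)
  for (i in 1:20) {
    x <- runif(2, -3, 3); y <- runif(2, -3, 3)
    expect_equal(kernelValue(x, y, sp), kernelValue(y, x, sp))
  }
  # closed forms written out directly
  x <- c(0.7, -0.2); y <- c(-0.4, 1.1)
  dd <- x - y; r2 <- sum(dd^2); c2 <- 1
  expect_equal(kernelGrad(x, y, sp), -dd * (c2 + r2)^(-3 / 2))
  expect_equal(kernelHess(x, y, sp),
               diag(2) * (c2 + r2)^(-3 / 2) -
                 3 * tcrossprod(dd) * (c2 + r2)^(-5 / 2))
})

test_that("kernel derivatives agree with finite differences for all families", {
  set.seed(2)
  h <- 1e-5
  for (fam in c("imq", "squared_exponential", "matern52")) {
    sp <- kernelSpec(fam, c = runif(1, 0.5, 2), amplitude = runif(1, 0.5, 3))
    for (i in 1:25) {
      x <- runif(2, -2, 2); y <- runif(2, -2, 2)
      gfd <- vapply(1:2, function(k) {
        xp <- x; xm <- x; xp[k] <- x[k] + h; xm[k] <- x[k] - h
        (kernelValue(xp, y, sp) - kernelValue(xm, y, sp)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(kernelGrad(x, y, sp) - gfd)) /
                  max(abs(gfd), 1e-3), 1e-5)
      Hfd <- vapply(1:2, function(k) {
        yp <- y; ym <- y; yp[k] <- y[k] + h; ym[k] <- y[k] - h
        (kernelGrad(x, yp, sp) - kernelGrad(x, ym, sp)) / (2 * h)
      }, numeric(2))
      expect_lt(max(abs(kernelHess(x, y, sp) - Hfd)) /
                  max(abs(Hfd), 1e-3), 1e-4)
    }
  }
  # thin plate derivatives hold away from coincidence, diverge at it
  sp <- kernelSpec("thin_plate")
  x <- c(1, 0.5); y <- c(-0.3, 0.2)
  gfd <- vapply(1:2, function(k) {
    xp <- x; xm <- x; xp[k] <- x[k] + h; xm[k] <- x[k] - h
    (kernelValue(xp, y, sp) - kernelValue(xm, y, sp)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(kernelGrad(x, y, sp) - gfd)), 1e-5)
  expect_error(kernelHess(x, x, sp), "singular")
})

test_that("IMQ tails decay as 1/r, 1/r^2 and 1/r^3", {
  a <- 2
  sp <- kernelSpec("imq", c = 0.7, amplitude = a)
  r <- 1000 * sp@c
  x <- c(r, 0); y <- c(0, 0)
  expect_lt(abs(kernelValue(x, y, sp) * r - a), 0.01 * a)
  expect_lt(abs(sqrt(sum(kernelGrad(x, y, sp)^2)) * r^2 - a), 0.01 * a)
  # leading Hessian entry along the separation axis is -2 a / r^3
  expect_lt(abs(max(abs(kernelHess(x, y, sp))) * r^3 - 2 * a), 0.05 * a)
})

test_that("augmented covariance has the printed block structure", {
  sp <- kernelSpec("imq", c = 2, amplitude = 1.5)
  # single point: value 1/c * amplitude, zero cross blocks, c^-3 Hessian
  K1 <- assembleAugmentedCovariance(matrix(c(0.4, -0.1), 1, 2), sp)
  expect_equal(dim(K1), c(3L, 3L))
  expect_equal(K1[1, 1], 1.5 / 2)
  expect_equal(K1[1, 2:3], c(0, 0))
  expect_equal(K1[2:3, 2:3], 1.5 * 2^(-3) * diag(2))
  # symmetry for random point sets
  set.seed(3)
  xs <- matrix(runif(16, -2, 2), 8, 2)
  K <- assembleAugmentedCovariance(xs, sp)
  expect_lt(max(abs(K - t(K))), 1e-12)
  # blocks agree with the scalar kernel API
  i <- 2; j <- 5
  bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
  g <- kernelGrad(xs[i, ], xs[j, ], sp)
  expect_equal(K[bi, bj],
               rbind(c(kernelValue(xs[i, ], xs[j, ], sp), -g),
                     cbind(g, kernelHess(xs[i, ], xs[j, ], sp))),
               ignore_attr = TRUE)
})

test_that("noiseless augmented IMQ covariances are positive semidefinite", {
  set.seed(4)
  for (trial in 1:10) {
    n <- sample(5:20, 1)
    xs <- matrix(runif(2 * n, -3, 3), n, 2)
    K <- assembleAugmentedCovariance(xs, kernelSpec("imq", runif(1, 0.3, 2)))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("full GP interpolates energies and gradients in the small-noise limit", {
  set.seed(5)
  n <- 12
  pts <- data.frame(s = runif(n, -1, 1), d = runif(n, -1, 1))
  pts$energy <- 0.3 * pts$s^2 + 0.2 * pts$d^2 + 0.1 * pts$s * pts$d
  pts$grad_s <- 0.6 * pts$s + 0.1 * pts$d
  pts$grad_d <- 0.4 * pts$d + 0.1 * pts$s
  m <- fitFull(pts, kernelSpec("imq", 0.8, 1.5), noise = 1e-10, center = 0)
  pr <- predictSurface(m, pts)
  expect_lt(max(abs(pr$mean - pts$energy)), 1e-6)
  # gradients via finite differences of the posterior mean
  h <- 1e-5
  for (i in c(2, 7)) {
    gs <- (predictSurface(m, cbind(pts$s[i] + h, pts$d[i]))$mean -
           predictSurface(m, cbind(pts$s[i] - h, pts$d[i]))$mean) / (2 * h)
    gd <- (predictSurface(m, cbind(pts$s[i], pts$d[i] + h))$mean -
           predictSurface(m, cbind(pts$s[i], pts$d[i] - h))$mean) / (2 * h)
    expect_lt(abs(gs - pts$grad_s[i]), 1e-5)
    expect_lt(abs(gd - pts$grad_d[i]), 1e-5)
  }
  # single observation at the origin is reproduced
  one <- data.frame(s = 0, d = 0, energy = 2, grad_s = 0, grad_d = 0)
  m1 <- fitFull(one, kernelSpec("imq"), noise = 1e-10, center = 0)
  expect_equal(predictSurface(m1, cbind(0, 0))$mean, 2, tolerance = 1e-6)
})

test_that("posterior std is small at the data and grows with distance", {
  set.seed(6)
  pts <- smoothSurfacePoints(25)
  m <- fitFull(pts, kernelSpec("imq", 1, 1), noise = 1e-8, center = 0)
  atData <- predictSurface(m, cbind(pts$s[10], pts$d[10]))$std
  far <- predictSurface(m, cbind(pts$s[10] + 10, pts$d[10] + 10))$std
  expect_lt(atData, far)
  # far-field mean reverts to the centering level
  base <- predictSurface(m, cbind(1e5, 1e5))$mean
  expect_lt(abs(base - m@center), 1e-3)
  # unfitted model errors
  m0 <- new("GPSurfaceModel", kernel = kernelSpec(), noise = 0,
            trainX = matrix(0, 1, 2), yFull = 0,
            solver = list(method = "none"), center = 0,
            useGradients = FALSE)
  expect_error(predictSurface(m0, cbind(0, 0)), "not fitted")
})

test_that("factorized solver matches the explicit dense-inverse oracle", {
  set.seed(7)
  for (trial in 1:5) {
    n <- sample(8:15, 1)
    pts <- data.frame(s = runif(n, -2, 2), d = runif(n, -2, 2))
    pts$energy <- sin(pts$s) + 0.3 * pts$d
    pts$grad_s <- cos(pts$s)
    pts$grad_d <- rep(0.3, n)
    sp <- kernelSpec("imq", runif(1, 0.5, 1.5), runif(1, 0.5, 2))
    noise <- 10^runif(1, -8, -4)
    m <- fitFull(pts, sp, noise, center = 0)
    q <- cbind(runif(6, -2, 2), runif(6, -2, 2))
    expect_lt(max(abs(predictSurface(m, q)$mean -
                      denseGPOracle(pts, sp, noise, q))), 1e-8)
  }
})

test_that("Nystrom with all points inducing reproduces the full model", {
  set.seed(8)
  pts <- smoothSurfacePoints(30)
  sp <- kernelSpec("imq", 1, 1)
  mF <- fitFull(pts, sp, 1e-6, center = 0)
  mN <- fitNystrom(pts, sp, 1e-6, inducing = seq_len(nrow(pts)), center = 0)
  q <- cbind(runif(40, 0, 3), runif(40, -0.3, 0.3))
  expect_lt(max(abs(predictSurface(mN, q)$mean -
                    predictSurface(mF, q)$mean)), 1e-6)
  # rank-1 degenerate case stays finite
  m1 <- fitNystrom(pts, sp, 1e-4, inducing = 15L, center = 0)
  at <- predictSurface(m1, cbind(pts$s[15], pts$d[15]))
  expect_true(is.finite(at$mean) && is.finite(at$std))
})

test_that("Nystrom error against the full GP shrinks as M grows", {
  set.seed(9)
  pts <- smoothSurfacePoints(60)
  sp <- kernelSpec("imq", 1, 1)
  mF <- fitFull(pts, sp, 1e-6, center = 0)
  tg <- cbind(seq(0, 3, length.out = 40), 0.1)
  full <- predictSurface(mF, tg)$mean
  errs <- vapply(c(5, 10, 20, 60), function(M) {
    idx <- unique(round(seq(1, 60, length.out = M)))
    m <- fitNystrom(pts, sp, 1e-6, inducing = idx, center = 0)
    sqrt(mean((predictSurface(m, tg)$mean - full)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[4], 1e-6)
  # near-identity already at M = N - 1 on smooth data
  mN1 <- fitNystrom(pts, sp, 1e-6, inducing = 1:59, center = 0)
  expect_lt(max(abs(predictSurface(mN1, tg)$mean - full)), 1e-3)
})

test_that("gradient observations add real predictive information", {
  set.seed(10)
  pts <- smoothSurfacePoints(12)
  sp <- kernelSpec("imq", 1, 1)
  held <- cbind(seq(0.2, 2.8, length.out = 30), 0.05)
  truth <- 0.5 * sin(2 * held[, 1]) + 0.3 * (held[, 2] - 0.1)^2
  mGrad <- fitFull(pts, sp, 1e-8, center = 0)
  mPlain <- fitFull(pts, sp, 1e-8, useGradients = FALSE, center = 0)
  errGrad <- sqrt(mean((predictSurface(mGrad, held)$mean - truth)^2))
  errPlain <- sqrt(mean((predictSurface(mPlain, held)$mean - truth)^2))
  expect_lt(errGrad, errPlain)
})

test_that("subset hyperparameter optimization recovers known scales", {
  spTrue <- kernelSpec("imq", c = 1, amplitude = 1)
  devs <- t(vapply(1:6, function(seed) {
    set.seed(seed)
    pts <- samplePriorPoints(20, spTrue, noise = 1e-2)
    hp <- suppressWarnings(optimizeHyperparameters(
      pts, kernelSpec("imq"), 1e-4,
      lower = c(c = 1e-3, amplitude = 1, noise = 1e-10),
      upper = c(c = 1e2, amplitude = 1, noise = 1), center = 0))
    c(log(hp$spec@c), log(hp$noise) - log(1e-2))
  }, numeric(2)))
  expect_lt(mean(abs(devs[, 1])), 0.5)
  expect_lt(mean(abs(devs[, 2])), 0.5)
  # noiseless smooth data pins the noise near its lower bound
  pts <- smoothSurfacePoints(15)
  hp <- suppressWarnings(optimizeHyperparameters(pts, kernelSpec("imq"),
                                                 1e-4, center = 0))
  expect_lt(hp$noise, 1e-6)
  # fully collapsed bounds come back unchanged
  hp0 <- optimizeHyperparameters(pts, kernelSpec("imq"), 1e-4,
    lower = c(c = 2, amplitude = 3, noise = 1e-5),
    upper = c(c = 2, amplitude = 3, noise = 1e-5), center = 0)
  expect_equal(hp0$spec@c, 2)
  expect_equal(hp0$spec@amplitude, 3)
  expect_equal(hp0$noise, 1e-5)
})

test_that("thin-plate surfaces fit energy-only and stay finite", {
  set.seed(13)
  pts <- smoothSurfacePoints(20)
  m <- fitFull(pts, kernelSpec("thin_plate"), noise = 1e-6)
  expect_false(m@useGradients)
  pr <- predictSurface(m, cbind(1.5, 0))
  expect_true(is.finite(pr$mean) && is.finite(pr$std))
})
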