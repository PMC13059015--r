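test_that("double-well landscape places minima and saddle exactly", {
  lw <- doubleWellLandscape(0.4, -0.8)
  expect_equal(lw@energyFn(c(-1, 0)), 0, tolerance = 1e-12)
  expect_equal(lw@energyFn(c(0, 0)), 0.4, tolerance = 1e-12)
  expect_equal(lw@energyFn(c(1, 0)), -0.8, tolerance = 1e-12)
  for (pt in list(c(-1, 0), c(0, 0), c(1, 0)))
    expect_lt(max(abs(lw@gradientFn(pt))), 1e-12)
  # symmetric wells when the asymmetry vanishes
  sym <- doubleWellLandscape(0.3, 0)
  expect_equal(sym@energyFn(c(-1, 0)), sym@energyFn(c(1, 0)))
  expect_equal(sym@energyFn(c(0, 0)), 0.3)
  expect_equal(sym@saddle, c(0, 0))
  expect_error(doubleWellLandscape(0), "positive")
})

test_that("analytic gradient matches finite differences of the energy", {
  lw <- doubleWellLandscape(0.55, -0.35, kappa = 1.7)
  set.seed(14)
  h <- 1e-6
  for (i in 1:25) {
    x <- runif(2, -1.4, 1.4)
    g <- lw@gradientFn(x)
    gfd <- c((lw@energyFn(x + c(h, 0)) - lw@energyFn(x - c(h, 0))) / (2 * h),
             (lw@energyFn(x + c(0, h)) - lw@energyFn(x - c(0, h))) / (2 * h))
    expect_lt(max(abs(g - gfd)), 1e-6)
  }
})

test_that("the 2D-to-3N lift is an exact isometry under the invariant metric", {
  emb <- makeEmbedding(8, 3)
  expect_equal(rmsd(liftTo3N(c(0.3, -0.2), embedding = emb),
                    liftTo3N(c(0.3, -0.2), embedding = emb)), 0,
               tolerance = 1e-12)
  set.seed(15)
  for (i in 1:15) {
    aa <- runif(2, -1.2, 1.2); bb <- runif(2, -1.2, 1.2)
    d <- rmsd(liftTo3N(aa, embedding = emb), liftTo3N(bb, embedding = emb),
              nStarts = 4)
    expect_lt(abs(d - sqrt(sum((aa - bb)^2))), 1e-8)
  }
  # decoration with rigid transforms + permutations does not move the point
  a <- c(-0.7, 0.3)
  plain <- rmsd(liftTo3N(a, embedding = emb),
                liftTo3N(c(1, 0), embedding = emb))
  dec <- rmsd(liftTo3N(a, embedding = emb, decorate = TRUE, decorSeed = 99),
              liftTo3N(c(1, 0), embedding = emb))
  expect_lt(abs(plain - dec), 1e-6)
})

test_that("embedding construction is deterministic in the seed", {
  e1 <- makeEmbedding(6, 11)
  e2 <- makeEmbedding(6, 11)
  e3 <- makeEmbedding(6, 12)
  expect_identical(e1$base, e2$base)
  expect_identical(e1$modes, e2$modes)
  expect_false(isTRUE(all.equal(e1$base, e3$base)))
})

test_that("synthetic histories relax toward the minimum-energy path", {
  lw <- doubleWellLandscape(0.4, -0.8)
  sh <- synthesizeNebHistory(lw, nImages = 15, nIterations = 200,
                             noise = 0.02, seed = 6)
  rec <- records(sh@history)
  expect_equal(nFrames(sh@history), nrow(rec))
  expect_gte(sum(finalPathMask(sh@history)), 2)
  # zero iterations leaves only the straight line
  sh0 <- synthesizeNebHistory(lw, nImages = 5, nIterations = 0, seed = 1)
  expect_equal(unique(records(sh0@history)$iteration), 0L)
  tr0 <- sh0@truth
  expect_lt(max(abs(tr0$y)), 1e-12)
  # highest final image within two image spacings of the true saddle
  fin <- sh@truth[sh@truth$iteration == max(sh@truth$iteration), ]
  spacing <- 2 / (15 - 1)
  xAtMax <- fin$x[which.max(fin$energy)]
  expect_lt(abs(xAtMax - lw@saddle[1]), 2 * spacing)
  # forces at interior final images shrink against the first sweep
  first <- rec[rec$iteration == 0, ]
  last <- rec[rec$iteration == max(rec$iteration), ]
  expect_lt(stats::median(abs(last$parallel_force[2:14])),
            stats::median(abs(first$parallel_force[2:14])))
  # full determinism under a fixed seed
  sh2 <- synthesizeNebHistory(lw, nImages = 15, nIterations = 200,
                              noise = 0.02, seed = 6)
  expect_identical(records(sh2@history), rec)
  expect_identical(positions(frames(sh2@history)[[40]]),
                   positions(frames(sh@history)[[40]]))
})

test_that("recorded tangential forces are consistent with projected arc", {
  lw <- doubleWellLandscape(0.4, -0.8)
  sh <- synthesizeNebHistory(lw, nImages = 21, nIterations = 40, noise = 0,
                             seed = 9, recordEvery = 40)
  rec <- records(sh@history)
  fin <- rec[rec$iteration == max(rec$iteration), ]
  # integrate -F_par along the recorded reaction coordinate: should track
  # the energy differences between images
  ds <- diff(fin$reaction_coordinate)
  mid <- -(fin$parallel_force[-1] + fin$parallel_force[-21]) / 2
  expect_lt(max(abs(cumsum(mid * ds) - (fin$energy[-1] - fin$energy[1]))),
            0.02)
  # the configuration-arc convention reports sqrt(N)-scaled coordinates
  shc <- synthesizeNebHistory(lw, nImages = 21, nIterations = 40, noise = 0,
                              seed = 9, recordEvery = 40,
                              forceConvention = "configuration")
  recc <- records(shc@history)
  finc <- recc[recc$iteration == max(recc$iteration), ]
  s3n <- cumulativeReactionCoordinate(
    frames(shc@history)[recc$iteration == max(recc$iteration)])
  expect_equal(finc$reaction_coordinate, s3n, tolerance = 1e-8)
})
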