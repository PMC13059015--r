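test_that("grid spans the data with margin and localizes low std at the data", {
  set.seed(16)
  # few, well-separated points so the posterior-std minimum is localized
  pts <- smoothSurfacePoints(8)
  m <- fitFull(pts, kernelSpec("imq", 0.5, 1), 1e-8, center = 0)
  g <- buildGrid(m, pts, resolution = 50, margin = 0.1)
  expect_equal(length(g@sAxis), 50L)
  expect_equal(dim(g@mean), c(50L, 50L))
  expect_lte(min(g@sAxis), min(pts$s))
  expect_gte(max(g@sAxis), max(pts$s))
  expect_true(all(g@std >= 0))
  # std minimum within one cell of a training point
  ij <- which(g@std == min(g@std), arr.ind = TRUE)[1, ]
  cell <- c(diff(g@sAxis[1:2]), diff(g@dAxis[1:2]))
  nearest <- min(sqrt((pts$s - g@sAxis[ij[1]])^2 / cell[1]^2 +
                      (pts$d - g@dAxis[ij[2]])^2 / cell[2]^2))
  expect_lt(nearest, sqrt(2))
})

test_that("external references project through the same pipeline", {
  pd <- projectedDoubleWell(seed = 8)
  ref0 <- projectReference(pd$reactant, pd$reactant, pd$product, pd$frame,
                           nStarts = 4)
  expect_lt(abs(ref0$r), 1e-10)
  expect_lt(max(abs(c(ref0$s, ref0$d))), 1e-10)
  # a final-path image projects onto its own history coordinates
  fin <- pd$points[pd$points$final, ]
  mid <- which(fin$final)[8]
  idx <- which(pd$points$final)[8]
  conf <- frames(pd$synth@history)[[idx]]
  refM <- projectReference(conf, pd$reactant, pd$product, pd$frame,
                           nStarts = 8)
  expect_lt(abs(refM$r - pd$points$r[idx]), 1e-9)
  expect_lt(abs(refM$p - pd$points$p[idx]), 1e-9)
  # invariance under rigid motion of the reference file
  set.seed(3)
  refT <- projectReference(rigidTransform(conf, permute = TRUE),
                           pd$reactant, pd$product, pd$frame, nStarts = 8)
  expect_lt(abs(refT$r - refM$r), 1e-6)
  expect_lt(abs(refT$p - refM$p), 1e-6)
})

test_that("rendering writes a figure plus faithful sidecar tables", {
  set.seed(17)
  pts <- smoothSurfacePoints(20)
  pts$r <- pts$s; pts$p <- max(pts$s) - pts$s   # minimal bookkeeping cols
  pts$energy <- pts$energy
  pts$iteration <- rep(0:1, each = 10)
  pts$image_index <- rep(1:10, 2)
  pts$reaction_coordinate <- pts$s
  pts$parallel_force <- -pts$grad_s
  pts$final <- pts$iteration == 1
  m <- fitFull(pts, kernelSpec("imq", 1, 1), 1e-8, center = 0)
  g <- buildGrid(m, pts, resolution = 25)
  scene <- landscapeScene(g, pts)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "scene")
  files <- renderLandscape(scene, prefix, plotStructures = "crit_points",
                           panels1d = TRUE)
  expect_true(file.exists(paste0(prefix, ".png")))
  for (sidecar in c("_grid.tsv", "_points.tsv", "_references.tsv",
                    "_crit_points.tsv"))
    expect_true(file.exists(paste0(prefix, sidecar)))
  # grid sidecar round-trips the posterior mean values
  gt <- utils::read.table(paste0(prefix, "_grid.tsv"), header = TRUE)
  expect_equal(nrow(gt), 25 * 25)
  expect_lt(max(abs(gt$mean - as.numeric(g@mean))), 1e-9)
  # every plotted marker appears in a sidecar
  pt <- utils::read.table(paste0(prefix, "_points.tsv"), header = TRUE)
  expect_equal(nrow(pt), nrow(pts))
  ct <- utils::read.table(paste0(prefix, "_crit_points.tsv"), header = TRUE)
  expect_setequal(ct$label, c("reactant", "product", "saddle_estimate",
                              "highest_energy_image"))
  # empty reference layer renders without error
  expect_silent(renderLandscape(scene, file.path(dir, "noref")))
})

test_that("the CLI runs end to end and sidecars are byte-identical on rerun", {
  lw <- doubleWellLandscape(0.4, -0.8)
  sh <- synthesizeNebHistory(lw, nImages = 9, nIterations = 40, noise = 0.02,
                             seed = 21, recordEvery = 20)
  dir <- withr::local_tempdir()
  fx <- writeHistoryFixture(sh, dir, lw)
  out1 <- file.path(dir, "run1")
  code <- cliMain(c(
    "--trajectory", fx$trajectory, "--path-table", fx$pathTable,
    "--reactant", fx$reactant, "--product", fx$product,
    "--out", out1, "--surface-type", "grad_imq_ny",
    "--ira-kmax", "3.5", "--plot-structures", "crit_points",
    "--additional-con", fx$saddle, "--resolution", "30", "--seed", "2"))
  expect_equal(code, 0L)
  expect_true(file.exists(paste0(out1, ".png")))
  expect_true(file.exists(paste0(out1, "_grid.tsv")))
  expect_true(file.exists(paste0(out1, "_projection.tsv")))
  refs <- utils::read.table(paste0(out1, "_references.tsv"), header = TRUE)
  expect_equal(nrow(refs), 1)
  # determinism: identical invocation gives byte-identical sidecars
  out2 <- file.path(dir, "run2")
  code2 <- cliMain(c(
    "--trajectory", fx$trajectory, "--path-table", fx$pathTable,
    "--reactant", fx$reactant, "--product", fx$product,
    "--out", out2, "--surface-type", "grad_imq_ny",
    "--ira-kmax", "3.5", "--plot-structures", "crit_points",
    "--additional-con", fx$saddle, "--resolution", "30", "--seed", "2"))
  expect_equal(code2, 0L)
  for (sidecar in c("_grid.tsv", "_points.tsv", "_projection.tsv"))
    expect_identical(readLines(paste0(out1, sidecar)),
                     readLines(paste0(out2, sidecar)))
})

test_that("the CLI reports usage errors cleanly", {
  expect_equal(cliMain("--help"), 0L)
  expect_equal(suppressMessages(cliMain(c("--trajectory", "x.xyz"))), 2L)
  # mismatched elements in an overlay give a runtime error, not a crash
  lw <- doubleWellLandscape(0.4, -0.8)
  sh <- synthesizeNebHistory(lw, nImages = 5, nIterations = 5, noise = 0,
                             seed = 22, recordEvery = 5)
  dir <- withr::local_tempdir()
  fx <- writeHistoryFixture(sh, dir, lw)
  alien <- file.path(dir, "alien.xyz")
  writeXYZTrajectory(atomicConfiguration(rep("Xe", 8),
                                         matrix(runif(24), 8, 3)), alien)
  code <- suppressMessages(cliMain(c(
    "--trajectory", fx$trajectory, "--path-table", fx$pathTable,
    "--reactant", fx$reactant, "--product", fx$product,
    "--out", file.path(dir, "bad"), "--additional-con", alien,
    "--resolution", "20", "--no-hyperopt")))
  expect_equal(code, 1L)
})
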