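#' Evaluate the posterior landscape on a regular grid
#'
#' Spans the bounding box of the projected samples, expanded by a margin
#' fraction on each side, with a regular `resolution x resolution` grid and
#' evaluates the GP posterior mean and standard deviation on it.
#'
#' @param model a fitted [GPSurfaceModel-class].
#' @param points data.frame of projected points (the same coordinate
#'   columns used to fit the model).
#' @param resolution cells per axis.
#' @param margin bounding-box expansion fraction.
#' @return a [LandscapeGrid-class].
#' @export
buildGrid <- function(model, points, resolution = 120L, margin = 0.1) {
  x <- .gpInputs(points, FALSE)$x
  rngS <- range(x[, 1L]); rngD <- range(x[, 2L])
  padS <- margin * max(diff(rngS), 1e-6)
  padD <- margin * max(diff(rngD), 1e-6)
  sAxis <- seq(rngS[1L] - padS, rngS[2L] + padS, length.out = resolution)
  dAxis <- seq(rngD[1L] - padD, rngD[2L] + padD, length.out = resolution)
  q <- cbind(rep(sAxis, times = length(dAxis)),
             rep(dAxis, each = length(sAxis)))
  pr <- predictSurface(model, q)
  new("LandscapeGrid", sAxis = sAxis, dAxis = dAxis,
      mean = matrix(pr$mean, length(sAxis), length(dAxis)),
      std = matrix(pr$std, length(sAxis), length(dAxis)))
}

#' Project an external reference structure
#'
#' Runs a single external geometry (for example a saddle point optimized
#' with a different method or level of theory) through the same
#' (r, p) / (s, d) pipeline as the history, so it can be overlaid on the
#' interpolated landscape for validation.
#'
#' @param structure an [AtomicConfiguration-class].
#' @param reactant,product the same references used for the history.
#' @param frame the [ProgressFrame-class] of the history (`NULL` leaves
#'   s, d as `NA`).
#' @param kmax,nStarts passed to [matchStructures()].
#' @param label free-text marker label.
#' @return one-row data.frame with columns `r`, `p`, `s`, `d`, `energy`,
#'   `label`.
#' @export
projectReference <- function(structure, reactant, product, frame = NULL,
                             kmax = 3.5, nStarts = 64L, label = "reference") {
  out <- data.frame(
    r = rmsd(structure, reactant, kmax = kmax, nStarts = nStarts),
    p = rmsd(structure, product, kmax = kmax, nStarts = nStarts),
    s = NA_real_, d = NA_real_,
    energy = potentialEnergy(structure),
    label = label, stringsAsFactors = FALSE)
  if (!is.null(frame)) {
    sd <- rotateToProgress(out, frame)
    out$s <- sd$s; out$d <- sd$d
  }
  out
}

#' Compose a landscape scene
#'
#' @param grid a [LandscapeGrid-class].
#' @param historyPoints all projected samples.
#' @param references labeled external reference projections (possibly
#'   empty).
#' @param inducingMask logical per history point (default none).
#' @return a [LandscapeScene-class].
#' @export
landscapeScene <- function(grid, historyPoints,
                           references = data.frame(),
                           inducingMask = NULL) {
  if (is.null(inducingMask))
    inducingMask <- rep(FALSE, nrow(historyPoints))
  new("LandscapeScene", grid = grid, historyPoints = historyPoints,
      finalPath = historyPoints[historyPoints$final, , drop = FALSE],
      references = references, inducingMask = inducingMask)
}

# grid as long data.frame (column-major over d, matching buildGrid)
.gridTable <- function(grid) {
  data.frame(s = rep(grid@sAxis, times = length(grid@dAxis)),
             d = rep(grid@dAxis, each = length(grid@sAxis)),
             mean = as.numeric(grid@mean),
             std = as.numeric(grid@std))
}

# deterministic TSV writer: fixed %.12g formatting, byte-stable
.writeTSV <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(v)
      if (is.numeric(v)) sprintf("%.12g", v) else as.character(v))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Render a landscape figure with sidecar tables
#'
#' Draws the interpolated energy surface (color), posterior-variance
#' contours (dashed, by default at 25/50/75% of the maximum grid standard
#' deviation), all sampled structures (dots, shaded dark to light from
#' early to late optimizer steps), the converged path (open circles) and
#' any reference structures (stars). Alongside the figure, machine-readable
#' sidecar tables are written for every plotted layer (grid, points,
#' references, critical points), so no data exists only as pixels.
#' Optionally adds the three companion 1D panels (energy against reaction
#' coordinate via the force-constrained Hermite profile, against image
#' index, and against RMSD from the reactant).
#'
#' @param scene a [LandscapeScene-class].
#' @param prefix output path prefix; the figure goes to `<prefix>.png` and
#'   sidecars to `<prefix>_grid.tsv`, `<prefix>_points.tsv`,
#'   `<prefix>_references.tsv` (and `<prefix>_crit_points.tsv` when
#'   requested).
#' @param contourLevels variance contour levels as fractions of the maximum
#'   grid std.
#' @param plotStructures `"none"` or `"crit_points"` (marks reactant,
#'   product, saddle estimate and highest-energy image).
#' @param panels1d add the 1D companion panels below the map.
#' @param width,height,dpi figure geometry.
#' @return invisibly, the named list of files written.
#' @export
renderLandscape <- function(scene, prefix, contourLevels = c(0.25, 0.5, 0.75),
                            plotStructures = c("none", "crit_points"),
                            panels1d = FALSE, width = 7, height = 6,
                            dpi = 150) {
  plotStructures <- match.arg(plotStructures)
  files <- list()
  gridTab <- .gridTable(scene@grid)
  pts <- scene@historyPoints
  pts$inducing <- scene@inducingMask
  files$grid <- .writeTSV(gridTab, paste0(prefix, "_grid.tsv"))
  files$points <- .writeTSV(pts, paste0(prefix, "_points.tsv"))
  files$references <- .writeTSV(scene@references,
                                paste0(prefix, "_references.tsv"))
  crit <- NULL
  if (plotStructures == "crit_points") {
    crit <- .criticalPoints(scene@finalPath)
    files$crit <- .writeTSV(crit, paste0(prefix, "_crit_points.tsv"))
  }

  useSD <- all(is.finite(pts$s))
  ax <- if (useSD) c("s", "d") else c("r", "p")
  names(gridTab)[1:2] <- ax
  maxStd <- max(gridTab$std)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = gridTab,
      ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]], fill = mean)) +
    ggplot2::scale_fill_viridis_c(name = "E (eV)", option = "C")
  if (maxStd > 0)
    p <- p + ggplot2::geom_contour(data = gridTab,
      ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]], z = std),
      breaks = contourLevels * maxStd, linetype = "dashed",
      colour = "grey20", linewidth = 0.3)
  p <- p +
    ggplot2::geom_point(data = pts,
      ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                   alpha = iteration),
      colour = "black", size = 0.8, show.legend = FALSE) +
    ggplot2::scale_alpha_continuous(range = c(0.25, 1)) +
    ggplot2::geom_point(data = scene@finalPath,
      ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]),
      shape = 1, colour = "black", size = 2)
  if (nrow(scene@references))
    p <- p + ggplot2::geom_point(data = scene@references,
      ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]),
      shape = 8, colour = "white", size = 3, stroke = 1.1)
  if (!is.null(crit))
    p <- p + ggplot2::geom_point(data = crit,
      ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]),
      shape = 5, colour = "white", size = 2.5)
  p <- p + ggplot2::labs(
    x = if (useSD) "reaction progress s (Å)" else "RMSD to reactant r (Å)",
    y = if (useSD) "orthogonal deviation d (Å)" else "RMSD to product p (Å)") +
    ggplot2::theme_minimal()

  if (panels1d) {
    panels <- .profilePanels(pts, ax)
    if (requireNamespace("patchwork", quietly = TRUE)) {
      p <- patchwork::wrap_plots(
        p, patchwork::wrap_plots(panels, nrow = 1),
        ncol = 1, heights = c(2, 1))
    } else {
      for (i in seq_along(panels)) {
        f1 <- paste0(prefix, "_panel", i, ".png")
        suppressMessages(ggplot2::ggsave(f1, panels[[i]],
          width = width / 2, height = height / 2.5, dpi = dpi))
        files[[paste0("panel", i)]] <- f1
      }
    }
  }
  fig <- paste0(prefix, ".png")
  suppressMessages(ggplot2::ggsave(fig, p, width = width, height = height,
                                   dpi = dpi))
  files$figure <- fig
  invisible(files)
}

# reactant, product, saddle estimate and highest-energy image of the final
# path; without a climbing-image marker the two saddle entries coincide
.criticalPoints <- function(finalPath) {
  hi <- which.max(finalPath$energy)
  out <- rbind(finalPath[1L, ], finalPath[nrow(finalPath), ],
               finalPath[hi, ], finalPath[hi, ])
  out$label <- c("reactant", "product", "saddle_estimate",
                 "highest_energy_image")
  out
}

.profilePanels <- function(pts, ax) {
  fin <- pts[pts$final, , drop = FALSE]
  base <- function() ggplot2::theme_minimal()
  p1 <- ggplot2::ggplot(pts, ggplot2::aes(x = reaction_coordinate,
                                          y = energy, group = iteration,
                                          colour = iteration)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_viridis_c()
  if (nrow(fin) >= 2L && all(diff(fin$reaction_coordinate) > 0)) {
    prof <- buildProfile(fin$reaction_coordinate, fin$energy,
                         fin$parallel_force)
    ss <- seq(min(fin$reaction_coordinate), max(fin$reaction_coordinate),
              length.out = 200)
    p1 <- p1 + ggplot2::geom_line(
      data = data.frame(reaction_coordinate = ss,
                        energy = profileEnergy(prof, ss), iteration = NA),
      colour = "black", linewidth = 0.7)
  }
  p1 <- p1 + ggplot2::labs(x = "reaction coordinate (Å)", y = "E (eV)") +
    base()
  p2 <- ggplot2::ggplot(pts, ggplot2::aes(x = image_index, y = energy,
                                          group = iteration,
                                          colour = iteration)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::geom_line(data = fin, colour = "black", linewidth = 0.7) +
    ggplot2::labs(x = "image index", y = "E (eV)") + base()
  p3 <- ggplot2::ggplot(pts, ggplot2::aes(x = r, y = energy,
                                          group = iteration,
                                          colour = iteration)) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::geom_point(data = fin, colour = "black", shape = 1) +
    ggplot2::labs(x = "RMSD from reactant (Å)", y = "E (eV)") + base()
  list(p1, p2, p3)
}

#' @importFrom rlang .data
NULL
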