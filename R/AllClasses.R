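#' @import methods
NULL

#' A single atomic configuration
#'
#' Holds one molecular geometry: element symbols, Cartesian coordinates in
#' Angstrom, and optionally a potential energy in eV and a free-text frame
#' label (typically the trajectory comment line).
#'
#' @slot symbols character vector of element symbols, one per atom.
#' @slot positions numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @slot energy length-one numeric, eV; `NA` when no energy is attached.
#' @slot tag free-text frame label.
#'
#' @seealso [atomicConfiguration()] for the user-facing constructor,
#'   [readXYZTrajectory()] for file input.
#' @export
setClass("AtomicConfiguration",
  representation(
    symbols = "character",
    positions = "matrix",
    energy = "numeric",
    tag = "character"
  ),
  prototype(
    symbols = character(),
    positions = matrix(numeric(), 0L, 3L),
    energy = NA_real_,
    tag = ""
  )
)

setValidity("AtomicConfiguration", function(object) {
  msg <- character()
  if (!is.numeric(object@positions) || ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be a numeric matrix with 3 columns")
  else {
    if (nrow(object@positions) != length(object@symbols))
      msg <- c(msg, "positions row count must equal number of symbols")
    if (length(object@positions) && !all(is.finite(object@positions)))
      msg <- c(msg, "all coordinates must be finite")
  }
  if (length(object@energy) != 1L)
    msg <- c(msg, "energy must have length 1 (use NA when absent)")
  if (length(msg)) msg else TRUE
})

#' Construct an AtomicConfiguration
#'
#' @param symbols character vector of element symbols.
#' @param positions numeric N x 3 matrix (Angstrom); a numeric vector of
#'   length 3N is reshaped row-wise.
#' @param energy optional potential energy (eV).
#' @param tag optional frame label.
#' @return An [AtomicConfiguration-class] object.
#' @examples
#' h2 <- atomicConfiguration(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' nAtoms(h2)
#' @export
atomicConfiguration <- function(symbols, positions, energy = NA_real_, tag = "") {
  if (is.vector(positions)) positions <- matrix(positions, ncol = 3L, byrow = TRUE)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  new("AtomicConfiguration",
    symbols = as.character(symbols), positions = positions,
    energy = as.numeric(energy)[1L], tag = as.character(tag)[1L]
  )
}

#' Ordered optimization history of a path search
#'
#' Collects every sampled image of a double-ended path optimization: the
#' geometries, the per-image records (image index within its snapshot,
#' cumulative reaction coordinate, energy, tangential force component), and
#' a mask marking which frames belong to the final converged path.
#'
#' @slot frames list of [AtomicConfiguration-class] objects, one per sample.
#' @slot records data.frame aligned with `frames`; columns `image_index`,
#'   `reaction_coordinate` (Angstrom), `energy` (eV), `parallel_force`
#'   (eV/Angstrom) and `iteration` (snapshot id, i.e. which optimizer step
#'   the image belongs to).
#' @slot finalPathMask logical per frame, `TRUE` for the last converged path.
#' @export
setClass("PathHistory",
  representation(
    frames = "list",
    records = "data.frame",
    finalPathMask = "logical"
  )
)

setValidity("PathHistory", function(object) {
  msg <- character()
  n <- length(object@frames)
  need <- c("image_index", "reaction_coordinate", "energy", "parallel_force",
            "iteration")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@records) != n)
      msg <- c(msg, "frames and records must have equal length")
    for (it in unique(object@records$iteration)) {
      idx <- object@records$image_index[object@records$iteration == it]
      if (any(diff(idx) <= 0)) {
        msg <- c(msg, sprintf(
          "image_index must be strictly increasing within snapshot %s", it))
        break
      }
    }
  }
  if (length(object@finalPathMask) != n)
    msg <- c(msg, "finalPathMask must have one entry per frame")
  if (sum(object@finalPathMask) < 2L)
    msg <- c(msg, "at least 2 frames must be marked final (path endpoints)")
  if (length(msg)) msg else TRUE
})

#' Construct a PathHistory
#'
#' @param frames list of [AtomicConfiguration-class] objects.
#' @param records data.frame with columns `image_index`,
#'   `reaction_coordinate`, `energy`, `parallel_force` and optionally
#'   `iteration` (defaults to a single snapshot).
#' @param finalPathMask logical per frame; default marks every frame of the
#'   last `iteration` as the final converged path.
#' @return A [PathHistory-class] object.
#' @export
pathHistory <- function(frames, records, finalPathMask = NULL) {
  if (is.null(records$iteration)) records$iteration <- 0L
  if (is.null(finalPathMask)) {
    finalPathMask <- records$iteration == max(records$iteration)
  }
  new("PathHistory", frames = frames, records = as.data.frame(records),
      finalPathMask = as.logical(finalPathMask))
}

#' Result of a structure alignment
#'
#' @slot distance RMSD after optimal superposition (Angstrom).
#' @slot rotation 3 x 3 proper rotation matrix (det +1) applied to the
#'   second structure.
#' @slot permutation integer vector: atom `i` of the first structure is
#'   matched to atom `permutation[i]` of the second.
#' @slot translation length-3 numeric; rigid shift completing the map of the
#'   second structure onto the first.
#' @export
setClass("AlignmentResult",
  representation(
    distance = "numeric",
    rotation = "matrix",
    permutation = "integer",
    translation = "numeric"
  )
)

setValidity("AlignmentResult", function(object) {
  msg <- character()
  Q <- object@rotation
  if (!all(dim(Q) == c(3L, 3L)))
    msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(Q) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthogonal to 1e-8")
    if (abs(det(Q) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (length(object@distance) != 1L || object@distance < -1e-12)
    msg <- c(msg, "distance must be a nonnegative scalar")
  if (!identical(sort(object@permutation), seq_along(object@permutation)))
    msg <- c(msg, "permutation must be a bijection on atom indices")
  if (length(msg)) msg else TRUE
})

#' Reaction-progress frame in the (r, p) plane
#'
#' The rigid rotation taking raw (distance-to-reactant, distance-to-product)
#' coordinates into reaction progress s and orthogonal deviation d. The
#' tangent points from the projected first path endpoint to the projected
#' last one; the normal is its 90-degree counter-clockwise rotation
#' (-s_p, s_r).
#'
#' @slot origin numeric length 2, (r0, p0) of the first path endpoint.
#' @slot tangent unit vector (s_r, s_p).
#' @slot normal unit vector (d_r, d_p) = (-s_p, s_r).
#' @slot length Euclidean distance between the projected endpoints (Angstrom).
#' @export
setClass("ProgressFrame",
  representation(
    origin = "numeric",
    tangent = "numeric",
    normal = "numeric",
    length = "numeric"
  )
)

setValidity("ProgressFrame", function(object) {
  msg <- character()
  if (length(object@tangent) != 2L || abs(sqrt(sum(object@tangent^2)) - 1) > 1e-10)
    msg <- c(msg, "tangent must be a 2D unit vector")
  if (length(object@normal) != 2L ||
      max(abs(object@normal - c(-object@tangent[2L], object@tangent[1L]))) > 1e-10)
    msg <- c(msg, "normal must equal (-s_p, s_r)")
  if (object@length <= 0)
    msg <- c(msg, "frame length must be positive")
  if (length(msg)) msg else TRUE
})

#' Force-constrained 1D energy profile
#'
#' Piecewise cubic Hermite interpolant of energy against the cumulative
#' reaction coordinate, with node derivatives prescribed as the negative
#' tangential force, dE/ds = -F_par.
#'
#' @slot sNodes cumulative reaction coordinate per image (Angstrom),
#'   strictly increasing.
#' @slot energies per-image energies (eV).
#' @slot parallelForces per-image tangential force components (eV/Angstrom).
#' @export
setClass("Profile1D",
  representation(
    sNodes = "numeric",
    energies = "numeric",
    parallelForces = "numeric"
  )
)

setValidity("Profile1D", function(object) {
  msg <- character()
  n <- length(object@sNodes)
  if (n < 2L) msg <- c(msg, "at least 2 nodes required")
  if (any(diff(object@sNodes) <= 0))
    msg <- c(msg, "sNodes must be strictly increasing")
  if (length(object@energies) != n || length(object@parallelForces) != n)
    msg <- c(msg, "energies and parallelForces must match sNodes length")
  if (length(msg)) msg else TRUE
})

#' Kernel specification for the landscape Gaussian process
#'
#' @slot family one of `"imq"` (inverse multiquadric), `"squared_exponential"`,
#'   `"matern52"` or `"thin_plate"`.
#' @slot c positive scale parameter (Angstrom).
#' @slot amplitude positive output scale (eV).
#' @export
setClass("KernelSpec",
  representation(family = "character", c = "numeric", amplitude = "numeric"),
  prototype(family = "imq", c = 1, amplitude = 1)
)

setValidity("KernelSpec", function(object) {
  fams <- c("imq", "squared_exponential", "matern52", "thin_plate")
  msg <- character()
  if (!(object@family %in% fams))
    msg <- c(msg, paste("family must be one of:", paste(fams, collapse = ", ")))
  if (object@c <= 0) msg <- c(msg, "c must be positive")
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be positive")
  if (length(msg)) msg else TRUE
})

#' @param family kernel family name.
#' @param c scale parameter (Angstrom).
#' @param amplitude output scale (eV).
#' @rdname KernelSpec-class
#' @export
kernelSpec <- function(family = "imq", c = 1, amplitude = 1) {
  new("KernelSpec", family = family, c = as.numeric(c),
      amplitude = as.numeric(amplitude))
}

#' Fitted gradient-enhanced GP surface model
#'
#' The observation vector interleaves energy and projected gradient per
#' training point, `[E1, gx1, gy1, E2, ...]`; the covariance combines kernel
#' values, first derivatives and second derivatives in matching blocks.
#' `solver` holds either the Cholesky factor of the full augmented covariance
#' or the Nystrom factorization (L, V, S, alpha_M).
#'
#' @slot kernel a [KernelSpec-class].
#' @slot noise observation noise variance sigma^2 (eV^2), shared by all
#'   channels.
#' @slot trainX n x 2 matrix of training inputs in the projected plane.
#' @slot yFull augmented (centered) observation vector.
#' @slot solver list of factorization artifacts; `solver$method` is
#'   `"full"` or `"nystrom"`.
#' @slot center energy offset subtracted before fitting (added back at
#'   prediction), so the GP prior mean sits at the reference level.
#' @slot useGradients logical; `FALSE` for energy-only fits (thin-plate).
#' @export
setClass("GPSurfaceModel",
  representation(
    kernel = "KernelSpec",
    noise = "numeric",
    trainX = "matrix",
    yFull = "numeric",
    solver = "list",
    center = "numeric",
    useGradients = "logical"
  )
)

setValidity("GPSurfaceModel", function(object) {
  msg <- character()
  n <- nrow(object@trainX)
  d <- if (object@useGradients) 3L else 1L
  if (length(object@yFull) != d * n)
    msg <- c(msg, "yFull length must be (D+1)*n_train (or n_train energy-only)")
  if (object@noise < 0) msg <- c(msg, "noise must be nonnegative")
  if (is.null(object@solver$method))
    msg <- c(msg, "solver must record its method")
  if (length(msg)) msg else TRUE
})

#' Regular grid of posterior landscape predictions
#'
#' @slot sAxis,dAxis monotone grid coordinates (Angstrom).
#' @slot mean matrix of posterior mean energies (eV), `length(sAxis)` rows.
#' @slot std matrix of posterior standard deviations (eV), same shape.
#' @export
setClass("LandscapeGrid",
  representation(
    sAxis = "numeric", dAxis = "numeric",
    mean = "matrix", std = "matrix"
  )
)

setValidity("LandscapeGrid", function(object) {
  msg <- character()
  if (!all(dim(object@mean) == c(length(object@sAxis), length(object@dAxis))))
    msg <- c(msg, "mean shape must be length(sAxis) x length(dAxis)")
  if (!all(dim(object@std) == dim(object@mean)))
    msg <- c(msg, "std shape must match mean")
  if (length(object@std) && min(object@std) < 0)
    msg <- c(msg, "std must be nonnegative everywhere")
  if (any(diff(object@sAxis) <= 0) || any(diff(object@dAxis) <= 0))
    msg <- c(msg, "axes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Analytic 2D model landscape
#'
#' A toy potential energy surface used to generate synthetic optimization
#' histories with known ground truth.
#'
#' @slot energyFn function of a length-2 numeric returning energy (eV).
#' @slot gradientFn function of a length-2 numeric returning its 2D gradient.
#' @slot minima 2 x 2 matrix; rows are the reactant and product minima.
#' @slot saddle length-2 numeric, the saddle location.
#' @export
setClass("ToyLandscape",
  representation(
    energyFn = "function", gradientFn = "function",
    minima = "matrix", saddle = "numeric"
  )
)

#' Synthetic optimization history with known ground truth
#'
#' @slot history the generated [PathHistory-class].
#' @slot truth data.frame of per-frame true 2D coordinates (`x`, `y`),
#'   energies and snapshot ids.
#' @slot embedding list describing the 2D-to-3N lift (base geometry, modes).
#' @export
setClass("SyntheticHistory",
  representation(history = "PathHistory", truth = "data.frame",
                 embedding = "list")
)

#' Composition of one landscape figure
#'
#' @slot grid a [LandscapeGrid-class].
#' @slot historyPoints data.frame of all projected samples (columns r, p, s,
#'   d, energy, grad_r, grad_p, iteration).
#' @slot finalPath data.frame of the converged-path subset.
#' @slot references data.frame of labeled external reference projections.
#' @slot inducingMask logical per history point; `TRUE` where the point was
#'   used as a Nystrom inducing point.
#' @export
setClass("LandscapeScene",
  representation(
    grid = "LandscapeGrid",
    historyPoints = "data.frame",
    finalPath = "data.frame",
    references = "data.frame",
    inducingMask = "logical"
  )
)
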