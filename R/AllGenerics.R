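#' Accessors for pathscape objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a pathscape S4 object.
#' @return `elementSymbols`: character vector; `positions`: N x 3 matrix;
#'   `potentialEnergy`: scalar eV (`NA` if absent); `nAtoms`, `nFrames`:
#'   integer counts; `records`: the per-image data.frame;
#'   `finalPathMask`: logical vector; `frames`: list of configurations.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("elementSymbols", function(object) standardGeneric("elementSymbols"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("potentialEnergy", function(object) standardGeneric("potentialEnergy"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("finalPathMask", function(object) standardGeneric("finalPathMask"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setMethod("elementSymbols", "AtomicConfiguration", function(object) object@symbols)
#' @rdname accessors
#' @export
setMethod("positions", "AtomicConfiguration", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("potentialEnergy", "AtomicConfiguration", function(object) object@energy)
#' @rdname accessors
#' @export
setMethod("nAtoms", "AtomicConfiguration", function(object) length(object@symbols))

#' @rdname accessors
#' @export
setMethod("nFrames", "PathHistory", function(object) length(object@frames))
#' @rdname accessors
#' @export
setMethod("records", "PathHistory", function(object) object@records)
#' @rdname accessors
#' @export
setMethod("finalPathMask", "PathHistory", function(object) object@finalPathMask)
#' @rdname accessors
#' @export
setMethod("frames", "PathHistory", function(object) object@frames)

setMethod("show", "AtomicConfiguration", function(object) {
  comp <- table(object@symbols)
  cat("AtomicConfiguration:", nAtoms(object), "atoms (",
      paste0(names(comp), comp, collapse = " "), ")\n")
  if (!is.na(object@energy)) cat("  energy:", object@energy, "eV\n")
  if (nzchar(object@tag)) cat("  tag:", object@tag, "\n")
})

setMethod("show", "PathHistory", function(object) {
  cat("PathHistory:", nFrames(object), "frames in",
      length(unique(object@records$iteration)), "snapshots;",
      sum(object@finalPathMask), "frames on the final path\n")
})

setMethod("show", "AlignmentResult", function(object) {
  cat("AlignmentResult: RMSD", format(object@distance, digits = 6), "A",
      "(permutation", if (identical(object@permutation,
                                    seq_along(object@permutation)))
        "identity)" else "non-trivial)", "\n")
})

setMethod("show", "KernelSpec", function(object) {
  cat("KernelSpec:", object@family, " c =", object@c,
      " amplitude =", object@amplitude, "\n")
})

setMethod("show", "GPSurfaceModel", function(object) {
  cat("GPSurfaceModel (", object@solver$method, "): ",
      nrow(object@trainX), " training points, ",
      if (object@useGradients) "gradient-augmented" else "energy-only",
      ", kernel ", object@kernel@family,
      " (c = ", format(object@kernel@c, digits = 4),
      ", amplitude = ", format(object@kernel@amplitude, digits = 4),
      "), noise = ", format(object@noise, digits = 4), "\n", sep = "")
})

setMethod("show", "LandscapeGrid", function(object) {
  cat("LandscapeGrid:", length(object@sAxis), "x", length(object@dAxis),
      "cells; s in [", min(object@sAxis), ",", max(object@sAxis),
      "], d in [", min(object@dAxis), ",", max(object@dAxis), "]\n")
})

setMethod("show", "ToyLandscape", function(object) {
  cat("ToyLandscape: minima at (", paste(object@minima[1, ], collapse = ", "),
      ") and (", paste(object@minima[2, ], collapse = ", "),
      "), saddle at (", paste(object@saddle, collapse = ", "), ")\n")
})
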