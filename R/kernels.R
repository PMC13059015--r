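#' Kernel evaluation
#'
#' Radial kernels are written as k(x, x') = g(t) with t = ||x - x'||^2, so
#' the derivative blocks of the gradient-augmented covariance follow from
#' g'(t) and g''(t):
#' dk/dx_i = 2 g'(t) (x_i - x'_i) and
#' d2k/dx_i dx'_j = -2 delta_ij g'(t) - 4 g''(t) (x_i - x'_i)(x_j - x'_j).
#' For the inverse multiquadric, k = amplitude (c^2 + t)^(-1/2), these
#' reduce to the closed forms
#' dk/dx_i = -(x_i - x'_i)(c^2 + t)^(-3/2) and
#' d2k/dx_i dx'_j = delta_ij (c^2 + t)^(-3/2)
#'   - 3 (x_i - x'_i)(x_j - x'_j)(c^2 + t)^(-5/2)
#' (times amplitude). The IMQ is completely monotone in t, hence strictly
#' positive definite in every dimension, and decays polynomially: values as
#' 1/r, first derivatives as 1/r^2, second as 1/r^3.
#'
#' @param x,x2 length-2 numeric inputs in the projected plane.
#' @param spec a [KernelSpec-class].
#' @return `kernelValue`: scalar; `kernelGrad`: length-2 gradient with
#'   respect to `x`; `kernelHess`: 2 x 2 matrix of mixed second derivatives
#'   d2k / dx_i dx'_j.
#' @examples
#' sp <- kernelSpec("imq", c = 1)
#' kernelValue(c(0, 0), c(1, sqrt(2)), sp)  # (1 + 3)^(-1/2) = 0.5
#' @export
kernelValue <- function(x, x2, spec) {
  d <- as.numeric(x) - as.numeric(x2)
  .kernParts(sum(d^2), spec, order = 0L)$g0
}

#' @rdname kernelValue
#' @export
kernelGrad <- function(x, x2, spec) {
  d <- as.numeric(x) - as.numeric(x2)
  pr <- .kernParts(sum(d^2), spec, order = 1L)
  2 * pr$g1 * d
}

#' @rdname kernelValue
#' @export
kernelHess <- function(x, x2, spec) {
  d <- as.numeric(x) - as.numeric(x2)
  t <- sum(d^2)
  if (spec@family == "thin_plate" && t < 1e-300)
    stop("thin-plate second derivatives are singular at coincident points")
  pr <- .kernParts(t, spec, order = 2L)
  -2 * pr$g1 * diag(2) - 4 * pr$g2 * tcrossprod(d)
}

# g(t), g'(t), g''(t) for each family; vectorized over t
.kernParts <- function(t, spec, order = 2L) {
  a <- spec@amplitude; c2 <- spec@c^2
  out <- list(g0 = NULL, g1 = NULL, g2 = NULL)
  switch(spec@family,
    imq = {
      u <- c2 + t
      out$g0 <- a * u^(-0.5)
      if (order >= 1L) out$g1 <- -0.5 * a * u^(-1.5)
      if (order >= 2L) out$g2 <- 0.75 * a * u^(-2.5)
    },
    squared_exponential = {
      e <- a * exp(-t / (2 * c2))
      out$g0 <- e
      if (order >= 1L) out$g1 <- -e / (2 * c2)
      if (order >= 2L) out$g2 <- e / (4 * c2^2)
    },
    matern52 = {
      s5 <- sqrt(5 * t) / spec@c
      e <- exp(-s5)
      out$g0 <- a * (1 + s5 + s5^2 / 3) * e
      if (order >= 1L) out$g1 <- -(5 * a / (6 * c2)) * (1 + s5) * e
      if (order >= 2L) out$g2 <- (25 * a / (12 * c2^2)) * e
    },
    thin_plate = {
      # k = amplitude * r^2 log(r) = (amplitude/2) t log t; k(0) = 0
      lt <- ifelse(t > 0, log(t), 0)
      out$g0 <- 0.5 * a * t * lt
      if (order >= 1L) out$g1 <- ifelse(t > 0, 0.5 * a * (lt + 1), 0)
      if (order >= 2L) out$g2 <- ifelse(t > 0, 0.5 * a / t, Inf)
    },
    stop("unknown kernel family: ", spec@family)
  )
  out
}

# prior variance k(x, x)
.kernSelf <- function(spec) .kernParts(0, spec, order = 0L)$g0
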