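#' Assemble the gradient-augmented covariance matrix
#'
#' Builds the full covariance of the interleaved observation vector
#' `[E1, gx1, gy1, E2, gx2, gy2, ...]`: for every point pair the 3 x 3 block
#' combines the kernel value, its first derivatives (energy-gradient
#' cross-covariances) and the mixed second derivatives (gradient-gradient
#' covariances). For the inverse multiquadric the result is strictly
#' positive definite on distinct points, so the Cholesky factorization
#' succeeds with at most tiny jitter.
#'
#' @param xs n x 2 matrix of 2D inputs.
#' @param spec a [KernelSpec-class].
#' @param noise nonnegative variance added to the diagonal (default 0:
#'   noiseless).
#' @param useGradients `FALSE` assembles the plain energy-only covariance.
#' @return a symmetric `(D+1)n x (D+1)n` matrix (D = 2), or `n x n` when
#'   `useGradients = FALSE`.
#' @export
assembleAugmentedCovariance <- function(xs, spec, noise = 0,
                                        useGradients = TRUE) {
  xs <- .as2col(xs)
  K <- .augCross(xs, xs, spec, rowGradients = useGradients,
                 colGradients = useGradients)
  if (noise > 0) K <- K + noise * diag(nrow(K))
  K
}

.as2col <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 2L, byrow = TRUE)
  storage.mode(x) <- "double"
  x
}

# cross-covariance between observation channels of point sets A and B;
# rows: A channels (value [+ gradients]), columns: B channels
.augCross <- function(A, B, spec, rowGradients = TRUE, colGradients = TRUE) {
  na <- nrow(A); nb <- nrow(B)
  DX <- outer(A[, 1L], B[, 1L], "-")
  DY <- outer(A[, 2L], B[, 2L], "-")
  Tm <- DX^2 + DY^2
  ord <- if (rowGradients || colGradients) 2L else 0L
  pr <- .kernParts(Tm, spec, order = ord)
  K0 <- matrix(pr$g0, na, nb)
  if (!rowGradients && !colGradients) return(K0)
  G1 <- matrix(pr$g1, na, nb)
  Gx <- 2 * G1 * DX                 # d k / d a_x
  Gy <- 2 * G1 * DY
  dr <- if (rowGradients) 3L else 1L
  dc <- if (colGradients) 3L else 1L
  K <- matrix(0, dr * na, dc * nb)
  iv <- seq(1L, by = dr, length.out = na)
  jv <- seq(1L, by = dc, length.out = nb)
  K[iv, jv] <- K0
  if (rowGradients) {
    K[iv + 1L, jv] <- Gx
    K[iv + 2L, jv] <- Gy
  }
  if (colGradients) {
    K[iv, jv + 1L] <- -Gx
    K[iv, jv + 2L] <- -Gy
  }
  if (rowGradients && colGradients) {
    G2 <- matrix(pr$g2, na, nb)
    K[iv + 1L, jv + 1L] <- -2 * G1 - 4 * G2 * DX^2
    K[iv + 1L, jv + 2L] <- -4 * G2 * DX * DY
    K[iv + 2L, jv + 1L] <- -4 * G2 * DX * DY
    K[iv + 2L, jv + 2L] <- -2 * G1 - 4 * G2 * DY^2
  }
  K
}

# Cholesky with multiplicative jitter escalation 1e-10 -> 1e-6
.cholJitter <- function(K, start = 1e-10, max = 1e-6) {
  sc <- mean(diag(K))
  j <- 0
  repeat {
    U <- tryCatch(chol(K + if (j > 0) j * sc * diag(nrow(K)) else 0),
                  error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = j))
    j <- if (j == 0) start else j * 10
    if (j > max)
      stop("covariance not positive definite even with jitter ", max,
           " (conditioning error)")
  }
}

# pull coordinates (and matching gradients) out of a projected-points frame
.gpInputs <- function(points, useGradients = TRUE) {
  if (!is.null(points$s) && !is.null(points$d) && all(is.finite(points$s))) {
    x <- cbind(points$s, points$d)
    g <- if (useGradients) cbind(points$grad_s, points$grad_d)
  } else {
    x <- cbind(points$r, points$p)
    g <- if (useGradients) cbind(points$grad_r, points$grad_p)
  }
  if (useGradients && (is.null(g) || ncol(g) != 2L || anyNA(g)))
    stop("points must carry both gradient components for a gradient-",
         "augmented fit")
  list(x = x, g = g)
}

#' Rotate projected gradients into the (s, d) frame
#'
#' Gradient components transform with the same rigid rotation as the
#' coordinates; this fills `grad_s`, `grad_d` from `grad_r`, `grad_p`.
#'
#' @param points data.frame with `grad_r`, `grad_p`.
#' @param frame a [ProgressFrame-class].
#' @return `points` with `grad_s`, `grad_d` added.
#' @export
rotateGradients <- function(points, frame) {
  points$grad_s <- points$grad_r * frame@tangent[1L] +
    points$grad_p * frame@tangent[2L]
  points$grad_d <- points$grad_r * frame@normal[1L] +
    points$grad_p * frame@normal[2L]
  points
}

#' Fit the full gradient-enhanced GP
#'
#' Exact GP regression with derivative observations: factorizes
#' `K_full + noise I` and solves for the weights against the augmented
#' observation vector. Energies are centered at a reference level (by
#' default the first final-path energy, i.e. the reactant) so the prior
#' mean 0 corresponds to the reactant level far from the data.
#'
#' @param points data.frame of projected points carrying coordinates
#'   (`s`/`d` if present, else `r`/`p`), `energy`, and matching gradient
#'   columns when `useGradients` is `TRUE`.
#' @param spec a [KernelSpec-class].
#' @param noise observation noise variance (eV^2), one scale for all
#'   channels.
#' @param useGradients include derivative observations (default `TRUE`
#'   except for the thin-plate kernel, whose second derivatives are
#'   singular at coincident points).
#' @param center energy reference subtracted before fitting; default the
#'   first final-path energy (first row if no `final` column).
#' @return a fitted [GPSurfaceModel-class].
#' @export
fitFull <- function(points, spec = kernelSpec(), noise = 1e-8,
                    useGradients = spec@family != "thin_plate",
                    center = NULL) {
  inp <- .gpInputs(points, useGradients)
  if (is.null(center)) center <- .defaultCenter(points)
  y <- .augObs(points$energy - center, inp$g, useGradients)
  K <- assembleAugmentedCovariance(inp$x, spec, noise = noise,
                                   useGradients = useGradients)
  if (spec@family == "thin_plate") {
    # the r^2 log r kernel is only conditionally positive definite, so the
    # system is solved by regularized LU instead of Cholesky; no posterior
    # variance is defined for this surface type
    alpha <- solve(K + max(noise, 1e-10) * diag(nrow(K)), y)
    solver <- list(method = "full", U = NULL, alpha = alpha, jitter = 0)
  } else {
    cf <- .cholJitter(K)
    alpha <- backsolve(cf$U, backsolve(cf$U, y, transpose = TRUE))
    solver <- list(method = "full", U = cf$U, alpha = alpha,
                   jitter = cf$jitter)
  }
  new("GPSurfaceModel", kernel = spec, noise = noise, trainX = inp$x,
      yFull = y, solver = solver,
      center = center, useGradients = useGradients)
}

.defaultCenter <- function(points) {
  if (!is.null(points$final) && any(points$final))
    points$energy[which(points$final)[1L]]
  else points$energy[1L]
}

.augObs <- function(e, g, useGradients) {
  if (!useGradients) return(as.numeric(e))
  as.numeric(t(cbind(e, g)))        # interleaved [E_i, gx_i, gy_i]
}

#' Fit a Nystrom low-rank gradient-enhanced GP
#'
#' Approximates the N-point augmented covariance through M inducing points:
#' K_NN ~ K_NM K_MM^-1 K_MN. With L the Cholesky factor of K_MM + sigma^2 I
#' and V = L^-1 K_MN, the predictive weights are
#' alpha_M = L^-T (S^-1 V y_full), S = V V^T + sigma^2 I, so the dominant
#' cost is O(N M^2) rather than O(N^3). The predictive variance uses the
#' subset-of-regressors form from the same factorization.
#'
#' @inheritParams fitFull
#' @param inducing integer indices (into `points`) of the inducing set; by
#'   default chosen by [selectInducing()].
#' @param M inducing budget when `inducing` is `NULL`.
#' @return a fitted [GPSurfaceModel-class] with `solver$method = "nystrom"`.
#' @export
fitNystrom <- function(points, spec = kernelSpec(), noise = 1e-8,
                       inducing = NULL, M = 300L,
                       useGradients = spec@family != "thin_plate",
                       center = NULL) {
  inp <- .gpInputs(points, useGradients)
  if (is.null(center)) center <- .defaultCenter(points)
  if (is.null(inducing)) inducing <- selectInducing(points, M)
  inducing <- sort(unique(as.integer(inducing)))
  if (!length(inducing) || any(inducing < 1L) ||
      any(inducing > nrow(inp$x)))
    stop("inducing indices out of range")
  y <- .augObs(points$energy - center, inp$g, useGradients)
  XM <- inp$x[inducing, , drop = FALSE]
  KMM <- assembleAugmentedCovariance(XM, spec, useGradients = useGradients)
  KMN <- .augCross(XM, inp$x, spec, rowGradients = useGradients,
                   colGradients = useGradients)
  # stabilized Cholesky of K_MM (jitter only); keeping sigma^2 out of this
  # factor makes the M = N case reduce exactly to the full GP
  cf <- .cholJitter(KMM)
  U <- cf$U
  V <- backsolve(U, KMN, transpose = TRUE)    # L^-1 K_MN
  S <- tcrossprod(V) + noise * diag(nrow(V))
  cfS <- .cholJitter(S)
  z <- backsolve(cfS$U, backsolve(cfS$U, V %*% y, transpose = TRUE))
  alpha <- backsolve(U, z)                    # L^-T (S^-1 V y)
  new("GPSurfaceModel", kernel = spec, noise = noise, trainX = inp$x,
      yFull = y,
      solver = list(method = "nystrom", U = U, SU = cfS$U, alpha = alpha,
                    inducing = inducing, XM = XM),
      center = center, useGradients = useGradients)
}

#' Choose Nystrom inducing points
#'
#' All final-converged-path points, padded with evenly strided history
#' points up to the budget `M`. The final path concentrates observations
#' near the converged minimum-energy path, which is where predictive
#' accuracy matters.
#'
#' @param points projected history data.frame (column `final` marks the
#'   converged path).
#' @param M inducing budget.
#' @return sorted integer indices into `points`.
#' @export
selectInducing <- function(points, M = 300L) {
  n <- nrow(points)
  fin <- if (!is.null(points$final)) which(points$final) else integer()
  if (length(fin) >= M) return(sort(fin[seq_len(M)]))
  rest <- setdiff(seq_len(n), fin)
  extra <- min(length(rest), M - length(fin))
  if (extra > 0L)
    fin <- c(fin, rest[unique(round(seq(1L, length(rest),
                                        length.out = extra)))])
  sort(unique(fin))
}

#' Posterior prediction on the projected plane
#'
#' Posterior mean energy and pointwise standard deviation at query
#' locations, from either the full or the Nystrom factorization. The
#' standard deviation is near zero at training inputs and grows with
#' distance from the data, delineating data-supported regions from
#' extrapolation.
#'
#' @param model a fitted [GPSurfaceModel-class].
#' @param query m x 2 matrix (columns s/d or r/p as used in fitting) or a
#'   data.frame with those columns.
#' @return list with numeric vectors `mean` (eV) and `std` (eV).
#' @export
predictSurface <- function(model, query) {
  if (is.data.frame(query)) query <- .gpInputs(query, FALSE)$x
  Xs <- .as2col(query)
  sol <- model@solver
  if (is.null(sol$method)) stop("model is not fitted")
  if (sol$method == "full") {
    Ks <- .augCross(Xs, model@trainX, model@kernel, rowGradients = FALSE,
                    colGradients = model@useGradients)
    mu <- as.numeric(Ks %*% sol$alpha) + model@center
    if (is.null(sol$U)) {          # conditionally PD kernel: no variance
      var <- rep(0, length(mu))
    } else {
      W <- backsolve(sol$U, t(Ks), transpose = TRUE)
      var <- .kernSelf(model@kernel) - colSums(W^2)
    }
  } else if (sol$method == "nystrom") {
    Ks <- .augCross(Xs, sol$XM, model@kernel, rowGradients = FALSE,
                    colGradients = model@useGradients)
    mu <- as.numeric(Ks %*% sol$alpha) + model@center
    B <- backsolve(sol$U, t(Ks), transpose = TRUE)     # L^-1 k_M*
    W <- backsolve(sol$SU, B, transpose = TRUE)        # chol(S)^-T ...
    var <- model@noise * colSums(W^2)
  } else {
    stop("model is not fitted")
  }
  list(mean = mu, std = sqrt(pmax(var, 0)))
}

#' @describeIn predictSurface standard `predict` method.
#' @param object a fitted [GPSurfaceModel-class].
#' @param newdata query locations.
#' @param ... ignored.
#' @export
setMethod("predict", "GPSurfaceModel", function(object, newdata, ...) {
  predictSurface(object, newdata)
})

#' Subset hyperparameter optimization
#'
#' Maximizes the log marginal likelihood of the gradient-augmented GP on a
#' small subset (the final converged path; typically n of order 20 against
#' a full history of hundreds to thousands) over the kernel scale c, the
#' amplitude and the noise variance, in log-parameter space with bounded
#' L-BFGS-B from a fixed set of deterministic starts. The optimized scales
#' are then reused when fitting the entire surface, which both cuts the
#' cost from O(N^3) to O(n^3) and isolates hyperparameter learning from
#' transient optimization dynamics.
#'
#' @param subset data.frame of final-path projected points (with
#'   gradients).
#' @param spec starting [KernelSpec-class] (family is kept).
#' @param noise starting noise variance.
#' @param lower,upper bounds as named vectors with entries `c`, `amplitude`,
#'   `noise` (natural scale). If a bound pair collapses to a point that
#'   parameter is fixed.
#' @param useGradients include derivative observations.
#' @param center energy reference (see [fitFull()]).
#' @return list with elements `spec` (optimized [KernelSpec-class]),
#'   `noise`, and `logLik`.
#' @export
optimizeHyperparameters <- function(subset, spec = kernelSpec(),
                                    noise = 1e-4,
                                    lower = c(c = 1e-3, amplitude = 1e-4,
                                              noise = 1e-10),
                                    upper = c(c = 1e2, amplitude = 1e4,
                                              noise = 1),
                                    useGradients = spec@family != "thin_plate",
                                    center = NULL) {
  inp <- .gpInputs(subset, useGradients)
  if (is.null(center)) center <- .defaultCenter(subset)
  y <- .augObs(subset$energy - center, inp$g, useGradients)
  lo <- log(lower[c("c", "amplitude", "noise")])
  hi <- log(upper[c("c", "amplitude", "noise")])
  nll <- function(th) {
    sp <- kernelSpec(spec@family, exp(th[1L]), exp(th[2L]))
    K <- assembleAugmentedCovariance(inp$x, sp, noise = exp(th[3L]),
                                     useGradients = useGradients)
    U <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    a <- backsolve(U, backsolve(U, y, transpose = TRUE))
    v <- 0.5 * sum(y * a) + sum(log(diag(U))) +
      0.5 * length(y) * log(2 * pi)
    if (!is.finite(v)) 1e10 else v
  }
  free <- which(hi - lo >= 1e-12)      # collapsed bounds pin a parameter
  if (!length(free)) {
    return(list(spec = kernelSpec(spec@family, exp(lo[1L]), exp(lo[2L])),
                noise = unname(exp(lo[3L])), logLik = -nll(lo)))
  }
  eScale <- stats::var(subset$energy - center)
  if (!is.finite(eScale) || eScale <= 0) eScale <- 1
  starts <- list(
    pmin(pmax(c(log(spec@c), log(spec@amplitude), log(noise)), lo), hi),
    pmin(pmax(c(log(0.3), log(eScale), log(1e-6)), lo), hi),
    pmin(pmax(c(log(3), log(eScale), log(1e-3)), lo), hi),
    pmin(pmax(c(log(1), log(1), log(1e-4)), lo), hi)
  )
  nllFree <- function(thf) {
    th <- lo
    th[free] <- thf
    nll(th)
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0[free], nllFree, method = "L-BFGS-B",
                   lower = lo[free], upper = hi[free],
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(best)) {
    th <- lo
    th[free] <- best$par
    best$par <- th
  }
  if (is.null(best)) {
    warning("hyperparameter optimizer failed to converge; returning start")
    best <- list(par = starts[[1L]], value = nll(starts[[1L]]),
                 convergence = 1L)
  }
  if (!is.null(best$convergence) && best$convergence != 0)
    warning("hyperparameter optimizer did not fully converge; ",
            "returning best iterate")
  list(spec = kernelSpec(spec@family, exp(best$par[1L]), exp(best$par[2L])),
       noise = unname(exp(best$par[3L])), logLik = -best$value)
}
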