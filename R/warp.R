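## Diffeomorphic machinery: stationary-velocity fields exponentiated by
## scaling-and-squaring, Jacobian-determinant maps for tensor-based
## morphometry, pairwise registration of tissue-probability stacks by a
## log-demons scheme, groupwise population-mean construction, and pullback
## warping of quantitative maps for voxel-based quantification.

## compose displacement fields: (a o b)(x) = b(x) + a(x + b(x))
composeDisplacement <- function(a, b) {
  d <- dim(a)[1:3]
  g <- coordinateGrids(d)
  xs <- as.numeric(g$x) + as.numeric(b[, , , 1])
  ys <- as.numeric(g$y) + as.numeric(b[, , , 2])
  zs <- as.numeric(g$z) + as.numeric(b[, , , 3])
  out <- b
  for (c3 in 1:3)
    out[, , , c3] <- b[, , , c3] +
      array(interpTrilinear(a[, , , c3], xs, ys, zs), d)
  out
}

## Jacobian determinant of x -> x + phi(x); central differences inside,
## one-sided at the faces.
jacobianFromDisplacement <- function(phi) {
  d <- dim(phi)[1:3]
  J <- vector("list", 9L)
  idx <- 1L
  for (comp in 1:3) {
    g <- volumeGradient(phi[, , , comp])
    J[[idx]] <- g$gx; J[[idx + 1L]] <- g$gy; J[[idx + 2L]] <- g$gz
    idx <- idx + 3L
  }
  ## determinant of I + dphi/dx
  a11 <- 1 + J[[1]]; a12 <- J[[2]]; a13 <- J[[3]]
  a21 <- J[[4]]; a22 <- 1 + J[[5]]; a23 <- J[[6]]
  a31 <- J[[7]]; a32 <- J[[8]]; a33 <- 1 + J[[9]]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Exponentiate a stationary velocity field (scaling and squaring)
#'
#' Computes the diffeomorphism `phi = exp(v)` by halving the velocity
#' `steps` times and self-composing the resulting small displacement with
#' trilinear interpolation. The per-voxel Jacobian determinant is computed by
#' central differences of the final mapping; non-positive Jacobians anywhere
#' cause an error (the velocity is too large for the step count).
#'
#' @param v 4-D array (x, y, z, component) of velocities, voxel units.
#' @param steps number of squaring steps (>= 4).
#' @param voxelSize voxel edge length, mm.
#' @return a [DeformationField-class].
#' @export
integrateVelocity <- function(v, steps = 6, voxelSize = 1) {
  stopifnot(length(dim(v)) == 4L, dim(v)[4] == 3L)
  if (steps < 4) stop("steps must be >= 4")
  phi <- v / 2^steps
  for (i in seq_len(steps)) phi <- composeDisplacement(phi, phi)
  jac <- jacobianFromDisplacement(phi)
  if (any(jac <= 0))
    stop(sprintf("non-diffeomorphic field: min Jacobian %.4f (velocity too large for %d steps)",
                 min(jac), steps))
  new("DeformationField", phi = phi, jac = jac, voxelSize = voxelSize)
}

#' Warp a quantitative map by pullback resampling
#'
#' Samples the input at `x + phi(x)` with trilinear interpolation. Voxels
#' mapping outside the field of view are set to `NA`. No smoothing is applied.
#'
#' @param qmap 3-D array.
#' @param phi a [DeformationField-class] or a raw 4-D displacement array.
#' @param interpolation only `"trilinear"` is provided.
#' @return warped 3-D array, same grid.
#' @export
warpQMap <- function(qmap, phi, interpolation = "trilinear") {
  interpolation <- match.arg(interpolation, "trilinear")
  disp <- if (is(phi, "DeformationField")) phi@phi else phi
  d <- dim(qmap)
  if (!identical(dim(disp)[1:3], d)) stop("grid mismatch between map and deformation")
  g <- coordinateGrids(d)
  xs <- as.numeric(g$x) + as.numeric(disp[, , , 1])
  ys <- as.numeric(g$y) + as.numeric(disp[, , , 2])
  zs <- as.numeric(g$z) + as.numeric(disp[, , , 3])
  array(interpTrilinear(qmap, xs, ys, zs, mode = "fill", fill = NA_real_), d)
}

## SSD objective of a warped probability stack vs the fixed stack
ssdObjective <- function(moving, fixed, disp) {
  K <- dim(moving)[4]
  s <- 0
  for (k in seq_len(K)) {
    w <- warpQMap(moving[, , , k], disp)
    s <- s + sum((fixed[, , , k] - w)^2, na.rm = TRUE)
  }
  s
}

resizeVelocity <- function(v, newDim) {
  oldDim <- dim(v)[1:3]
  g <- coordinateGrids(newDim)
  out <- array(0, c(newDim, 3L))
  sc <- (oldDim - 1) / pmax(newDim - 1, 1L)
  xs <- 1 + (as.numeric(g$x) - 1) * sc[1]
  ys <- 1 + (as.numeric(g$y) - 1) * sc[2]
  zs <- 1 + (as.numeric(g$z) - 1) * sc[3]
  for (c3 in 1:3)
    out[, , , c3] <- array(interpTrilinear(v[, , , c3], xs, ys, zs), newDim) / sc[c3]
  out
}

#' Register one tissue-probability stack to another
#'
#' Stationary-velocity log-demons: minimizes the multi-class sum of squared
#' differences between the warped moving stack and the fixed stack with
#' Gaussian fluid/elastic regularization of the velocity, by multi-resolution
#' alternation of force computation and smoothing. The objective is
#' non-increasing over accepted steps; ten consecutive rejected steps stop a
#' level.
#'
#' @param moving,fixed 4-D arrays (x, y, z, class) on one grid.
#' @param levels number of resolution levels (coarsest first).
#' @param itersPerLevel gradient iterations per level.
#' @param fluidSigma Gaussian sigma (voxels) smoothing the update force.
#' @param elasticSigma Gaussian sigma (voxels) smoothing the velocity.
#' @param step initial step length (voxels per unit force).
#' @return 4-D velocity array with attribute `objective` (a list of
#'   objective traces, one per resolution level, coarsest first).
#' @export
registerPair <- function(moving, fixed, levels = 3, itersPerLevel = 12,
                         fluidSigma = 2, elasticSigma = 1.2, step = NULL) {
  stopifnot(identical(dim(moving), dim(fixed)))
  K <- dim(moving)[4]
  pyramid <- list(list(m = moving, f = fixed))
  for (l in seq_len(levels - 1L)) {
    prev <- pyramid[[l]]
    dn <- function(stack) {
      d0 <- pmax(dim(stack)[1:3] %/% 2L, 1L)
      out <- array(0, c(d0, K))
      for (k in seq_len(K)) out[, , , k] <- downsampleVolume(stack[, , , k])
      out
    }
    pyramid[[l + 1L]] <- list(m = dn(prev$m), f = dn(prev$f))
  }
  v <- NULL
  traces <- list()
  for (l in rev(seq_len(levels))) {
    m <- pyramid[[l]]$m; f <- pyramid[[l]]$f
    d <- dim(m)[1:3]
    v <- if (is.null(v)) array(0, c(d, 3L)) else resizeVelocity(v, d)
    stepL <- if (is.null(step)) 2.0 else step
    phi <- integrateVelocity(v, steps = 6)@phi
    obj <- ssdObjective(m, f, phi)
    fails <- 0L
    trace <- obj
    for (it in seq_len(itersPerLevel)) {
      ## demons force: sum_k (f_k - m_k o phi) * grad(m_k o phi)
      force <- array(0, c(d, 3L))
      for (k in seq_len(K)) {
        w <- warpQMap(m[, , , k], phi)
        w[is.na(w)] <- 0
        err <- f[, , , k] - w
        gr <- volumeGradient(w)
        force[, , , 1] <- force[, , , 1] + err * gr$gx
        force[, , , 2] <- force[, , , 2] + err * gr$gy
        force[, , , 3] <- force[, , , 3] + err * gr$gz
      }
      for (c3 in 1:3) force[, , , c3] <- smoothGaussianFFT(force[, , , c3], fluidSigma)
      nrm <- max(sqrt(sumOverClasses(force^2)))
      if (nrm < 1e-12) break
      accepted <- FALSE
      while (fails < 10L) {
        vTry <- v + stepL / nrm * force
        for (c3 in 1:3) vTry[, , , c3] <- smoothGaussianFFT(vTry[, , , c3], elasticSigma)
        ## cap the per-step displacement so exp stays diffeomorphic
        phiTry <- tryCatch(integrateVelocity(vTry, steps = 6)@phi, error = function(e) NULL)
        objTry <- if (is.null(phiTry)) Inf else ssdObjective(m, f, phiTry)
        if (objTry < obj) {
          v <- vTry; phi <- phiTry; obj <- objTry
          stepL <- stepL * 1.1
          accepted <- TRUE
          break
        }
        stepL <- stepL / 2
        fails <- fails + 1L
      }
      trace <- c(trace, obj)
      if (!accepted) break
    }
    traces[[length(traces) + 1L]] <- trace
  }
  attr(v, "objective") <- traces
  v
}

#' Groupwise population mean of tissue-probability stacks
#'
#' Alternates registration of every subject to the current mean with
#' voxelwise averaging (and renormalization) of the warped stacks. Velocities
#' are centered across subjects at every round so the mean log-Jacobian stays
#' near zero (drift control).
#'
#' @param stacks list of 4-D tissue-probability arrays on one grid.
#' @param iters number of register/average rounds.
#' @param ... passed to [registerPair()].
#' @return list with `mean` (4-D stack summing to 1 per voxel),
#'   `deformations` (per-subject [DeformationField-class], subject to mean)
#'   and `velocities`.
#' @export
buildPopulationMean <- function(stacks, iters = 3, ...) {
  n <- length(stacks)
  if (n < 2) stop("at least 2 subjects required")
  d <- dim(stacks[[1]])[1:3]; K <- dim(stacks[[1]])[4]
  renorm <- function(stack) {
    stack <- pmax(stack, 1e-12)
    s <- sumOverClasses(stack)
    for (k in seq_len(K)) stack[, , , k] <- stack[, , , k] / s
    stack
  }
  mean0 <- renorm(Reduce(`+`, stacks) / n)
  vels <- replicate(n, array(0, c(d, 3L)), simplify = FALSE)
  for (round in seq_len(iters)) {
    for (i in seq_len(n)) {
      vi <- tryCatch(registerPair(stacks[[i]], mean0, ...),
                     error = function(e)
                       stop(sprintf("registration failed for subject %d: %s", i, conditionMessage(e))))
      vels[[i]] <- vi
    }
    vbar <- Reduce(`+`, vels) / n                  # center: remove common drift
    vels <- lapply(vels, function(v) v - vbar)
    acc <- array(0, c(d, K))
    for (i in seq_len(n)) {
      phiI <- integrateVelocity(vels[[i]], steps = 6)@phi
      for (k in seq_len(K)) {
        w <- warpQMap(stacks[[i]][, , , k], phiI)
        w[is.na(w)] <- 0
        acc[, , , k] <- acc[, , , k] + w
      }
    }
    mean0 <- renorm(acc / n)
  }
  defs <- lapply(vels, integrateVelocity, steps = 6)
  list(mean = mean0, deformations = defs, velocities = vels)
}
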