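## Population tissue-template learning: multivariate Gaussian mixture over
## image channels with spatially varying priors (tissue probability maps),
## fit by Expectation-Maximization across spatially aligned subjects.

#' Restrict a volume to a brainstem mask
#'
#' Sets voxels outside the mask to `NA` and reports the bookkeeping.
#'
#' @param volume 3-D array.
#' @param mask logical 3-D mask on the same grid (non-empty).
#' @return the masked volume with attribute `nMasked` (voxels set missing).
#' @export
extractBrainstem <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) stop("mask grid mismatch")
  if (!any(mask)) stop("empty mask")
  volume[!mask] <- NA_real_
  attr(volume, "nMasked") <- sum(!mask)
  volume
}

## Gaussian log density for a data matrix (V x C) under one class
classLogDensity <- function(x, mean, cov) {
  C <- length(mean)
  ch <- chol(cov)
  xc <- sweep(x, 2L, mean)
  q <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(q^2) - sum(log(diag(ch))) - 0.5 * C * log(2 * pi)
}

#' E-step: class responsibilities under spatially varying priors
#'
#' Computes `gamma_k(v) = pi_k(v) N(x(v); mu_k, Sigma_k) / sum_j ...` with
#' log-sum-exp stabilization, and the observed-data log-likelihood
#' `sum_v log sum_k pi_k(v) N(x(v); mu_k, Sigma_k)`.
#'
#' @param data V x C matrix of channel values (complete cases).
#' @param means K x C class means.
#' @param covariances C x C x K class covariances.
#' @param priors V x K voxelwise priors (rows summing to 1); a length-K
#'   vector is recycled as a stationary prior.
#' @return list with `resp` (V x K), `logLik`, and `voxelLogLik` (the
#'   per-voxel log marginal densities).
#' @export
eStep <- function(data, means, covariances, priors) {
  K <- nrow(means)
  V <- nrow(data)
  if (is.null(dim(priors))) priors <- matrix(priors, V, K, byrow = TRUE)
  lg <- matrix(0, V, K)
  for (k in seq_len(K))
    lg[, k] <- log(pmax(priors[, k], 1e-300)) +
      classLogDensity(data, means[k, ], covariances[, , k])
  lse <- logSumExpRows(lg)
  resp <- exp(lg - lse)
  list(resp = resp, logLik = sum(lse), voxelLogLik = lse)
}

#' M-step: update class means, covariances and mixing weights
#'
#' Weighted maximum-likelihood updates with an eigenvalue floor on each
#' covariance (`floorFrac` times the mean channel variance) to prevent
#' degeneracy. Empty classes (total responsibility < `1e-8`) keep their mean
#' and receive an inflated covariance, with a warning.
#'
#' @param data V x C matrix.
#' @param resp V x K responsibility matrix.
#' @param floorFrac covariance eigenvalue floor as a fraction of the mean
#'   channel variance.
#' @param covariance `"full"` (one covariance per class) or `"tied"` (one
#'   pooled covariance shared by all classes; symmetric class boundaries,
#'   robust to partial-volume halos).
#' @param weights optional per-voxel weights (fractional voxel replication;
#'   used for partial-volume-aware estimation).
#' @return list with `means`, `covariances`, `mixing`.
#' @export
mStep <- function(data, resp, floorFrac = 1e-6, covariance = c("full", "tied"),
                  weights = NULL) {
  covariance <- match.arg(covariance)
  if (!is.null(weights)) resp <- resp * weights
  K <- ncol(resp); C <- ncol(data)
  nk <- colSums(resp)
  chanVar <- mean(apply(data, 2L, stats::var))
  floorVal <- max(floorFrac * chanVar, 1e-12)
  means <- matrix(0, K, C)
  covs <- array(0, c(C, C, K))
  for (k in seq_len(K)) {
    if (nk[k] < 1e-8) {
      warning(sprintf("class %d empty; covariance inflated", k))
      means[k, ] <- colMeans(data)
      covs[, , k] <- diag(C) * chanVar * 10
      next
    }
    mu <- colSums(resp[, k] * data) / nk[k]
    xc <- sweep(data, 2L, mu)
    S <- crossprod(xc * sqrt(resp[, k])) / nk[k]
    eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
    ev <- pmax(eig$values, floorVal)
    means[k, ] <- mu
    covs[, , k] <- eig$vectors %*% (ev * t(eig$vectors))
  }
  if (covariance == "tied") {
    pooledS <- matrix(0, C, C)
    for (k in seq_len(K)) {
      xc <- sweep(data, 2L, means[k, ])
      pooledS <- pooledS + crossprod(xc * sqrt(resp[, k]))
    }
    pooledS <- pooledS / sum(nk)
    eig <- eigen((pooledS + t(pooledS)) / 2, symmetric = TRUE)
    ev <- pmax(eig$values, floorVal)
    pooledS <- eig$vectors %*% (ev * t(eig$vectors))
    for (k in seq_len(K)) covs[, , k] <- pooledS
  }
  list(means = means, covariances = covs, mixing = nk / sum(nk))
}

#' Update the spatially varying priors from aligned responsibilities
#'
#' Dirichlet-regularized average of the per-subject posteriors on the common
#' grid: `pi_k(v) = (sum_s gamma_sk(v) + alpha) / (S + K alpha)`, followed by
#' optional spatial smoothing and renormalization.
#'
#' @param respList list of V x K responsibility matrices (aligned subjects).
#' @param alpha Dirichlet pseudocount per class (floor; > 0).
#' @param smoothing optional Gaussian sigma (voxels) applied to the prior
#'   field; requires `gridDim`.
#' @param gridDim grid shape, needed only when `smoothing > 0`.
#' @return V x K prior matrix, rows summing to 1.
#' @export
updateTPMs <- function(respList, alpha = 1e-4, smoothing = 0, gridDim = NULL) {
  S <- length(respList)
  if (S == 1L) warning("single subject: priors degenerate to that subject's posterior")
  acc <- Reduce(`+`, respList)
  pri <- (acc + alpha) / (S + ncol(acc) * alpha)
  if (smoothing > 0) {
    stopifnot(!is.null(gridDim))
    for (k in seq_len(ncol(pri)))
      pri[, k] <- as.numeric(smoothGaussianFFT(array(pri[, k], gridDim), smoothing))
    pri <- pmax(pri, 1e-12)
  }
  pri / rowSums(pri)
}

#' Fit the mixture and population priors by Expectation-Maximization
#'
#' Alternates the E-step per subject, a pooled M-step over all subjects, and
#' the prior-field update, until the relative change of the objective falls
#' below `tol` or `maxIter` is reached. The reported objective is the MAP
#' objective (observed-data log-likelihood plus the Dirichlet prior term on
#' the spatial priors); it is non-decreasing across iterations.
#'
#' @param dataList list of V x C matrices, one per subject, on one voxel grid
#'   (complete cases; use one common mask).
#' @param K number of classes.
#' @param priors optional initial V x K prior field (e.g. ground-truth or
#'   uniform); defaults to uniform.
#' @param init `"kmeans"` (pooled, seeded), `"priors"` (prior-weighted means
#'   and scatters; anchors classes to the supplied prior field), or a list
#'   with `means`, `covariances`, `mixing`.
#' @param maxIter,tol convergence controls (relative objective change).
#' @param alpha Dirichlet pseudocount for the prior update.
#' @param updatePriors learn the spatially varying priors (`TRUE`) or keep
#'   the supplied field fixed.
#' @param seed RNG seed for the k-means initialization.
#' @param covariance covariance structure passed to [mStep()]; `"tied"` is
#'   recommended for segmentation of soft-boundary data.
#' @param voxelWeights optional length-V weights (e.g. [priorConfidence()]);
#'   voxels enter the objective and the M-step fractionally, which keeps the
#'   reported trace a proper (weighted) EM objective.
#' @return list with `model` (a [MixtureModel-class] without grid attached),
#'   `responsibilities` (per subject), `priors` (V x K), `logLikTrace`,
#'   `iterations`.
#' @export
fitEM <- function(dataList, K, priors = NULL, init = "kmeans",
                  maxIter = 200, tol = 1e-6, alpha = 1e-4,
                  updatePriors = TRUE, seed = 1,
                  covariance = c("full", "tied"), voxelWeights = NULL) {
  covariance <- match.arg(covariance)
  S <- length(dataList)
  V <- nrow(dataList[[1]])
  C <- ncol(dataList[[1]])
  if (is.null(priors)) priors <- matrix(1 / K, V, K)
  if (is.character(init) && init == "priors") {
    ## anchor each class to the prior field: prior-weighted moments
    C <- ncol(dataList[[1]])
    means <- matrix(0, K, C)
    covs <- array(0, c(C, C, K))
    pooled <- do.call(rbind, dataList)
    priRep <- do.call(rbind, replicate(S, priors, simplify = FALSE))
    chanVar <- mean(apply(pooled, 2L, stats::var))
    for (k in seq_len(K)) {
      wk <- priRep[, k]
      means[k, ] <- colSums(wk * pooled) / sum(wk)
      xc <- sweep(pooled, 2L, means[k, ])
      Sm <- crossprod(xc * sqrt(wk)) / sum(wk)
      covs[, , k] <- Sm + diag(C) * 1e-6 * chanVar
    }
    mixing <- colSums(priRep) / sum(priRep)
  } else if (is.character(init) && init == "kmeans") {
    set.seed(seed)
    pooled <- do.call(rbind, dataList)
    if (nrow(pooled) > 20000) pooled <- pooled[sample(nrow(pooled), 20000), , drop = FALSE]
    km <- stats::kmeans(pooled, centers = K, nstart = 3, iter.max = 50)
    ord <- order(km$centers[, 1])
    means <- km$centers[ord, , drop = FALSE]
    covs <- array(0, c(C, C, K))
    for (k in seq_len(K)) {
      sel <- km$cluster == ord[k]
      covs[, , k] <- if (sum(sel) > C) stats::cov(pooled[sel, , drop = FALSE]) else diag(C)
      covs[, , k] <- covs[, , k] + diag(C) * 1e-6 * mean(diag(covs[, , k]) + 1)
    }
    mixing <- rep(1 / K, K)
  } else {
    means <- init$means; covs <- init$covariances
    mixing <- if (!is.null(init$mixing)) init$mixing else rep(1 / K, K)
  }
  dirichletTerm <- function(pri) alpha * sum(log(pmax(pri, 1e-300)))
  trace <- numeric(0)
  respList <- NULL
  for (it in seq_len(maxIter)) {
    ll <- 0
    respList <- vector("list", S)
    for (s in seq_len(S)) {
      es <- eStep(dataList[[s]], means, covs, priors)
      respList[[s]] <- es$resp
      ll <- ll + if (is.null(voxelWeights)) es$logLik else
        sum(voxelWeights * es$voxelLogLik)
    }
    obj <- ll + dirichletTerm(priors)
    if (!is.finite(obj)) stop("non-finite log-likelihood; aborting EM")
    trace <- c(trace, obj)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1e-12)) break
    pooledResp <- do.call(rbind, respList)
    pooledData <- do.call(rbind, dataList)
    ms <- mStep(pooledData, pooledResp, covariance = covariance,
                weights = if (is.null(voxelWeights)) NULL else
                  rep(voxelWeights, S))
    means <- ms$means; covs <- ms$covariances; mixing <- ms$mixing
    if (updatePriors) priors <- updateTPMs(respList, alpha = alpha)
  }
  model <- new("MixtureModel", means = means, covariances = covs,
               mixing = mixing, tpm = array(1, c(1, 1, 1, 1)),
               channels = colnames(dataList[[1]]) %||% paste0("ch", seq_len(C)))
  list(model = model, responsibilities = respList, priors = priors,
       logLikTrace = trace, iterations = length(trace))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxel confidence from a spatial prior field
#'
#' Linear ramp of the prior purity: 0 where the largest class prior is 1/2
#' (fully ambiguous) and 1 where a single class has all the mass. Used to
#' down-weight partial-volume voxels in the M-step so that class parameters
#' are estimated from representative tissue.
#'
#' @param priors V x K prior matrix (rows summing to 1).
#' @return numeric vector of weights in [0, 1].
#' @export
priorConfidence <- function(priors) {
  pmax(2 * do.call(pmax, as.data.frame(priors)) - 1, 0)
}

#' Hard segmentation from responsibilities
#'
#' @param resp V x K responsibility matrix.
#' @return integer vector of argmax labels.
#' @export
hardLabels <- function(resp) max.col(resp, ties.method = "first")

#' Dice coefficient per class between two hard labelings
#'
#' @param labels,truth integer vectors of equal length.
#' @param K number of classes.
#' @return numeric vector of per-class Dice coefficients.
#' @export
diceCoefficient <- function(labels, truth, K = max(truth)) {
  vapply(seq_len(K), function(k) {
    a <- labels == k; b <- truth == k
    denom <- sum(a) + sum(b)
    if (denom == 0) return(NA_real_)
    2 * sum(a & b) / denom
  }, numeric(1))
}

#' Merge brainstem priors with whole-volume background classes
#'
#' Inside the brainstem mask the brainstem classes are scaled by
#' `1 - background mass`; outside they are zero. The merged field has
#' `K + B` classes and sums to 1 at every voxel; mass conflicts (> 1) are
#' renormalized and the maximum violation reported.
#'
#' @param brainstemTpm 4-D (x, y, z, K) prior field (sums to 1 in mask).
#' @param backgroundTpm 4-D (x, y, z, B) background priors covering the
#'   complement of the mask.
#' @param mask logical 3-D brainstem mask.
#' @return 4-D merged field (x, y, z, K + B) with attribute `maxViolation`.
#' @export
mergeTPMs <- function(brainstemTpm, backgroundTpm, mask) {
  d <- dim(brainstemTpm)[1:3]
  K <- dim(brainstemTpm)[4]; B <- dim(backgroundTpm)[4]
  stopifnot(identical(dim(backgroundTpm)[1:3], d), identical(dim(mask), d))
  bgMass <- sumOverClasses(backgroundTpm)
  out <- array(0, c(d, K + B))
  scale <- pmax(1 - bgMass, 0)
  for (k in seq_len(K))
    out[, , , k] <- brainstemTpm[, , , k] * scale * mask
  for (b in seq_len(B))
    out[, , , K + b] <- backgroundTpm[, , , b]
  s <- sumOverClasses(out)
  maxViolation <- max(abs(s - 1))
  s[s <= 0] <- 1
  for (j in seq_len(K + B)) out[, , , j] <- out[, , , j] / s
  attr(out, "maxViolation") <- maxViolation
  out
}

#' Segment the phantom cohort and learn population priors
#'
#' Convenience wrapper for the full tissue-model stage on simulated subjects:
#' builds the channel matrices (MT saturation and PDw mean by default) inside
#' the common mask and runs [fitEM()].
#'
#' @param qmapsList list of [QMaps-class] objects on one grid.
#' @param pdwMeans list of matching averaged PDw volumes.
#' @param mask common logical mask.
#' @param K classes.
#' @param priors optional V x K spatial prior field; when given, class
#'   parameters are estimated with [priorConfidence()] voxel weights.
#' @param covariance covariance structure (tied by default for segmentation).
#' @param ... passed to [fitEM()].
#' @return the [fitEM()] result plus `mask` and `gridDim`.
#' @export
segmentCohort <- function(qmapsList, pdwMeans, mask, K = 7, priors = NULL,
                          covariance = "tied", ...) {
  sel <- which(mask)
  dataList <- lapply(seq_along(qmapsList), function(i) {
    m <- cbind(MTsat = qmapsList[[i]]@MTsat[sel], PDw = pdwMeans[[i]][sel])
    m[!is.finite(m)] <- 0
    m
  })
  vw <- if (is.null(priors)) NULL else priorConfidence(priors)
  fit <- fitEM(dataList, K = K, priors = priors, covariance = covariance,
               voxelWeights = vw, ...)
  fit$mask <- mask
  fit$gridDim <- dim(mask)
  fit
}
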