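## Voxel-wise general linear model on Jacobian (TBM) and warped quantitative
## maps (VBQ), residual-based random-field smoothness estimation, and
## cluster-level family-wise-error inference by Gaussian-random-field
## approximations within regions of interest.

#' Build a design matrix with nuisance covariates
#'
#' One column for the effect of interest (group indicator or clinical score),
#' an intercept, and the nuisance covariates age, total intracranial volume
#' and scanner. The returned contrast selects the effect column.
#'
#' @param effect numeric vector (group coded 0/1, or a clinical score).
#' @param covariates data.frame with columns `age`, `tiv`, `scanner` (any
#'   subset; missing ones are skipped).
#' @param direction `+1` tests positive effect, `-1` negative.
#' @return list with `X` (n x p, full column rank), `contrast`.
#' @export
buildDesign <- function(effect, covariates = NULL, direction = -1) {
  X <- cbind(intercept = 1, effect = effect)
  if (!is.null(covariates))
    for (nm in intersect(c("age", "tiv", "scanner"), names(covariates)))
      X <- cbind(X, stats::setNames(data.frame(covariates[[nm]]), nm))
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank-deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  ctr <- rep(0, ncol(X)); ctr[2] <- direction
  list(X = X, contrast = ctr)
}

#' Voxel-wise GLM t-statistics
#'
#' Ordinary least squares at every voxel with a single contrast:
#' `t = c'beta / sqrt(sigma2 c'(X'X)^-1 c)`, the Z-equivalent obtained by
#' tail-symmetric probability mapping of the t CDF, and the residual matrix
#' returned for smoothness estimation. Subjects with missing observations
#' must be removed beforehand (listwise).
#'
#' @param Y n x V observation matrix (subjects in rows).
#' @param X n x p design matrix.
#' @param contrast length-p contrast vector.
#' @return list with `t`, `z` (length V), `df`, `beta`, `residuals` (n x V).
#' @export
fitGLM <- function(Y, X, contrast) {
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("Y and X disagree on the number of subjects")
  if (length(contrast) != p) stop("contrast length must equal ncol(X)")
  if (qr(X)$rank < p) stop("design matrix rank-deficient")
  xtxInv <- chol2inv(chol(crossprod(X)))
  beta <- xtxInv %*% crossprod(X, Y)
  fitted <- X %*% beta
  res <- Y - fitted
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(pmax(sigma2, 0) * drop(t(contrast) %*% xtxInv %*% contrast))
  tval <- drop(contrast %*% beta) / se
  tval[se == 0] <- 0
  list(t = tval, z = tToZ(tval, df), df = df, beta = beta, residuals = res)
}

#' Convert t-statistics to Z-equivalents
#'
#' Tail-symmetric probability mapping `z = Phi^-1(F_t(t))` computed in log
#' space so large |t| stay finite.
#'
#' @param t numeric vector of t values.
#' @param df error degrees of freedom (`Inf` leaves the values unchanged).
#' @return numeric vector of Z scores.
#' @export
tToZ <- function(t, df) {
  if (!is.finite(df)) return(t)
  lo <- stats::pt(-abs(t), df, log.p = TRUE)
  z <- -stats::qnorm(lo, log.p = TRUE)
  sign(t) * z
}

#' Random-field smoothness from GLM residuals
#'
#' Per-axis FWHM from the variance of spatial first differences of the
#' voxel-normalized residual images, with an exact solve of the Gaussian
#' autocorrelation model and a one-voxel-squared lattice-sampling correction
#' added in quadrature (so unsmoothed white noise reports about one voxel).
#'
#' @param residuals n x V matrix of residual images (n >= 3), or a list of
#'   3-D arrays.
#' @param mask logical 3-D mask locating the V voxels.
#' @return list of class `smoothnessEstimate` with `fwhm` (voxels, per axis)
#'   and `lambda` (difference variances).
#' @export
estimateSmoothness <- function(residuals, mask) {
  d <- dim(mask)
  if (is.list(residuals))
    residuals <- t(vapply(residuals, function(a) a[mask], numeric(sum(mask))))
  n <- nrow(residuals)
  if (n < 3) stop("at least 3 residual images required")
  ssq <- colSums(residuals^2)
  if (any(ssq < 1e-12 * n)) stop("degenerate residuals (near-zero variance)")
  U <- sweep(residuals, 2L, sqrt(ssq), "/")
  sel <- which(mask)
  coordOf <- arrayInd(sel, d)
  lin <- array(0L, d); lin[sel] <- seq_along(sel)
  lambda <- numeric(3)
  for (axis in 1:3) {
    nb <- coordOf
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= d[axis]
    nbLin <- lin[nb[ok, , drop = FALSE]]
    here <- which(ok)[nbLin > 0]
    there <- nbLin[nbLin > 0]
    if (length(here) < 10) stop("mask too thin along axis ", axis)
    dif <- U[, there, drop = FALSE] - U[, here, drop = FALSE]
    lambda[axis] <- sum(dif^2) / length(there)
  }
  rho <- pmin(pmax(1 - lambda / 2, 1e-6), 1 - 1e-6)
  sigma2 <- -1 / (4 * log(rho))
  fwhm <- sqrt(8 * log(2) * sigma2 + 1)            # +1: lattice sampling width
  structure(list(fwhm = fwhm, lambda = lambda), class = "smoothnessEstimate")
}

#' Resel counts of a region of interest
#'
#' Lattice resel counts (Worsley-style): vertices, edges, faces and cubes of
#' the mask lattice scaled by the per-axis FWHM.
#'
#' @param mask logical 3-D ROI mask.
#' @param fwhm per-axis FWHM in voxels (scalar recycled).
#' @return numeric length-4 vector `R0..R3`.
#' @export
reselCounts <- function(mask, fwhm) {
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3)
  d <- dim(mask)
  m <- array(FALSE, d + 1L)
  m[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
  sh <- function(dx, dy, dz)
    m[seq_len(d[1]) + dx, seq_len(d[2]) + dy, seq_len(d[3]) + dz]
  P <- sum(mask)
  Ex <- sum(mask & sh(1, 0, 0)); Ey <- sum(mask & sh(0, 1, 0)); Ez <- sum(mask & sh(0, 0, 1))
  Fxy <- sum(mask & sh(1, 0, 0) & sh(0, 1, 0) & sh(1, 1, 0))
  Fxz <- sum(mask & sh(1, 0, 0) & sh(0, 0, 1) & sh(1, 0, 1))
  Fyz <- sum(mask & sh(0, 1, 0) & sh(0, 0, 1) & sh(0, 1, 1))
  C <- sum(mask & sh(1, 0, 0) & sh(0, 1, 0) & sh(0, 0, 1) &
           sh(1, 1, 0) & sh(1, 0, 1) & sh(0, 1, 1) & sh(1, 1, 1))
  fx <- fwhm[1]; fy <- fwhm[2]; fz <- fwhm[3]
  c(R0 = P - Ex - Ey - Ez + Fxy + Fxz + Fyz - C,
    R1 = (Ex - Fxy - Fxz + C) / fx + (Ey - Fxy - Fyz + C) / fy +
         (Ez - Fxz - Fyz + C) / fz,
    R2 = (Fxy - C) / (fx * fy) + (Fxz - C) / (fx * fz) + (Fyz - C) / (fy * fz),
    R3 = C / (fx * fy * fz))
}

## Euler-characteristic densities of a t field (Gaussian when df = Inf)
ecDensities <- function(u, df) {
  l2 <- sqrt(4 * log(2))
  if (!is.finite(df)) {
    e <- exp(-u^2 / 2)
    return(c(stats::pnorm(u, lower.tail = FALSE),
             l2 / (2 * pi) * e,
             l2^2 / (2 * pi)^1.5 * u * e,
             l2^3 / (2 * pi)^2 * (u^2 - 1) * e))
  }
  base <- (1 + u^2 / df)^(-(df - 1) / 2)
  c(stats::pt(u, df, lower.tail = FALSE),
    l2 / (2 * pi) * base,
    l2^2 / (2 * pi)^1.5 *
      exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) * u * base,
    l2^3 / (2 * pi)^2 * ((df - 1) / df * u^2 - 1) * base)
}

## 26-connectivity components of a logical 3-D array; returns a list of
## voxel-index vectors. Works on the supra-threshold set only, which is tiny
## at a 0.001 cluster-defining threshold.
connectedComponents26 <- function(supra) {
  d <- dim(supra)
  sel <- which(supra)
  if (!length(sel)) return(list())
  lab <- array(0L, d); lab[sel] <- seq_along(sel)
  comp <- integer(length(sel))
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  coords <- arrayInd(sel, d)
  cur <- 0L
  for (i in seq_along(sel)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      cj <- coords[j, ]
      for (r in seq_len(nrow(nb))) {
        p <- cj + nb[r, ]
        if (any(p < 1L) || any(p > d)) next
        id <- lab[p[1], p[2], p[3]]
        if (id > 0L && comp[id] == 0L) {
          comp[id] <- cur
          queue <- c(queue, id)
        }
      }
    }
  }
  split(sel, comp)
}

#' Cluster-level family-wise-error inference within a region of interest
#'
#' Thresholds the t map at the upper-tail `cdtP` quantile, extracts
#' 26-connected supra-threshold clusters, and assigns each a family-wise
#' error corrected p value from the Gaussian-random-field approximation:
#' the expected cluster count is the expected Euler characteristic over the
#' ROI resel counts, the cluster-extent tail follows
#' `P(n >= k) = exp(-beta k^(2/3))` matched to the expected cluster size, and
#' `p_FWE = 1 - exp(-E[m] P(n >= k))`.
#'
#' @param stat 3-D t (or Z, with `df = Inf`) map.
#' @param df error degrees of freedom.
#' @param roi logical 3-D region-of-interest mask.
#' @param fwhm smoothness (per-axis FWHM in voxels) from
#'   [estimateSmoothness()] or known by construction.
#' @param cdtP cluster-defining threshold as an upper-tail probability.
#' @param alpha FWE significance level used for the `significant` flag.
#' @param voxelSize voxel edge length in mm (for peak coordinates).
#' @param origin grid origin in mm (defaults to the grid center).
#' @param allClusters return all clusters (`TRUE`) or only significant ones.
#' @return data.frame with one row per cluster: `p_fwe`, `extent_vox`,
#'   `z_peak`, `x_mm`, `y_mm`, `z_mm`, `significant`.
#' @export
clusterInference <- function(stat, df, roi, fwhm, cdtP = 0.001, alpha = 0.05,
                             voxelSize = 1, origin = NULL, allClusters = FALSE) {
  d <- dim(stat)
  stopifnot(identical(dim(roi), d))
  if (is.list(fwhm)) fwhm <- fwhm$fwhm
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3)
  if (any(fwhm <= 0)) stop("invalid smoothness for ROI")
  u <- if (is.finite(df)) stats::qt(cdtP, df, lower.tail = FALSE)
       else stats::qnorm(cdtP, lower.tail = FALSE)
  supra <- roi & is.finite(stat) & stat > u
  empty <- data.frame(p_fwe = numeric(0), extent_vox = integer(0),
                      z_peak = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      significant = logical(0))
  if (!any(supra)) return(empty)
  R <- reselCounts(roi, fwhm)
  rho <- ecDensities(u, df)
  Em <- max(sum(R * rho), 1e-12)                   # expected cluster count
  pVox <- if (is.finite(df)) stats::pt(u, df, lower.tail = FALSE)
          else stats::pnorm(u, lower.tail = FALSE)
  En <- sum(roi) * pVox / Em                       # expected cluster extent
  beta <- (gamma(2.5) / En)^(2 / 3)
  if (is.null(origin)) origin <- (d + 1) / 2
  comps <- connectedComponents26(supra)
  rows <- lapply(comps, function(vox) {
    k <- length(vox)
    pk <- exp(-beta * k^(2 / 3))
    pf <- 1 - exp(-Em * pk)
    peak <- vox[which.max(stat[vox])]
    pc <- arrayInd(peak, d)
    data.frame(p_fwe = pf, extent_vox = k,
               z_peak = tToZ(stat[peak], df),
               x_mm = (pc[1] - origin[1]) * voxelSize,
               y_mm = (pc[2] - origin[2]) * voxelSize,
               z_mm = (pc[3] - origin[3]) * voxelSize,
               significant = pf < alpha)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$p_fwe)
  out <- out[ord, , drop = FALSE]
  comps <- comps[ord]
  if (!allClusters) {
    keep <- out$significant
    out <- out[keep, , drop = FALSE]
    comps <- comps[keep]
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- u
  attr(out, "clusters") <- comps
  out
}

#' Run the full voxel-based study across modalities
#'
#' For every modality (Jacobian determinants for tensor-based morphometry and
#' the warped quantitative maps for voxel-based quantification) fits the GLM
#' with nuisance covariates, estimates residual smoothness, and performs
#' cluster-level FWE inference within each ROI. Subjects with a missing
#' effect value are dropped listwise per contrast; the per-modality n is
#' recorded.
#'
#' @param modalities named list; each element an n x V matrix of
#'   template-space observations (subjects in rows, voxels = `which(mask)`).
#' @param effect numeric effect of interest (n; NAs allowed, dropped).
#' @param covariates data.frame of nuisance covariates (n rows).
#' @param mask logical 3-D analysis mask locating the V voxels.
#' @param rois named list of logical 3-D ROI masks (subsets of `mask`).
#' @param direction +1/-1 tail of the contrast.
#' @param cdtP,alpha thresholds as in [clusterInference()].
#' @param voxelSize mm per voxel.
#' @param allClusters report all clusters rather than significant only.
#' @return data.frame with columns `modality, p_fwe, extent_vox, z_peak,
#'   x_mm, y_mm, z_mm, roi` (and `n`), ordered by modality then p.
#' @export
runStudy <- function(modalities, effect, covariates, mask, rois,
                     direction = -1, cdtP = 0.001, alpha = 0.05,
                     voxelSize = 1, allClusters = FALSE) {
  out <- list()
  for (mod in names(modalities)) {
    Y <- modalities[[mod]]
    keep <- is.finite(effect) & stats::complete.cases(covariates)
    if (sum(keep) < ncol(covariates) + 3) {
      warning("modality ", mod, ": too few complete subjects; skipped")
      next
    }
    Yk <- Y[keep, , drop = FALSE]
    ## analysis restricted to voxels observed in every kept subject
    vox <- colSums(!is.finite(Yk)) == 0
    if (sum(vox) < 10) {
      warning("modality ", mod, ": too few complete voxels; skipped")
      next
    }
    des <- buildDesign(effect[keep], covariates[keep, , drop = FALSE],
                       direction = direction)
    fit <- fitGLM(Yk[, vox, drop = FALSE], des$X, des$contrast)
    maskMod <- array(FALSE, dim(mask)); maskMod[which(mask)[vox]] <- TRUE
    sm <- estimateSmoothness(fit$residuals, maskMod)
    tMap <- array(NA_real_, dim(mask)); tMap[maskMod] <- fit$t
    for (rn in names(rois)) {
      cl <- clusterInference(tMap, fit$df, rois[[rn]], sm$fwhm,
                             cdtP = cdtP, alpha = alpha,
                             voxelSize = voxelSize, allClusters = allClusters)
      if (nrow(cl)) {
        cl$modality <- mod; cl$roi <- rn; cl$n <- sum(keep)
        out[[length(out) + 1L]] <- cl
      }
    }
  }
  if (!length(out))
    return(data.frame(modality = character(0), p_fwe = numeric(0),
                      extent_vox = integer(0), z_peak = numeric(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      roi = character(0), n = integer(0)))
  res <- do.call(rbind, out)
  res <- res[, c("modality", "p_fwe", "extent_vox", "z_peak",
                 "x_mm", "y_mm", "z_mm", "roi", "n")]
  res[order(res$modality, res$p_fwe), , drop = FALSE]
}
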