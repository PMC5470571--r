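## Quantitative map estimation from the three multi-echo FLASH series:
## echo averaging, log-linear R2* from the PDw echoes, dual-flip-angle R1 and
## amplitude by the small-angle rational approximation of the spoiled
## gradient-echo steady state, MT saturation from the MTw mean, and a smooth
## multiplicative bias-field correction.

#' Average the echoes of one weighting
#'
#' Voxelwise arithmetic mean over a set of echoes. By default echoes 1-6
#' (TE <= 14.76 ms at the default protocol) are used: these are common to all
#' three weightings, so the three means share one effective echo time and the
#' R2* decay factor cancels from the parameter estimators downstream.
#'
#' @param series list of 3-D echo volumes with attribute `TE` (seconds).
#' @param echoes integer indices of the echoes to average.
#' @return 3-D mean volume with attribute `effectiveTE` (mean TE, seconds).
#' @export
averageEchoes <- function(series, echoes = 1:6) {
  if (length(series) < 2L) stop("at least 2 echoes must be present")
  echoes <- echoes[echoes <= length(series)]
  if (length(echoes) < 2L) stop("at least 2 echoes must be averaged")
  d <- dim(series[[1]])
  for (e in echoes)
    if (!identical(dim(series[[e]]), d)) stop("mismatched echo grids")
  out <- Reduce(`+`, series[echoes]) / length(echoes)
  te <- attr(series, "TE")
  attr(out, "effectiveTE") <- if (!is.null(te)) mean(te[echoes]) else NA_real_
  out
}

#' Voxelwise R2* from the log signal of a multi-echo series
#'
#' Ordinary least squares of `log(S)` on TE at every voxel; `R2s = -slope`.
#' Voxels with any non-positive signal are masked out (`NA`) and counted.
#'
#' @param series list of >= 3 echo volumes (typically the 8 PDw echoes).
#' @param TE echo times in seconds; defaults to the series' `TE` attribute.
#' @return list with `R2s` (1/s), `S0` (intercept, signal units) and
#'   `nFlagged` (voxels masked for non-positive signal).
#' @export
fitR2star <- function(series, TE = attr(series, "TE")) {
  stopifnot(length(series) >= 3L, length(TE) == length(series))
  d <- dim(series[[1]])
  n <- length(series)
  S <- vapply(series, as.numeric, numeric(prod(d)))
  bad <- rowSums(S <= 0) > 0
  logS <- log(pmax(S, .Machine$double.xmin))
  teC <- TE - mean(TE)
  slope <- as.numeric(logS %*% teC) / sum(teC^2)
  inter <- rowMeans(logS) - slope * mean(TE)
  r2s <- -slope
  r2s[bad] <- NA_real_
  s0 <- exp(inter)
  s0[bad] <- NA_real_
  list(R2s = array(r2s, d), S0 = array(s0, d), nFlagged = sum(bad))
}

#' Dual-flip-angle R1 and amplitude maps
#'
#' Small-angle rational approximation of the spoiled gradient-echo steady
#' state applied to the averaged PDw and T1w signals:
#' \deqn{R_1 \approx \frac{1}{2}\,
#'   \frac{S_{T1}\alpha_{T1}/TR_{T1} - S_{PD}\alpha_{PD}/TR_{PD}}
#'        {S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1}}}
#' \deqn{A \approx S_{PD} S_{T1}\,
#'   \frac{TR_{PD}\,\alpha_{T1}/\alpha_{PD} - TR_{T1}\,\alpha_{PD}/\alpha_{T1}}
#'        {S_{T1} TR_{PD}\,\alpha_{T1} - S_{PD} TR_{T1}\,\alpha_{PD}}}
#' Voxels with non-physical output (R1 <= 0) are masked and counted.
#'
#' @param pdwMean,t1wMean averaged PDw and T1w volumes on one grid.
#' @param protoPD,protoT1 the matching [AcquisitionProtocol-class]s; the flip
#'   angles must differ.
#' @return list with `R1` (1/s), `A` (signal units), `nFlagged`.
#' @export
estimateR1Amplitude <- function(pdwMean, t1wMean, protoPD, protoT1) {
  stopifnot(identical(dim(pdwMean), dim(t1wMean)))
  aPD <- protoPD@flipAngle; aT1 <- protoT1@flipAngle
  if (abs(aPD - aT1) < 1e-9) stop("flip angles must differ (system singular)")
  trPD <- protoPD@TR; trT1 <- protoT1@TR
  d <- dim(pdwMean)
  Spd <- as.numeric(pdwMean); St1 <- as.numeric(t1wMean)
  R1 <- 0.5 * (St1 * aT1 / trT1 - Spd * aPD / trPD) /
    (Spd / aPD - St1 / aT1)
  A <- Spd * St1 * (trPD * aT1 / aPD - trT1 * aPD / aT1) /
    (St1 * trPD * aT1 - Spd * trT1 * aPD)
  bad <- !is.finite(R1) | R1 <= 0 | !is.finite(A) | A <= 0
  R1[bad] <- NA_real_; A[bad] <- NA_real_
  list(R1 = array(R1, d), A = array(A, d), nFlagged = sum(bad))
}

#' MT saturation from the MT-weighted mean
#'
#' Percent-unit MT saturation from the MTw signal given the amplitude and R1
#' maps:
#' \deqn{\delta = \left(\frac{A\,\alpha_{MT}}{S_{MT}} - 1\right) TR_{MT} R_1
#'       - \frac{\alpha_{MT}^2}{2}}
#' (expressed in p.u., i.e. multiplied by 100). Voxels with `S_MT <= 0` or
#' missing A/R1 are masked and counted.
#'
#' @param mtwMean averaged MTw volume.
#' @param A,R1 amplitude and R1 maps from [estimateR1Amplitude()].
#' @param protoMT the MTw [AcquisitionProtocol-class].
#' @return list with `MTsat` (p.u.) and `nFlagged`.
#' @export
estimateMTsat <- function(mtwMean, A, R1, protoMT) {
  stopifnot(identical(dim(mtwMean), dim(A)), identical(dim(A), dim(R1)))
  aMT <- protoMT@flipAngle; trMT <- protoMT@TR
  d <- dim(mtwMean)
  Smt <- as.numeric(mtwMean)
  bad <- Smt <= 0 | !is.finite(Smt) | !is.finite(as.numeric(A)) | !is.finite(as.numeric(R1))
  delta <- (as.numeric(A) * aMT / Smt - 1) * trMT * as.numeric(R1) - aMT^2 / 2
  delta[bad] <- NA_real_
  list(MTsat = array(100 * delta, d), nFlagged = sum(bad))
}

#' Smooth multiplicative bias-field correction
#'
#' Simplified transmit-inhomogeneity correction: a low-order polynomial
#' log-domain field is fit by ridge-penalized regression to the deviation of
#' the log map from its within-class median (classes from equal-width
#' intensity bins), giving a smooth strictly positive multiplicative field.
#' The field is gauge-fixed to mean 1 over the mask and divided out.
#'
#' @param map 3-D input map (positive inside the mask).
#' @param mask logical 3-D mask (non-empty).
#' @param basisOrder polynomial order (<= 4).
#' @param nClasses intensity classes used for the within-class reference.
#' @param lambda ridge penalty on the non-constant coefficients.
#' @return list with `corrected` (map / field), `field` (mean 1 over mask),
#'   and `basisOrder`. On a degenerate fit a warning is issued and the
#'   identity field returned.
#' @export
correctBias <- function(map, mask, basisOrder = 3, nClasses = 3, lambda = 1e-3) {
  stopifnot(basisOrder <= 4, any(mask))
  d <- dim(map)
  sel <- which(mask & is.finite(map) & map > 0)
  logm <- log(map[sel])
  ## intensity classes by equal-width binning of the log intensities;
  ## within-class median as reference
  rng <- range(logm)
  cls <- if (diff(rng) < 1e-12) rep(1L, length(logm))
         else cut(logm, breaks = seq(rng[1] - 1e-9, rng[2] + 1e-9,
                                     length.out = nClasses + 1),
                  include.lowest = TRUE)
  ref <- stats::ave(logm, cls, FUN = stats::median)
  resid <- logm - ref
  B <- polyBasis3D(d, basisOrder, subset = sel)
  pen <- diag(ncol(B)) * lambda * length(sel)
  pen[1, 1] <- 0
  xtx <- crossprod(B) + pen
  cn <- kappa(xtx, exact = FALSE)
  if (!is.finite(cn) || cn > 1e10) {
    warning("degenerate bias fit; returning identity field")
    field <- array(1, d)
    return(list(corrected = map, field = field, basisOrder = basisOrder))
  }
  coef <- solve(xtx, crossprod(B, resid))
  full <- polyBasis3D(d, basisOrder)
  field <- array(exp(as.numeric(full %*% coef)), d)
  field <- field / mean(field[mask])
  list(corrected = map / field, field = field, basisOrder = basisOrder)
}

#' Estimate the full set of quantitative maps for one subject
#'
#' Runs the estimation chain on a simulated (or loaded) multi-echo subject:
#' echo averaging per weighting, R2* from the raw PDw echoes, dual-flip-angle
#' R1 and amplitude, MT saturation, and optionally bias correction of the R1
#' map. Flagged-voxel counts are accumulated per map (input voxels = retained
#' + flagged).
#'
#' @param echoes subject echo data as returned by [simulateSubject()].
#' @param mask logical analysis (brainstem) mask.
#' @param protocols list of the three protocols; defaults to the `protocols`
#'   attribute of `echoes`.
#' @param avgEchoes echo indices averaged for the three means.
#' @param r2sEchoes echo indices used in the R2* fit (all 8 PDw by default).
#' @param biasCorrect apply [correctBias()] to the R1 map.
#' @param biasOrder polynomial order for the bias correction.
#' @return a [QMaps-class] object.
#' @export
fitQMaps <- function(echoes, mask, protocols = attr(echoes, "protocols"),
                     avgEchoes = 1:6, r2sEchoes = NULL,
                     biasCorrect = FALSE, biasOrder = 3) {
  pdwMean <- averageEchoes(echoes$PDw, avgEchoes)
  t1wMean <- averageEchoes(echoes$T1w, avgEchoes)
  mtwMean <- averageEchoes(echoes$MTw, avgEchoes)
  pdw <- echoes$PDw
  if (!is.null(r2sEchoes)) {
    te <- attr(pdw, "TE")[r2sEchoes]
    pdw <- pdw[r2sEchoes]
    attr(pdw, "TE") <- te
  }
  r2sFit <- fitR2star(pdw)
  r1Fit <- estimateR1Amplitude(pdwMean, t1wMean, protocols$PDw, protocols$T1w)
  if (biasCorrect) {
    bc <- correctBias(r1Fit$R1, mask & is.finite(r1Fit$R1), basisOrder = biasOrder)
    r1Fit$R1 <- bc$corrected
  }
  mtFit <- estimateMTsat(mtwMean, r1Fit$A, r1Fit$R1, protocols$MTw)
  maskNA <- function(v) { v[!mask] <- NA_real_; v }
  r1 <- maskNA(r1Fit$R1)
  bad <- mask & (!is.finite(r1) | r1 <= 0)
  r1[bad] <- NA_real_
  new("QMaps",
      MTsat = maskNA(mtFit$MTsat), R1 = r1,
      R2s = maskNA(r2sFit$R2s), A = maskNA(r1Fit$A),
      mask = mask, voxelSize = 1,
      flagged = c(R2s = as.integer(r2sFit$nFlagged),
                  R1 = as.integer(r1Fit$nFlagged),
                  MTsat = as.integer(mtFit$nFlagged)))
}
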