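#' qmriMorph: quantitative MRI brainstem morphometry
#'
#' Simulation and analysis pipeline for quantitative-MRI morphometry of the
#' brainstem: multi-echo FLASH phantom simulation, MTsat/R1/R2* map
#' estimation, Gaussian-mixture tissue-template learning, diffeomorphic
#' registration with Jacobian-based morphometry, GLM cluster-level inference,
#' and ISNCSCI/SCIM clinical scoring.
#'
#' @name qmriMorph-package
#' @aliases qmriMorph
#' @keywords internal
"_PACKAGE"

#' @import methods
NULL

#' AcquisitionProtocol: one FLASH weighting of the multi-parameter protocol
#'
#' Describes a spoiled gradient-echo (FLASH) acquisition: the weighting label,
#' repetition time, excitation flip angle and multi-echo readout times. The
#' MT-weighted acquisition carries an off-resonance saturation pulse
#' (`mtPulse`). Flip angles are stored in radians; the constructor
#' [acquisitionProtocol()] takes degrees.
#'
#' @slot weighting one of `"T1w"`, `"PDw"`, `"MTw"`.
#' @slot TR repetition time in seconds.
#' @slot flipAngle excitation flip angle in radians, in (0, pi/2).
#' @slot TEList echo times in seconds, strictly increasing, all < TR.
#' @slot mtPulse logical; `TRUE` iff `weighting == "MTw"`.
#' @export
setClass("AcquisitionProtocol",
  representation(weighting = "character", TR = "numeric",
                 flipAngle = "numeric", TEList = "numeric", mtPulse = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (!object@weighting %in% c("T1w", "PDw", "MTw"))
      msg <- c(msg, "weighting must be T1w, PDw or MTw")
    if (length(object@TEList) < 1L || any(diff(object@TEList) <= 0))
      msg <- c(msg, "TEList must be strictly increasing")
    if (any(object@TEList >= object@TR))
      msg <- c(msg, "all echo times must be shorter than TR")
    if (object@flipAngle <= 0 || object@flipAngle >= pi / 2)
      msg <- c(msg, "flipAngle must lie in (0, pi/2) radians")
    if (object@mtPulse != (object@weighting == "MTw"))
      msg <- c(msg, "mtPulse must be TRUE exactly for the MTw weighting")
    if (length(msg)) msg else TRUE
  })

#' Construct an AcquisitionProtocol
#'
#' @param weighting `"T1w"`, `"PDw"` or `"MTw"`.
#' @param TR repetition time, seconds.
#' @param flipDeg excitation flip angle, degrees.
#' @param TE echo times, seconds (strictly increasing).
#' @return an [AcquisitionProtocol-class] object.
#' @examples
#' acquisitionProtocol("T1w", TR = 0.025, flipDeg = 23,
#'                     TE = seq(2.46, 17.22, by = 2.46) / 1000)
#' @export
acquisitionProtocol <- function(weighting, TR, flipDeg, TE) {
  new("AcquisitionProtocol", weighting = weighting, TR = TR,
      flipAngle = flipDeg * pi / 180, TEList = TE,
      mtPulse = identical(weighting, "MTw"))
}

#' Default multi-parameter-mapping protocols
#'
#' The three FLASH weightings of the whole-brain multi-parameter qMRI
#' protocol used as simulator defaults: T1w 25 ms/23 deg, PDw 25 ms/4 deg,
#' MTw 37 ms/9 deg; seven equidistant echoes from 2.46 ms to 17.22 ms for all
#' weightings plus an additional 19.68 ms echo for PDw and T1w.
#'
#' @return named list of three [AcquisitionProtocol-class] objects.
#' @export
defaultProtocols <- function() {
  te7 <- seq(2.46, 17.22, by = 2.46) / 1000
  te8 <- c(te7, 19.68 / 1000)
  list(
    T1w = acquisitionProtocol("T1w", TR = 0.025, flipDeg = 23, TE = te8),
    PDw = acquisitionProtocol("PDw", TR = 0.025, flipDeg = 4,  TE = te8),
    MTw = acquisitionProtocol("MTw", TR = 0.037, flipDeg = 9,  TE = te7)
  )
}

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol %s: TR %.1f ms, flip %.1f deg, %d echoes (%.2f-%.2f ms)%s\n",
              object@weighting, 1000 * object@TR, object@flipAngle * 180 / pi,
              length(object@TEList), 1000 * min(object@TEList),
              1000 * max(object@TEList),
              if (object@mtPulse) ", MT pulse" else ""))
})

#' DeformationField: invertible spatial mapping with Jacobian determinants
#'
#' The mapping is stored as a dense displacement field `phi` in voxel units
#' (`x -> x + phi(x)`), with the per-voxel Jacobian determinant of the mapping.
#' Fields produced by [integrateVelocity()] are diffeomorphic: all Jacobian
#' determinants are strictly positive.
#'
#' @slot phi 4-D array (x, y, z, component) of displacements, voxel units.
#' @slot jac 3-D array of Jacobian determinants, strictly positive.
#' @slot voxelSize voxel edge length in mm.
#' @export
setClass("DeformationField",
  representation(phi = "array", jac = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@phi)) != 4L || dim(object@phi)[4] != 3L)
      msg <- c(msg, "phi must be a 4-D array with 3 components")
    if (!identical(dim(object@phi)[1:3], dim(object@jac)))
      msg <- c(msg, "jac grid must match phi grid")
    if (any(!is.finite(object@jac)) || any(object@jac <= 0))
      msg <- c(msg, "Jacobian determinants must be finite and strictly positive")
    if (length(msg)) msg else TRUE
  })

#' @describeIn DeformationField-class displacement array accessor
#' @param x a `DeformationField`.
#' @export
displacement <- function(x) x@phi

#' @describeIn DeformationField-class Jacobian-determinant map accessor
#' @export
jacobianMap <- function(x) x@jac

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@jac)
  cat(sprintf("DeformationField %dx%dx%d, |phi| mean %.3f vox, jac in [%.3f, %.3f]\n",
              d[1], d[2], d[3],
              mean(sqrt(sumOverClasses(object@phi^2))),
              min(object@jac), max(object@jac)))
})

#' PhantomTruth: ground truth for one simulated subject
#'
#' Holds everything the simulator knows about one subject: the subject-space
#' per-voxel class probability field, the realized per-class tissue
#' parameters, smooth multiplicative bias fields per weighting, the
#' template-to-subject deformation, and the brainstem mask.
#'
#' @slot labelProb 4-D array (x, y, z, class): per-voxel class probabilities,
#'   summing to 1 at every voxel.
#' @slot templateProb the undeformed template probability field (same layout).
#' @slot params data.frame with one row per class: `class_id`, `name`, `A`
#'   (signal units), `R1` (1/s), `R2s` (1/s), `MTsat` (percent units) as
#'   realized for this subject.
#' @slot bias named list of strictly positive 3-D arrays, one per weighting.
#' @slot deformation a [DeformationField-class] (template to subject).
#' @slot mask logical 3-D brainstem mask.
#' @slot voxelSize voxel edge length, mm.
#' @export
setClass("PhantomTruth",
  representation(labelProb = "array", templateProb = "array",
                 params = "data.frame", bias = "list",
                 deformation = "DeformationField", mask = "array",
                 voxelSize = "numeric"),
  validity = function(object) {
    msg <- character(0)
    s <- sumOverClasses(object@labelProb)
    if (max(abs(s - 1)) > 1e-9)
      msg <- c(msg, "labelProb must sum to 1 at every voxel (tol 1e-9)")
    if (any(vapply(object@bias, function(b) any(b <= 0), logical(1))))
      msg <- c(msg, "bias fields must be strictly positive")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PhantomTruth-class subject-space class-probability field
#' @param x a `PhantomTruth`.
#' @export
labelProbabilities <- function(x) x@labelProb

#' @describeIn PhantomTruth-class realized per-class tissue parameters
#' @export
tissueParams <- function(x) x@params

#' @describeIn PhantomTruth-class brainstem mask accessor
#' @export
brainstemMask <- function(x) x@mask

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@labelProb)
  cat(sprintf("PhantomTruth %dx%dx%d, %d classes, %d mask voxels, voxel %.1f mm\n",
              d[1], d[2], d[3], d[4], sum(object@mask), object@voxelSize))
})

#' QMaps: co-registered quantitative maps for one subject
#'
#' Quantitative magnetisation-transfer saturation (percent units),
#' longitudinal relaxation rate R1 (1/s), effective transverse relaxation
#' rate R2* (1/s) and signal amplitude maps on a common grid, with the
#' analysis mask and a log of voxels flagged during estimation.
#'
#' @slot MTsat,R1,R2s,A 3-D arrays on one grid (NA outside mask/flagged).
#' @slot mask logical 3-D analysis mask.
#' @slot voxelSize voxel edge length, mm.
#' @slot flagged named integer vector: voxels flagged per map.
#' @export
setClass("QMaps",
  representation(MTsat = "array", R1 = "array", R2s = "array", A = "array",
                 mask = "array", voxelSize = "numeric", flagged = "integer"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@MTsat)
    if (!identical(d, dim(object@R1)) || !identical(d, dim(object@R2s)) ||
        !identical(d, dim(object@A)) || !identical(d, dim(object@mask)))
      msg <- c(msg, "all maps and the mask must share one grid")
    inm <- object@mask & is.finite(object@R1)
    if (any(object@R1[inm] <= 0)) msg <- c(msg, "R1 must be > 0 inside the mask")
    if (length(msg)) msg else TRUE
  })

#' @describeIn QMaps-class MT saturation map (percent units)
#' @param x a `QMaps`.
#' @export
mtsatMap <- function(x) x@MTsat
#' @describeIn QMaps-class R1 map (1/s)
#' @export
r1Map <- function(x) x@R1
#' @describeIn QMaps-class R2* map (1/s)
#' @export
r2sMap <- function(x) x@R2s
#' @describeIn QMaps-class amplitude map (signal units)
#' @export
amplitudeMap <- function(x) x@A
#' @describeIn QMaps-class analysis mask
#' @export
analysisMask <- function(x) x@mask

setMethod("show", "QMaps", function(object) {
  d <- dim(object@MTsat)
  inm <- object@mask
  cat(sprintf("QMaps %dx%dx%d (%d mask voxels)\n", d[1], d[2], d[3], sum(inm)))
  cat(sprintf("  MTsat %.2f p.u. | R1 %.2f 1/s | R2* %.1f 1/s (mask medians)\n",
              stats::median(object@MTsat[inm], na.rm = TRUE),
              stats::median(object@R1[inm], na.rm = TRUE),
              stats::median(object@R2s[inm], na.rm = TRUE)))
  if (sum(object@flagged) > 0)
    cat("  flagged voxels:", paste(names(object@flagged), object@flagged,
                                   sep = "=", collapse = ", "), "\n")
})

#' MixtureModel: multivariate Gaussian mixture with spatially varying priors
#'
#' Per-class multivariate Gaussian parameters over C image channels plus the
#' spatially varying prior field (tissue probability maps). Covariances are
#' kept symmetric positive-definite by an eigenvalue floor.
#'
#' @slot means K x C matrix of class means.
#' @slot covariances C x C x K array of class covariances.
#' @slot mixing length-K global mixing weights, summing to 1.
#' @slot tpm 4-D array (x, y, z, class) of voxelwise priors, summing to 1.
#' @slot channels character vector naming the C channels.
#' @export
setClass("MixtureModel",
  representation(means = "matrix", covariances = "array", mixing = "numeric",
                 tpm = "array", channels = "character"),
  validity = function(object) {
    msg <- character(0)
    K <- nrow(object@means)
    if (abs(sum(object@mixing) - 1) > 1e-8)
      msg <- c(msg, "mixing weights must sum to 1")
    if (dim(object@covariances)[3] != K)
      msg <- c(msg, "one covariance per class required")
    for (k in seq_len(K)) {
      ev <- eigen(object@covariances[, , k], symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) { msg <- c(msg, "covariances must be positive-definite"); break }
    }
    if (length(dim(object@tpm)) == 4L) {
      s <- sumOverClasses(object@tpm)
      if (max(abs(s - 1)) > 1e-9)
        msg <- c(msg, "tpm must sum to 1 per voxel (tol 1e-9)")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn MixtureModel-class class means accessor
#' @param x a `MixtureModel`.
#' @export
classMeans <- function(x) x@means
#' @describeIn MixtureModel-class class covariances accessor
#' @export
classCovariances <- function(x) x@covariances
#' @describeIn MixtureModel-class global mixing weights
#' @export
mixingWeights <- function(x) x@mixing
#' @describeIn MixtureModel-class tissue-probability-map field
#' @export
tpmField <- function(x) x@tpm

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: %d classes, %d channels (%s)\n",
              nrow(object@means), ncol(object@means),
              paste(object@channels, collapse = ", ")))
  cat("  mixing:", paste(sprintf("%.3f", object@mixing), collapse = " "), "\n")
})
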