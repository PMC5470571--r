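## Phantom simulator: brainstem-like geometry with known tissue parameters,
## smooth bias fields, subject-specific diffeomorphic deformations, a patient
## group with localized atrophy and myelin reduction, and linked clinical
## scores. Every downstream stage of the pipeline is testable against the
## ground truth generated here.

#' Steady-state spoiled gradient-echo (FLASH) signal
#'
#' Closed-form signal of a perfectly spoiled gradient-echo acquisition with a
#' multiplicative magnetisation-transfer saturation term applied in the
#' dual-excitation approximation:
#' \deqn{S = A \sin\alpha (1-\delta) \frac{1-E_1}{1-\cos\alpha (1-\delta) E_1}
#'       e^{-TE \cdot R_2^*}, \quad E_1 = e^{-TR \cdot R_1}.}
#'
#' @param A signal amplitude (effective proton density), > 0. Vectorized.
#' @param R1 longitudinal relaxation rate, 1/s, > 0. Vectorized.
#' @param R2s effective transverse relaxation rate, 1/s, >= 0. Vectorized.
#' @param delta fractional MT saturation in [0, 1); must be 0 unless the
#'   protocol carries an MT pulse.
#' @param proto an [AcquisitionProtocol-class].
#' @param TE echo time in seconds; must be 0 (zero-echo limit) or one of the
#'   protocol's echo times.
#' @return signal in the same units as `A` (non-negative).
#' @examples
#' p <- defaultProtocols()$T1w
#' spgrSignal(1000, 1.0, 0, 0, p, TE = 0)   # ~94.4
#' @export
spgrSignal <- function(A, R1, R2s, delta, proto, TE) {
  stopifnot(is(proto, "AcquisitionProtocol"))
  if (any(A <= 0)) stop("A must be strictly positive")
  if (any(R1 <= 0)) stop("R1 must be strictly positive")
  if (any(R2s < 0)) stop("R2s must be non-negative")
  if (any(delta < 0) || any(delta >= 1)) stop("delta must lie in [0, 1)")
  if (!proto@mtPulse && any(delta != 0))
    stop("delta must be 0 for a protocol without MT pulse")
  if (length(TE) != 1L || (TE != 0 && min(abs(TE - proto@TEList)) > 1e-9))
    stop("TE must be 0 or one of the protocol's echo times")
  E1 <- exp(-proto@TR * R1)
  a <- proto@flipAngle
  A * sin(a) * (1 - delta) * (1 - E1) /
    (1 - cos(a) * (1 - delta) * E1) * exp(-TE * R2s)
}

#' Default per-class tissue parameters
#'
#' Literature-plausible 3T values for brainstem-like compartments: a white
#' matter tegmentum matrix, CSF, corticospinal tract (CST) columns, medial
#' lemniscus, periaqueductal grey (PAG), red nuclei and substantia nigra.
#' `A` in arbitrary signal units, `R1`/`R2s` in 1/s, `MTsat` in percent units.
#'
#' @param K number of classes (2..7); classes are taken in the order listed
#'   above, the remainder of the volume falling to the tegmentum matrix.
#' @param betweenSubjectCv multiplicative between-subject coefficient of
#'   variation (fraction in [0, 0.5]).
#' @return data.frame with columns `class_id`, `name`, `A`, `R1`, `R2s`,
#'   `MTsat`, `cv`.
#' @export
defaultTissueParams <- function(K = 7, betweenSubjectCv = 0.05) {
  stopifnot(K >= 2, K <= 7)
  stopifnot(betweenSubjectCv >= 0, betweenSubjectCv <= 0.5)
  full <- data.frame(
    name  = c("tegmentum", "csf", "cst", "medial_lemniscus", "pag",
              "red_nucleus", "substantia_nigra"),
    A     = c(1000, 1200, 980, 970, 1060, 950, 940),
    R1    = c(0.95, 0.30, 1.10, 1.05, 0.80, 1.00, 0.95),
    R2s   = c(24, 3, 22, 23, 19, 30, 33),
    MTsat = c(3.0, 0.1, 4.3, 3.8, 1.8, 2.6, 2.3),
    stringsAsFactors = FALSE)
  out <- full[seq_len(K), , drop = FALSE]
  out <- cbind(class_id = seq_len(K), out, cv = betweenSubjectCv)
  rownames(out) <- NULL
  out
}

#' Phantom configuration
#'
#' Bundles grid geometry, tissue parameters and the generative nuisance
#' settings (bias fields, random subject deformations, noise).
#'
#' @param grid integer length-3 grid shape (voxels).
#' @param voxelSize voxel edge length, mm.
#' @param K number of tissue classes (2..7).
#' @param params tissue parameter table as from [defaultTissueParams()].
#' @param softEdgeSigma Gaussian sigma (voxels) for soft class boundaries.
#' @param biasAmplitude log-amplitude of the multiplicative bias fields.
#' @param biasOrder polynomial order of the bias log-field.
#' @param warpSigma smoothness (voxels) of random subject velocities.
#' @param warpAmplitude RMS displacement magnitude (voxels) of the random
#'   subject deformation.
#' @param noiseSd additive Gaussian noise sd, signal units.
#' @return a list of class `phantomConfig`.
#' @export
phantomConfig <- function(grid = c(48L, 64L, 96L), voxelSize = 1,
                          K = 7, params = NULL, softEdgeSigma = 0.75,
                          biasAmplitude = 0.05, biasOrder = 2,
                          warpSigma = 6, warpAmplitude = 1.0,
                          noiseSd = 5) {
  if (is.null(params)) params <- defaultTissueParams(K)
  stopifnot(length(grid) == 3L, all(grid >= 8L), K >= 2, nrow(params) == K)
  stopifnot(all(params$A > 0), all(params$R1 > 0), all(params$R2s > 0 | params$name == "csf"),
            all(params$MTsat >= 0), all(params$MTsat < 100),
            all(params$cv >= 0 & params$cv <= 0.5))
  structure(list(grid = as.integer(grid), voxelSize = voxelSize, K = as.integer(K),
                 params = params, softEdgeSigma = softEdgeSigma,
                 biasAmplitude = biasAmplitude, biasOrder = biasOrder,
                 warpSigma = warpSigma, warpAmplitude = warpAmplitude,
                 noiseSd = noiseSd),
            class = "phantomConfig")
}

## Deterministic template geometry: nested columns and nuclei in a
## superelliptic brainstem body. Returns list(prob = 4-D array, mask = body).
phantomTemplate <- function(config) {
  d <- config$grid; K <- config$K
  g <- coordinateGrids(d)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  rx <- 0.33 * d[1]; ry <- 0.31 * d[2]
  ux <- (g$x - cx) / rx; uy <- (g$y - cy) / ry
  body <- ux^2 + uy^2 <= 1
  aq <- c(cx, cy + 0.45 * ry)                      # aqueduct axis
  raq <- 0.045 * d[1]
  dAq <- sqrt((g$x - aq[1])^2 + (g$y - aq[2])^2)
  zf <- g$z / d[3]
  ind <- vector("list", 7L)
  ind[[2]] <- !body | (dAq <= raq)                 # csf: exterior + aqueduct
  cstOff <- 0.146 * d[1]; cstR <- 0.08 * d[1]; cstCy <- cy - 0.40 * ry
  ind[[3]] <- (sqrt((g$x - (cx - cstOff))^2 + (g$y - cstCy)^2) <= cstR) |
              (sqrt((g$x - (cx + cstOff))^2 + (g$y - cstCy)^2) <= cstR)
  ind[[4]] <- abs(g$x - cx) <= 0.09 * d[1] & abs(g$y - (cy + 0.10 * ry)) <= 0.08 * d[2]
  ind[[5]] <- dAq > raq & dAq <= raq + 0.10 * d[1] & zf > 0.60    # pag (midbrain)
  rnC <- 0.78 * d[3]
  ind[[6]] <- (((g$x - (cx - 0.11 * d[1])) / (0.10 * d[1]))^2 +
               ((g$y - (cy + 0.05 * ry)) / (0.10 * d[1]))^2 +
               ((g$z - rnC) / (0.07 * d[3]))^2 <= 1) |
              (((g$x - (cx + 0.11 * d[1])) / (0.10 * d[1]))^2 +
               ((g$y - (cy + 0.05 * ry)) / (0.10 * d[1]))^2 +
               ((g$z - rnC) / (0.07 * d[3]))^2 <= 1)
  snC <- 0.72 * d[3]
  ind[[7]] <- (((g$x - (cx - 0.17 * d[1])) / (0.09 * d[1]))^2 +
               ((g$y - (cy - 0.15 * ry)) / (0.06 * d[2]))^2 +
               ((g$z - snC) / (0.09 * d[3]))^2 <= 1) |
              (((g$x - (cx + 0.17 * d[1])) / (0.09 * d[1]))^2 +
               ((g$y - (cy - 0.15 * ry)) / (0.06 * d[2]))^2 +
               ((g$z - snC) / (0.09 * d[3]))^2 <= 1)
  ## priority: specific structures override; tegmentum is the remainder
  taken <- array(FALSE, d)
  hard <- array(0L, d)
  for (k in c(2L, 5L, 6L, 7L, 3L, 4L)) {          # csf/pag/nuclei before columns
    if (k > K) next
    sel <- ind[[k]] & !taken
    hard[sel] <- k
    taken <- taken | ind[[k]]
  }
  hard[hard == 0L] <- 1L                           # tegmentum matrix
  prob <- array(0, c(d, K))
  for (k in seq_len(K)) {
    pk <- smoothGaussianFFT((hard == k) * 1, config$softEdgeSigma)
    prob[, , , k] <- pmax(pk, 1e-12)
  }
  s <- sumOverClasses(prob)
  for (k in seq_len(K)) prob[, , , k] <- prob[, , , k] / s
  list(prob = prob, mask = body)
}

#' Localized patient group effect
#'
#' Encodes regional atrophy (a volume scaling applied through the subject
#' deformation) and additive quantitative-parameter shifts within a spherical
#' region of the template brainstem, by default placed in the left CST column
#' at mid-medulla level.
#'
#' @param config a [phantomConfig()].
#' @param nVoxels approximate region size in voxels.
#' @param center region center (voxel coordinates); default left CST column.
#' @param volumeScale local volume scaling in (0.5, 1.5]; 0.85 means 15%
#'   local atrophy.
#' @param mtsatShift reduction of MT saturation inside the region, p.u.
#' @param r1Shift reduction of R1 inside the region, 1/s.
#' @param r2sShift reduction of R2* inside the region, 1/s.
#' @return list of class `groupEffect` with the region mask, a smooth window
#'   and the shifts.
#' @export
groupEffect <- function(config, nVoxels = 500, center = NULL,
                        volumeScale = 0.85, mtsatShift = 0.4,
                        r1Shift = 0.05, r2sShift = 0) {
  stopifnot(volumeScale > 0.5, volumeScale <= 1.5)
  d <- config$grid
  if (is.null(center)) {
    center <- c((d[1] + 1) / 2 - 0.146 * d[1],
                (d[2] + 1) / 2 - 0.40 * 0.31 * d[2],
                0.35 * d[3])
  }
  r <- (3 * nVoxels / (4 * pi))^(1 / 3)
  g <- coordinateGrids(d)
  dist <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  mask <- dist <= r
  if (!any(mask)) stop("effect region is empty (mask outside grid?)")
  tmpl <- phantomTemplate(config)
  if (any(mask & !tmpl$mask))
    stop("effect region must lie inside the brainstem mask")
  ## window ~1 over the whole region, decaying smoothly outside it
  window <- smoothGaussianFFT((dist <= r + 3) * 1, 1)
  window <- pmin(pmax(window, 0), 1)
  structure(list(mask = mask, window = window, center = center, radius = r,
                 volumeScale = volumeScale, mtsatShift = mtsatShift,
                 r1Shift = r1Shift, r2sShift = r2sShift),
            class = "groupEffect")
}

#' Generate the ground truth for one subject
#'
#' Realizes per-class tissue parameters with between-subject variability,
#' smooth multiplicative bias fields per weighting, and a random smooth
#' diffeomorphic deformation; for patients, superimposes the [groupEffect()]
#' contraction on the velocity and records the lesioned parameter set.
#'
#' @param config a [phantomConfig()].
#' @param seed integer RNG seed (bit-identical output for identical input).
#' @param effect optional [groupEffect()] (patients).
#' @param severity scalar multiplier of the effect magnitude for this subject.
#' @param template precomputed [phantomTemplate()] result (cached across a
#'   cohort); recomputed when `NULL`.
#' @return a [PhantomTruth-class] object.
#' @export
makePhantom <- function(config, seed, effect = NULL, severity = 1,
                        template = NULL) {
  stopifnot(inherits(config, "phantomConfig"))
  set.seed(seed)
  d <- config$grid
  tmpl <- if (is.null(template)) phantomTemplate(config) else template
  K <- config$K
  params <- config$params
  ## multiplicative log-normal between-subject variability (mean-preserving)
  for (col in c("A", "R1", "R2s", "MTsat")) {
    cv <- params$cv
    f <- exp(stats::rnorm(K, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2))))
    params[[col]] <- params[[col]] * f
  }
  ## smooth strictly positive bias fields (exponentiated low-order polynomial)
  basis <- polyBasis3D(d, config$biasOrder)
  bias <- lapply(c(T1w = 1, PDw = 2, MTw = 3), function(i) {
    coef <- stats::rnorm(ncol(basis), 0, config$biasAmplitude / sqrt(ncol(basis)))
    coef[1] <- 0
    array(exp(as.numeric(basis %*% coef)), d)
  })
  ## random smooth stationary velocity; patients add the contraction component
  vel <- array(0, c(d, 3L))
  for (c3 in 1:3) {
    n <- smoothGaussianFFT(array(stats::rnorm(prod(d)), d), config$warpSigma)
    vel[, , , c3] <- n / sqrt(mean(n^2)) * config$warpAmplitude / sqrt(3)
  }
  appliedEffect <- list()
  if (!is.null(effect)) {
    logs <- severity * log(effect$volumeScale)
    g <- coordinateGrids(d)
    w <- effect$window
    vel[, , , 1] <- vel[, , , 1] + (logs / 3) * (g$x - effect$center[1]) * w
    vel[, , , 2] <- vel[, , , 2] + (logs / 3) * (g$y - effect$center[2]) * w
    vel[, , , 3] <- vel[, , , 3] + (logs / 3) * (g$z - effect$center[3]) * w
    lesioned <- params
    lesioned$MTsat <- pmax(lesioned$MTsat - severity * effect$mtsatShift, 0)
    lesioned$R1 <- pmax(lesioned$R1 - severity * effect$r1Shift, 1e-3)
    lesioned$R2s <- pmax(lesioned$R2s - severity * effect$r2sShift, 0)
    appliedEffect <- list(window = w, params = lesioned, effect = effect,
                          severity = severity)
  }
  fwd <- integrateVelocity(vel, steps = 6)         # template -> subject
  inv <- integrateVelocity(-vel, steps = 6)        # subject -> template
  ## subject-space class probabilities: pull template probs back through the
  ## inverse map, then renormalize (conservation contract)
  g <- coordinateGrids(d)
  xs <- as.numeric(g$x) + as.numeric(inv@phi[, , , 1])
  ys <- as.numeric(g$y) + as.numeric(inv@phi[, , , 2])
  zs <- as.numeric(g$z) + as.numeric(inv@phi[, , , 3])
  prob <- array(0, c(d, K))
  for (k in seq_len(K))
    prob[, , , k] <- array(interpTrilinear(tmpl$prob[, , , k], xs, ys, zs), d)
  prob <- pmax(prob, 1e-12)
  s <- sumOverClasses(prob)
  for (k in seq_len(K)) prob[, , , k] <- prob[, , , k] / s
  maskS <- array(interpTrilinear(tmpl$mask * 1, xs, ys, zs), d) >= 0.5
  truth <- new("PhantomTruth", labelProb = prob, templateProb = tmpl$prob,
               params = params, bias = bias, deformation = fwd,
               mask = maskS, voxelSize = config$voxelSize)
  attr(truth, "inverseDeformation") <- inv
  attr(truth, "effect") <- appliedEffect
  attr(truth, "templateMask") <- tmpl$mask
  truth
}

#' Ground-truth voxelwise quantitative parameter maps for a phantom subject
#'
#' Probability-weighted mixture of the realized class parameters (with the
#' lesioned parameters blended in through the effect window for patients).
#'
#' @param truth a [PhantomTruth-class].
#' @return list of 3-D arrays `MTsat` (p.u.), `R1`, `R2s` (1/s), `A`.
#' @export
truthParameterMaps <- function(truth) {
  d <- dim(truth@labelProb)[1:3]
  K <- dim(truth@labelProb)[4]
  eff <- attr(truth, "effect")
  out <- list()
  for (col in c("MTsat", "R1", "R2s", "A")) {
    base <- array(0, d)
    for (k in seq_len(K))
      base <- base + truth@labelProb[, , , k] * truth@params[[col]][k]
    if (length(eff)) {
      les <- array(0, d)
      for (k in seq_len(K))
        les <- les + truth@labelProb[, , , k] * eff$params[[col]][k]
      base <- (1 - eff$window) * base + eff$window * les
    }
    out[[col]] <- base
  }
  out
}

#' Simulate the multi-echo FLASH series for one subject
#'
#' The noiseless value at voxel v for weighting w and echo TE is
#' `bias_w(v) * sum_k p_k(v) * spgrSignal(params_k, TE)`, with the lesioned
#' parameter set blended through the effect window for patients; additive
#' Gaussian noise of the given sd is then applied.
#'
#' @param truth a [PhantomTruth-class].
#' @param protocols named list of the three [AcquisitionProtocol-class]s.
#' @param noiseSd additive Gaussian noise sd (signal units), >= 0.
#' @param seed integer RNG seed.
#' @return named list per weighting, each a list of 3-D echo volumes with the
#'   echo times as attribute `TE`.
#' @export
simulateSubject <- function(truth, protocols = defaultProtocols(),
                            noiseSd = 5, seed = 1) {
  stopifnot(is(truth, "PhantomTruth"))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  need <- c("T1w", "PDw", "MTw")
  if (!all(need %in% names(protocols)))
    stop("protocols must cover T1w, PDw and MTw")
  set.seed(seed)
  d <- dim(truth@labelProb)[1:3]
  K <- dim(truth@labelProb)[4]
  eff <- attr(truth, "effect")
  out <- list()
  for (w in need) {
    proto <- protocols[[w]]
    delta <- if (proto@mtPulse) truth@params$MTsat / 100 else rep(0, K)
    deltaL <- if (length(eff) && proto@mtPulse) eff$params$MTsat / 100 else delta
    echoes <- vector("list", length(proto@TEList))
    for (e in seq_along(proto@TEList)) {
      TE <- proto@TEList[e]
      base <- array(0, d)
      for (k in seq_len(K))
        base <- base + truth@labelProb[, , , k] *
          spgrSignal(truth@params$A[k], truth@params$R1[k], truth@params$R2s[k],
                     delta[k], proto, TE)
      if (length(eff)) {
        les <- array(0, d)
        for (k in seq_len(K))
          les <- les + truth@labelProb[, , , k] *
            spgrSignal(eff$params$A[k], eff$params$R1[k], eff$params$R2s[k],
                       deltaL[k], proto, TE)
        base <- (1 - eff$window) * base + eff$window * les
      }
      vol <- base * truth@bias[[w]]
      if (noiseSd > 0) vol <- vol + array(stats::rnorm(prod(d), 0, noiseSd), d)
      echoes[[e]] <- vol
    }
    attr(echoes, "TE") <- proto@TEList
    out[[w]] <- echoes
  }
  attr(out, "protocols") <- protocols[need]
  out
}

#' Simulate a control/patient cohort with linked clinical scores
#'
#' Patients receive the [groupEffect()] scaled by a per-subject severity drawn
#' from U(0.5, 1.5); their clinical scores follow a truncated linear link
#' `score = s0 - slope * magnitude + noise`, where the magnitude is the
#' realized mean MT-saturation reduction (p.u.) over the effect region.
#' Controls carry no effect and no injury scores.
#'
#' @param nControl,nPatient group sizes (each >= 2).
#' @param config a [phantomConfig()].
#' @param effect a [groupEffect()]; `NULL` simulates a null cohort.
#' @param clinicalLink list with elements `s0` (named baseline per score),
#'   `slope` (points per p.u. of regional MT reduction) and `noiseSd`.
#' @param seed integer RNG seed.
#' @param simulateEchoes if `FALSE`, only ground truth is generated (fast
#'   path for morphometry-only studies).
#' @param noiseSd additive signal noise sd; defaults to `config$noiseSd`.
#' @return list of class `qmriCohort`: per-subject entries with `group`,
#'   `truth`, optional `echoes`, `covariates`, `scores`; plus `config`.
#' @export
simulateCohort <- function(nControl, nPatient, config = phantomConfig(),
                           effect = groupEffect(config),
                           clinicalLink = list(
                             s0 = c(lems = 25, uems = 45, pp = 65, lt = 75, scim = 65),
                             slope = 30, noiseSd = 5),
                           seed = 1, simulateEchoes = TRUE,
                           noiseSd = config$noiseSd) {
  stopifnot(nControl >= 2, nPatient >= 2)
  bounds <- list(lems = c(0, 50), uems = c(0, 50), pp = c(0, 112),
                 lt = c(0, 112), scim = c(0, 100))
  set.seed(seed)
  sev <- stats::runif(nPatient, 0.5, 1.5)
  template <- phantomTemplate(config)
  subjects <- list()
  for (i in seq_len(nControl + nPatient)) {
    patient <- i > nControl
    sseed <- (seed * 1000L + i) %% .Machine$integer.max
    truth <- makePhantom(config, seed = sseed,
                         effect = if (patient) effect else NULL,
                         severity = if (patient) sev[i - nControl] else 1,
                         template = template)
    set.seed(sseed + 1L)
    cov <- list(age = if (patient) stats::runif(1, 19, 73) else stats::runif(1, 24, 66),
                tiv = stats::rnorm(1, 1450, 130),
                scanner = stats::rbinom(1, 1, 0.5))
    scores <- NULL
    if (patient) {
      eff <- attr(truth, "effect")
      tm <- truthParameterMaps(truth)
      baseMT <- array(0, dim(truth@mask))
      for (k in seq_len(config$K))
        baseMT <- baseMT + truth@labelProb[, , , k] * truth@params$MTsat[k]
      mag <- mean((baseMT - tm$MTsat)[effect$mask])   # realized p.u. reduction
      scores <- lapply(names(bounds), function(nm) {
        raw <- clinicalLink$s0[[nm]] - clinicalLink$slope * mag +
          stats::rnorm(1, 0, clinicalLink$noiseSd)
        min(max(raw, bounds[[nm]][1]), bounds[[nm]][2])
      })
      names(scores) <- names(bounds)
      scores$magnitude <- mag
    }
    echoes <- if (simulateEchoes)
      simulateSubject(truth, noiseSd = noiseSd, seed = sseed + 2L) else NULL
    subjects[[i]] <- list(id = i, group = if (patient) "patient" else "control",
                          truth = truth, echoes = echoes,
                          covariates = cov, scores = scores)
  }
  structure(list(subjects = subjects, config = config, effect = effect,
                 clinicalLink = clinicalLink, seed = seed),
            class = "qmriCohort")
}

#' @export
print.qmriCohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("qmriCohort: %d controls, %d patients, grid %s\n",
              sum(grp == "control"), sum(grp == "patient"),
              paste(x$config$grid, collapse = "x")))
  invisible(x)
}
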