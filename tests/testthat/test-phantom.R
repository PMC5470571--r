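test_that("spgr signal matches the closed form and its limits", {
  p <- defaultProtocols()
  ## direct evaluation of the closed form (frozen oracle value)
  expect_equal(spgrSignal(1000, 1.0, 0, 0, p$T1w, TE = 0), 94.37438,
               tolerance = 1e-6)
  ## saturation limit: TR >> T1 drives E1 -> 0, S -> A sin(alpha)
  long <- acquisitionProtocol("T1w", TR = 10, flipDeg = 23, TE = 0.01)
  expect_equal(spgrSignal(1000, 1.0, 0, 0, long, TE = 0),
               1000 * sin(23 * pi / 180), tolerance = 1e-4)
  ## vanishing flip angle drives the signal to zero
  smallFlip <- acquisitionProtocol("T1w", TR = 0.025, flipDeg = 1e-4, TE = 0.01)
  expect_lt(spgrSignal(1000, 1.0, 0, 0, smallFlip, TE = 0), 1e-2)
})

test_that("spgr signal rejects invalid inputs", {
  p <- defaultProtocols()
  expect_error(spgrSignal(-1, 1, 0, 0, p$T1w, 0), "positive")
  expect_error(spgrSignal(1000, 0, 0, 0, p$T1w, 0), "positive")
  expect_error(spgrSignal(1000, 1, 0, 0, p$T1w, 0.003), "echo times")
  expect_error(spgrSignal(1000, 1, 0, 0.01, p$T1w, 0), "MT pulse")
})

test_that("spgr signal is monotone in TE, R2s and MT saturation", {
  p <- defaultProtocols()
  sTE <- vapply(p$MTw@TEList, function(te)
    spgrSignal(1000, 1, 20, 0.02, p$MTw, te), numeric(1))
  expect_true(all(diff(sTE) < 0))
  sR2 <- vapply(c(0, 10, 20, 40), function(r2)
    spgrSignal(1000, 1, r2, 0.02, p$MTw, p$MTw@TEList[3]), numeric(1))
  expect_true(all(diff(sR2) < 0))
  sD <- vapply(c(0, 0.01, 0.02, 0.05), function(d)
    spgrSignal(1000, 1, 20, d, p$MTw, p$MTw@TEList[1]), numeric(1))
  expect_true(all(diff(sD) < 0))
  ## MTw signal never exceeds the delta = 0 equivalent
  expect_lt(spgrSignal(1000, 1, 20, 0.02, p$MTw, p$MTw@TEList[1]),
            spgrSignal(1000, 1, 20, 0, p$MTw, p$MTw@TEList[1]))
})

test_that("makePhantom is deterministic and conserves probability", {
  cfg <- tinyConfig()
  tmpl <- cachedTemplate(cfg, "tinyTmpl")
  t1 <- makePhantom(cfg, seed = 42, template = tmpl)
  t2 <- makePhantom(cfg, seed = 42, template = tmpl)
  expect_identical(labelProbabilities(t1), labelProbabilities(t2))
  expect_identical(t1@params, t2@params)
  expect_identical(displacement(t1@deformation), displacement(t2@deformation))
  s <- qmriMorph:::sumOverClasses(labelProbabilities(t1))
  expect_lt(max(abs(s - 1)), 1e-9)
  expect_true(all(jacobianMap(t1@deformation) > 0))
  for (b in t1@bias) expect_true(all(b > 0))
})

test_that("two-class phantom yields exactly two classes summing to one", {
  cfg <- tinyConfig(K = 2)
  t1 <- makePhantom(cfg, seed = 1)
  expect_equal(dim(labelProbabilities(t1))[4], 2L)
  s <- qmriMorph:::sumOverClasses(labelProbabilities(t1))
  expect_lt(max(abs(s - 1)), 1e-9)
})

test_that("every default class occupies at least 1% of the brainstem mask", {
  cfg <- phantomConfig()
  truth <- makePhantom(cfg, seed = 3)
  lab <- array(max.col(matrix(labelProbabilities(truth), ncol = cfg$K)),
               cfg$grid)
  inm <- brainstemMask(truth)
  frac <- tabulate(lab[inm], nbins = cfg$K) / sum(inm)
  expect_true(all(frac >= 0.01))
})

test_that("noiseless single-tissue voxels reproduce the closed-form signal", {
  ## hard class boundaries so genuinely pure voxels exist
  cfg <- tinyConfig(softEdgeSigma = 0, biasAmplitude = 0, warpAmplitude = 0,
                    noiseSd = 0)
  truth <- makePhantom(cfg, seed = 7)
  ech <- simulateSubject(truth, noiseSd = 0, seed = 1)
  ## a deep-interior voxel that is pure tegmentum
  pure <- which(labelProbabilities(truth)[, , , 1] > 1 - 1e-6)[1]
  expect_false(is.na(pure))
  p <- defaultProtocols()
  prm <- tissueParams(truth)
  for (e in c(1L, 4L, 8L)) {
    expected <- spgrSignal(prm$A[1], prm$R1[1], prm$R2s[1], 0, p$PDw,
                           p$PDw@TEList[e])
    expect_equal(ech$PDw[[e]][pure], expected, tolerance = 1e-9)
  }
  ## log signal across the PDw echoes is exactly linear with slope -R2*
  sig <- vapply(ech$PDw, function(v) v[pure], numeric(1))
  slope <- stats::coef(stats::lm(log(sig) ~ p$PDw@TEList))[2]
  expect_equal(unname(slope), -prm$R2s[1], tolerance = 1e-6)
})

test_that("additive noise has the configured standard deviation", {
  cfg <- tinyConfig(biasAmplitude = 0, warpAmplitude = 0)
  truth <- makePhantom(cfg, seed = 9, template = cachedTemplate(cfg, "tinyTmpl0b"))
  clean <- simulateSubject(truth, noiseSd = 0, seed = 1)
  noisy <- simulateSubject(truth, noiseSd = 5, seed = 1)
  dif <- c(noisy$PDw[[1]] - clean$PDw[[1]], noisy$PDw[[2]] - clean$PDw[[2]],
           noisy$T1w[[1]] - clean$T1w[[1]])
  expect_gt(length(dif), 1e5)
  expect_equal(stats::sd(dif), 5, tolerance = 0.02)
})

test_that("a null group effect leaves patient truth identical to control truth", {
  cfg <- tinyConfig(noiseSd = 0)
  d <- cfg$grid
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2, 0.35 * d[3])
  nullEff <- groupEffect(cfg, nVoxels = 150, center = ctr, volumeScale = 1,
                         mtsatShift = 0, r1Shift = 0, r2sShift = 0)
  tmpl <- cachedTemplate(cfg, "tinyTmplN")
  a <- makePhantom(cfg, seed = 5, template = tmpl)
  b <- makePhantom(cfg, seed = 5, effect = nullEff, template = tmpl)
  expect_equal(labelProbabilities(a), labelProbabilities(b), tolerance = 1e-12)
  ta <- truthParameterMaps(a); tb <- truthParameterMaps(b)
  expect_equal(ta$MTsat, tb$MTsat, tolerance = 1e-12)
})

test_that("regional volume scaling is reflected in the Jacobian integral", {
  ## isolate the contraction mechanism: no random subject deformation
  cfg <- phantomConfig(warpAmplitude = 0, noiseSd = 0)
  eff <- groupEffect(cfg, nVoxels = 500, volumeScale = 0.8,
                     mtsatShift = 0, r1Shift = 0)
  truth <- makePhantom(cfg, seed = 2, effect = eff)
  jint <- sum(jacobianMap(truth@deformation)[eff$mask])
  expect_equal(jint / sum(eff$mask), 0.8, tolerance = 0.02)
})

test_that("group-effect validation rejects bad regions and scales", {
  cfg <- tinyConfig()
  expect_error(groupEffect(cfg, volumeScale = 0.4), "volumeScale")
  expect_error(groupEffect(cfg, nVoxels = 200, center = c(2, 2, 24)),
               "inside the brainstem")
})

test_that("cohorts are reproducible and clinical scores obey their bounds", {
  cfg <- tinyConfig(noiseSd = 0)
  d <- cfg$grid
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2, 0.35 * d[3])
  eff <- groupEffect(cfg, nVoxels = 150, center = ctr)
  c1 <- simulateCohort(2, 3, config = cfg, effect = eff, seed = 11,
                       simulateEchoes = FALSE)
  c2 <- simulateCohort(2, 3, config = cfg, effect = eff, seed = 11,
                       simulateEchoes = FALSE)
  expect_identical(lapply(c1$subjects, function(s) s$scores),
                   lapply(c2$subjects, function(s) s$scores))
  expect_identical(labelProbabilities(c1$subjects[[5]]$truth),
                   labelProbabilities(c2$subjects[[5]]$truth))
  for (s in c1$subjects) {
    if (s$group == "control") { expect_null(s$scores); next }
    expect_true(s$scores$lems >= 0 && s$scores$lems <= 50)
    expect_true(s$scores$scim >= 0 && s$scores$scim <= 100)
    expect_true(s$scores$pp >= 0 && s$scores$pp <= 112)
  }
})

test_that("a zero clinical slope decouples scores from effect magnitude", {
  cfg <- tinyConfig(noiseSd = 0)
  d <- cfg$grid
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2, 0.35 * d[3])
  eff <- groupEffect(cfg, nVoxels = 150, center = ctr)
  coh <- simulateCohort(2, 12, config = cfg, effect = eff, seed = 21,
                        clinicalLink = list(
                          s0 = c(lems = 25, uems = 45, pp = 65, lt = 75, scim = 65),
                          slope = 0, noiseSd = 5),
                        simulateEchoes = FALSE)
  pat <- Filter(function(s) s$group == "patient", coh$subjects)
  mag <- vapply(pat, function(s) s$scores$magnitude, numeric(1))
  scim <- vapply(pat, function(s) s$scores$scim, numeric(1))
  expect_lt(abs(stats::cor(mag, scim)), 2 / sqrt(length(pat)))
})
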