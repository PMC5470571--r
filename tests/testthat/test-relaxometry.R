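makeSeries <- function(S0, R2s, TE, dims = c(4, 4, 4), noiseSd = 0) {
  out <- lapply(TE, function(te) {
    v <- array(S0 * exp(-R2s * te), dims)
    if (noiseSd > 0) v <- v + array(stats::rnorm(prod(dims), 0, noiseSd), dims)
    v
  })
  attr(out, "TE") <- TE
  out
}

test_that("echo averaging equals the direct mean and tracks effective TE", {
  te <- seq(2.46, 14.76, by = 2.46) / 1000
  ## two identical volumes average to themselves
  s <- makeSeries(50, 0, te[1:2])
  expect_equal(averageEchoes(s, 1:2), s[[1]], ignore_attr = TRUE)
  ## direct-summation oracle on a mono-exponential decay
  s2 <- makeSeries(100, 20, te)
  oracle <- mean(100 * exp(-20 * te))
  avg <- averageEchoes(s2, 1:6)
  expect_equal(avg[1, 1, 1], oracle, tolerance = 1e-12)
  expect_equal(attr(avg, "effectiveTE"), mean(te))
  expect_error(averageEchoes(s2[1], 1), "at least 2 echoes")
})

test_that("averaging reduces noise by the square root of the echo count", {
  set.seed(31)
  te <- seq(2.46, 14.76, by = 2.46) / 1000
  dims <- c(48, 48, 48)
  s <- makeSeries(100, 0, te, dims = dims, noiseSd = 3)
  avg <- averageEchoes(s, 1:6)
  expect_gt(prod(dims), 1e5)
  expect_equal(stats::sd(avg - 100), 3 / sqrt(6), tolerance = 0.03)
})

test_that("R2* fitting is exact on noiseless mono-exponential input", {
  te <- defaultProtocols()$PDw@TEList
  for (r2s in c(0, 1, 20, 75, 200)) {
    fit <- fitR2star(makeSeries(100, r2s, te))
    expect_equal(max(abs(fit$R2s - r2s)), 0, tolerance = 1e-9 * max(r2s, 1))
    expect_equal(fit$S0[1, 1, 1], 100, tolerance = 1e-9 * 100)
  }
  ## constant echoes decay at rate zero
  expect_equal(max(abs(fitR2star(makeSeries(50, 0, te))$R2s)), 0,
               tolerance = 1e-12)
})

test_that("R2* fitting masks non-positive voxels and stays calibrated under noise", {
  te <- defaultProtocols()$PDw@TEList
  s <- makeSeries(100, 20, te)
  s[[3]][1, 1, 1] <- -1
  fit <- fitR2star(s)
  expect_equal(fit$nFlagged, 1L)
  expect_true(is.na(fit$R2s[1, 1, 1]))
  ## Monte-Carlo calibration: mean estimate over many replicate voxels
  set.seed(17)
  sn <- makeSeries(100, 20, te, dims = c(22, 22, 22), noiseSd = 1)
  fitn <- fitR2star(sn)
  expect_gt(sum(is.finite(fitn$R2s)), 1e4)
  expect_lt(abs(mean(fitn$R2s, na.rm = TRUE) - 20), 0.5)
})

test_that("dual-flip-angle estimation inverts its own rational model exactly", {
  p <- defaultProtocols()
  rational <- function(A, R1, proto)
    A * proto@flipAngle * proto@TR * R1 / (proto@TR * R1 + proto@flipAngle^2 / 2)
  for (r1 in c(0.25, 1, 2)) {
    est <- estimateR1Amplitude(array(rational(1000, r1, p$PDw), c(1, 1, 1)),
                               array(rational(1000, r1, p$T1w), c(1, 1, 1)),
                               p$PDw, p$T1w)
    expect_equal(est$R1[1], r1, tolerance = 1e-9)
    expect_equal(est$A[1], 1000, tolerance = 1e-9)
  }
  expect_error(estimateR1Amplitude(array(1, c(1, 1, 1)), array(1, c(1, 1, 1)),
                                   p$PDw, p$PDw), "flip angles")
})

test_that("R1 recovery from exact steady-state signals is within 2%", {
  p <- defaultProtocols()
  for (r1 in c(0.25, 0.5, 1.0, 2.0)) {
    spd <- spgrSignal(1000, r1, 0, 0, p$PDw, 0)
    st1 <- spgrSignal(1000, r1, 0, 0, p$T1w, 0)
    ## independent oracle: numeric root-finding on the exact signal ratio
    oracle <- stats::uniroot(function(r) {
      spgrSignal(1000, r, 0, 0, p$T1w, 0) / spgrSignal(1000, r, 0, 0, p$PDw, 0) -
        st1 / spd
    }, c(0.01, 10), tol = 1e-10)$root
    expect_equal(oracle, r1, tolerance = 1e-6)
    est <- estimateR1Amplitude(array(spd, c(1, 1, 1)), array(st1, c(1, 1, 1)),
                               p$PDw, p$T1w)
    expect_equal(est$R1[1], r1, tolerance = 0.02)
  }
  ## monotone recovery preserves ordering
  rec <- vapply(c(0.25, 2.0), function(r1) {
    estimateR1Amplitude(array(spgrSignal(1000, r1, 0, 0, p$PDw, 0), c(1, 1, 1)),
                        array(spgrSignal(1000, r1, 0, 0, p$T1w, 0), c(1, 1, 1)),
                        p$PDw, p$T1w)$R1[1]
  }, numeric(1))
  expect_lt(rec[1], rec[2])
})

test_that("MT saturation recovery meets the null, 5% and doubling contracts", {
  p <- defaultProtocols()
  est <- function(deltaPu, r1 = 1, A = 1000) {
    smt <- spgrSignal(A, r1, 0, deltaPu / 100, p$MTw, 0)
    spd <- spgrSignal(A, r1, 0, 0, p$PDw, 0)
    st1 <- spgrSignal(A, r1, 0, 0, p$T1w, 0)
    fit <- estimateR1Amplitude(array(spd, c(1, 1, 1)), array(st1, c(1, 1, 1)),
                               p$PDw, p$T1w)
    estimateMTsat(array(smt, c(1, 1, 1)), fit$A, fit$R1, p$MTw)$MTsat[1]
  }
  expect_lt(abs(est(0)), 0.05)                       # null saturation, p.u.
  expect_equal(est(2), 2, tolerance = 0.05)          # 5% relative at 2 p.u.
  expect_true(est(2) / est(1) > 1.9 && est(2) / est(1) < 2.1)
})

test_that("MT saturation masks non-positive MTw signal", {
  p <- defaultProtocols()
  out <- estimateMTsat(array(c(-5, 50), c(2, 1, 1)), array(1000, c(2, 1, 1)),
                       array(1, c(2, 1, 1)), p$MTw)
  expect_true(is.na(out$MTsat[1, 1, 1]))
  expect_false(is.na(out$MTsat[2, 1, 1]))
  expect_equal(out$nFlagged, 1L)
})

test_that("bias correction recovers a synthetic field and fixes the gauge", {
  d <- c(24, 24, 24)
  mask <- array(TRUE, d)
  base <- array(rep(c(50, 100), each = prod(d) / 2), d)   # piecewise constant
  ## identity input: field within 1% of one everywhere
  bc0 <- correctBias(base, mask, basisOrder = 2)
  expect_lt(max(abs(bc0$field - 1)), 0.01)
  expect_equal(mean(bc0$field[mask]), 1, tolerance = 1e-6)
  ## +/-10% linear-gradient bias: within-class CV reduced by at least half
  g <- qmriMorph:::coordinateGrids(d)
  bias <- exp(0.1 * (2 * (g$x - 1) / (d[1] - 1) - 1))
  biased <- base * bias
  bc <- correctBias(biased, mask, basisOrder = 2)
  cvWithin <- function(m) {
    v1 <- m[base == 50]; v2 <- m[base == 100]
    mean(c(stats::sd(v1) / mean(v1), stats::sd(v2) / mean(v2)))
  }
  expect_lt(cvWithin(bc$corrected), 0.5 * cvWithin(biased))
  expect_equal(mean(bc$field[mask]), 1, tolerance = 1e-6)
})

test_that("quantitative maps are scale-equivariant and account for all voxels", {
  fx <- cleanSubject()
  qm <- fitQMaps(fx$echoes, brainstemMask(fx$truth))
  scaled <- fx$echoes
  for (w in names(scaled)) {
    te <- attr(scaled[[w]], "TE")
    scaled[[w]] <- lapply(scaled[[w]], function(v) v * 3)
    attr(scaled[[w]], "TE") <- te
  }
  attr(scaled, "protocols") <- attr(fx$echoes, "protocols")
  qs <- fitQMaps(scaled, brainstemMask(fx$truth))
  m <- brainstemMask(fx$truth)
  expect_equal(r1Map(qs)[m], r1Map(qm)[m], tolerance = 1e-9)
  expect_equal(r2sMap(qs)[m], r2sMap(qm)[m], tolerance = 1e-9)
  expect_equal(mtsatMap(qs)[m], mtsatMap(qm)[m], tolerance = 1e-9)
  expect_equal(amplitudeMap(qs)[m], 3 * amplitudeMap(qm)[m], tolerance = 1e-9)
  ## masked-voxel accounting: retained + flagged covers the mask
  expect_equal(sum(is.finite(r1Map(qm)[m])) + sum(m & !is.finite(r1Map(qm))),
               sum(m))
})

test_that("joint recovery on a noiseless phantom subject meets the error budget", {
  fx <- cleanSubject()
  qm <- fitQMaps(fx$echoes, brainstemMask(fx$truth))
  tm <- truthParameterMaps(fx$truth)
  ## evaluate on pure-tissue voxels; partial-volume voxels mix class signals
  ## and have no single true parameter value
  pure <- brainstemMask(fx$truth) &
    qmriMorph:::maxOverClasses(labelProbabilities(fx$truth)) > 0.99
  expect_gt(sum(pure), 1000)
  ok <- pure & is.finite(r1Map(qm))
  expect_lt(mean(abs(r1Map(qm)[ok] - tm$R1[ok]) / tm$R1[ok]), 0.02)
  expect_lt(mean(abs(mtsatMap(qm)[ok] - tm$MTsat[ok]) /
                   pmax(tm$MTsat[ok], 0.05)), 0.05)
  expect_lt(mean(abs(r2sMap(qm)[ok] - tm$R2s[ok])), 0.5)
})
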