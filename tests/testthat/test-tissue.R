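## independent brute-force Gaussian density (no shared code with eStep)
bruteDensity <- function(x, mu, Sigma) {
  C <- length(mu)
  xc <- x - mu
  exp(-0.5 * drop(t(xc) %*% solve(Sigma) %*% xc)) /
    sqrt((2 * pi)^C * det(Sigma))
}

## a reproducible 3-class 2-channel toy problem with 30 points
toyProblem <- function() {
  set.seed(99)
  means <- rbind(c(0, 0), c(3, 1), c(-1, 4))
  covs <- array(0, c(2, 2, 3))
  covs[, , 1] <- diag(2)
  covs[, , 2] <- matrix(c(1.5, 0.4, 0.4, 0.8), 2)
  covs[, , 3] <- matrix(c(0.7, -0.2, -0.2, 1.2), 2)
  x <- do.call(rbind, lapply(1:3, function(k) {
    L <- chol(covs[, , k])
    matrix(stats::rnorm(20), 10) %*% L + rep(means[k, ], each = 10)
  }))
  pri <- matrix(stats::runif(30 * 3, 0.1, 1), 30)
  pri <- pri / rowSums(pri)
  list(x = x, means = means, covs = covs, priors = pri)
}

test_that("brainstem extraction is exact bookkeeping", {
  v <- array(stats::runif(60), c(3, 4, 5))
  mask <- array(rep(c(TRUE, FALSE), 30), c(3, 4, 5))
  out <- extractBrainstem(v, mask)
  expect_equal(sum(!is.na(out)), sum(mask))
  expect_equal(attr(out, "nMasked"), sum(!mask))
  expect_equal(out[mask], v[mask])
  allIn <- extractBrainstem(v, array(TRUE, dim(v)))
  expect_equal(as.numeric(allIn), as.numeric(v))
  expect_error(extractBrainstem(v, array(FALSE, dim(v))), "empty mask")
})

test_that("responsibilities match a brute-force evaluation on the toy problem", {
  toy <- toyProblem()
  es <- eStep(toy$x, toy$means, toy$covs, toy$priors)
  for (i in c(1, 7, 16, 30)) {
    num <- vapply(1:3, function(k)
      toy$priors[i, k] * bruteDensity(toy$x[i, ], toy$means[k, ], toy$covs[, , k]),
      numeric(1))
    expect_equal(es$resp[i, ], num / sum(num), tolerance = 1e-10)
  }
  llBrute <- sum(log(vapply(1:30, function(i)
    sum(vapply(1:3, function(k)
      toy$priors[i, k] * bruteDensity(toy$x[i, ], toy$means[k, ], toy$covs[, , k]),
      numeric(1))), numeric(1))))
  expect_equal(es$logLik, llBrute, tolerance = 1e-10)
})

test_that("single-class and symmetric two-class E-steps are degenerate", {
  x <- matrix(stats::rnorm(20), 10)
  es1 <- eStep(x, matrix(0, 1, 2), array(diag(2), c(2, 2, 1)), rep(1, 1))
  expect_true(all(es1$resp == 1))
  expect_equal(es1$logLik,
               sum(stats::dnorm(x, log = TRUE)), tolerance = 1e-10)
  ## datum equidistant between two classes with equal priors and covariances
  es2 <- eStep(matrix(c(0.5, 0), 1), rbind(c(0, 0), c(1, 0)),
               array(rep(diag(2), 2), c(2, 2, 2)), c(0.5, 0.5))
  expect_equal(as.numeric(es2$resp), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("M-step reproduces weighted moments and respects the floor", {
  toy <- toyProblem()
  es <- eStep(toy$x, toy$means, toy$covs, toy$priors)
  ms <- mStep(toy$x, es$resp)
  for (k in 1:3) {
    wk <- es$resp[, k]
    expect_equal(ms$means[k, ], colSums(wk * toy$x) / sum(wk),
                 tolerance = 1e-10)
  }
  ## hard responsibilities give per-class sample means exactly
  hard <- matrix(0, 30, 3); hard[cbind(1:30, rep(1:3, each = 10))] <- 1
  msh <- mStep(toy$x, hard)
  expect_equal(msh$means[2, ], colMeans(toy$x[11:20, ]), tolerance = 1e-12)
  ## identical data collapse onto the covariance floor, not zero
  same <- matrix(1, 20, 2)
  msd <- mStep(same, matrix(1, 20, 1))
  ev <- eigen(msd$covariances[, , 1], only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("EM converges fast on a well-separated mixture initialized at truth", {
  set.seed(5)
  n <- 400
  truthLab <- rep(1:2, each = n / 2)
  x <- cbind(stats::rnorm(n, ifelse(truthLab == 1, 0, 8), 1),
             stats::rnorm(n, ifelse(truthLab == 1, 0, 8), 1))   # 8 sd apart
  init <- list(means = rbind(c(0, 0), c(8, 8)),
               covariances = array(rep(diag(2), 2), c(2, 2, 2)),
               mixing = c(0.5, 0.5))
  fit <- fitEM(list(x), K = 2, init = init, maxIter = 10, tol = 1e-8,
               updatePriors = FALSE)
  expect_lte(fit$iterations, 3)
  lab <- hardLabels(fit$responsibilities[[1]])
  expect_gte(mean(lab == truthLab), 0.99)
  expect_true(all(diff(fit$logLikTrace) >=
                  -1e-8 * abs(fit$logLikTrace[-length(fit$logLikTrace)])))
})

test_that("permuting the class initialization leaves the final likelihood unchanged", {
  toy <- toyProblem()
  runWith <- function(perm) {
    init <- list(means = toy$means[perm, ], covariances = toy$covs[, , perm],
                 mixing = rep(1 / 3, 3))
    fit <- fitEM(list(toy$x), K = 3, init = init, maxIter = 100, tol = 1e-10,
                 updatePriors = FALSE)
    max(fit$logLikTrace)
  }
  expect_equal(runWith(c(2, 3, 1)), runWith(1:3), tolerance = 1e-6)
})

test_that("prior updates average, floor and renormalize", {
  resp <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 3, 2, byrow = TRUE)
  expect_warning(one <- updateTPMs(list(resp)), "single subject")
  expect_equal(rowSums(one), rep(1, 3), tolerance = 1e-9)
  expect_equal(one[1, 1], (1 + 1e-4) / (1 + 2e-4), tolerance = 1e-12)
  ## complementary subjects average to a half/half prior
  two <- updateTPMs(list(resp, resp[, 2:1]))
  expect_equal(two[1, ], c(0.5, 0.5), tolerance = 1e-9)
  expect_true(all(abs(rowSums(two) - 1) < 1e-9))
})

test_that("merging with background classes conserves probability mass", {
  d <- c(6, 6, 6)
  bs <- array(0, c(d, 2)); bs[, , , 1] <- 0.7; bs[, , , 2] <- 0.3
  mask <- array(FALSE, d); mask[2:5, 2:5, 2:5] <- TRUE
  bg <- array(0, c(d, 1)); bg[, , , 1] <- ifelse(mask, 0, 1)
  merged <- mergeTPMs(bs, bg, mask)
  expect_equal(dim(merged)[4], 3L)
  s <- qmriMorph:::sumOverClasses(merged)
  expect_lt(max(abs(s - 1)), 1e-9)
  ## zero background inside the mask leaves brainstem classes unchanged
  expect_equal(merged[3, 3, 3, 1], 0.7, tolerance = 1e-12)
  ## checker pattern with partial background mass inside the mask
  bg2 <- array(0.2, c(d, 1))
  merged2 <- mergeTPMs(bs, bg2, mask)
  s2 <- qmriMorph:::sumOverClasses(merged2)
  expect_lt(max(abs(s2 - 1)), 1e-9)
  expect_equal(merged2[3, 3, 3, 1], 0.7 * 0.8, tolerance = 1e-12)
})

test_that("informative spatial priors beat uniform priors across seeds", {
  cfg <- tinyConfig(noiseSd = 2)
  tmpl <- cachedTemplate(cfg, "tinyTmplP")
  wins <- 0
  for (s in 1:10) {
    truth <- makePhantom(cfg, seed = 300 + s, template = tmpl)
    ech <- simulateSubject(truth, noiseSd = 2, seed = 400 + s)
    qm <- fitQMaps(ech, brainstemMask(truth))
    pdw <- averageEchoes(ech$PDw)
    m <- erodeMask(brainstemMask(truth), 2)
    sel <- which(m)
    dataM <- cbind(mtsatMap(qm)[sel], pdw[sel])
    dataM[!is.finite(dataM)] <- 0
    pri <- vapply(seq_len(cfg$K),
                  function(k) labelProbabilities(truth)[, , , k][sel],
                  numeric(length(sel)))
    fitI <- fitEM(list(dataM), K = cfg$K, priors = pri, init = "priors",
                  maxIter = 15, tol = 1e-7, updatePriors = FALSE,
                  covariance = "tied")
    fitU <- fitEM(list(dataM), K = cfg$K, priors = NULL, init = "kmeans",
                  maxIter = 15, tol = 1e-7, updatePriors = FALSE,
                  covariance = "tied", seed = s)
    ## compare final observed-data log-likelihoods under each prior field
    llI <- eStep(dataM, classMeans(fitI$model), classCovariances(fitI$model),
                 pri)$logLik
    llU <- eStep(dataM, classMeans(fitU$model), classCovariances(fitU$model),
                 matrix(1 / cfg$K, length(sel), cfg$K))$logLik
    wins <- wins + (llI >= llU)
  }
  expect_gte(wins, 8)
})
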