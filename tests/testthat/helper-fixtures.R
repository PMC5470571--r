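## shared fixtures: a small phantom configuration and cached templates so the
## expensive default-grid geometry is built at most once per test run

tinyConfig <- function(...) phantomConfig(grid = c(24L, 32L, 48L), ...)

.fixtureCache <- new.env(parent = emptyenv())

cachedTemplate <- function(config, key) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, qmriMorph:::phantomTemplate(config), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

## noiseless tiny subject with no bias and no random warp (shared by several
## relaxometry tests)
cleanSubject <- function() {
  if (!exists("cleanSubj", envir = .fixtureCache)) {
    cfg <- tinyConfig(biasAmplitude = 0, warpAmplitude = 0, noiseSd = 0)
    truth <- makePhantom(cfg, seed = 7, template = cachedTemplate(cfg, "tinyTmpl0"))
    ech <- simulateSubject(truth, noiseSd = 0, seed = 1)
    assign("cleanSubj", list(cfg = cfg, truth = truth, echoes = ech),
           envir = .fixtureCache)
  }
  get("cleanSubj", envir = .fixtureCache)
}

fixturePath <- function() system.file("extdata", "table1_cohort.csv",
                                      package = "qmriMorph")

## fully intact ISNCSCI exam, to be degraded per test
intactExam <- function() {
  derm <- sensoryDermatomes()
  list(lt = stats::setNames(rep(2, length(derm)), derm),
       pp = stats::setNames(rep(2, length(derm)), derm),
       motor = stats::setNames(rep(5, length(keyMyotomes())), keyMyotomes()))
}
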