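geo20 <- FeatureMapGeometry(20)

test_that("the L1 parameter gap matches hand arithmetic and is symmetric", {
  gt <- BBox(1, 1, 0.5, 0.5)
  pred <- BBox(7, 1, 1, 2)
  expect_equal(l1Gap(gt, pred), 6 + 0 + 0.5 + 1.5)
  expect_equal(l1Gap(gt, gt), 0)
  expect_equal(l1Gap(pred, gt), l1Gap(gt, pred))
})

test_that("a gradient step leaves the optimum fixed", {
  b <- BBox(5, 5, 2, 3)
  for (nm in c("giou", "siou", "smpdiou")) {
    b2 <- gdStep(nm, b, b, geometry = geo20)
    expect_equal(as.data.frame(b2), as.data.frame(b), label = nm)
  }
})

test_that("small steps never increase the loss (descent direction)", {
  set.seed(31)
  gt <- randomBoxes(50); pred <- randomBoxes(50)
  for (nm in lossNames()) {
    spec <- lossSpec(nm, if (nm %in% c("mpdiou", "smpdiou")) geo20)
    before <- lossAndGradient(spec, gt, pred)$loss
    stepped <- gdStep(spec, gt, pred, learningRate = 1e-6)
    after <- lossAndGradient(spec, gt, stepped)$loss
    expect_true(all(after <= before + 1e-12), label = nm)
  }
})

test_that("an S-MPDIoU step is the unit-scale step at scale-times the rate", {
  # disjoint regime: the IoU term is flat, so the update is purely the
  # penalty's and the scale constant is interchangeable with the rate
  gt <- BBox(1, 1, 0.5, 0.5); pred <- BBox(7, 7, 1, 2)
  s <- scaleFactor(geo20)
  full <- gdStep("smpdiou", gt, pred, learningRate = 0.02, geometry = geo20)
  p <- smpdiou:::.pairmats(gt, pred)
  unitGrad <- smpdiou:::.metricGrad("smpdiou", p$A, p$B, W = 20, H = 20,
                                    fixed = list(scale = 1))$grad
  manual <- smpdiou:::.boxmat(pred) + 0.02 * s * unitGrad
  expect_equal(unname(smpdiou:::.boxmat(full)), unname(manual),
               tolerance = 1e-14)
})

test_that("a case starting at the ground truth converges at epoch zero", {
  gt <- BBox(1, 1, 0.5, 0.5)
  r <- runCase("smpdiou", gt, gt, geometry = geo20)
  expect_identical(convergedEpochs(r), 0L)
})

test_that("S-MPDIoU converges in the diagonal case where GIoU struggles", {
  gt <- BBox(1, 1, 0.5, 0.5); pred0 <- BBox(7, 7, 1, 2)
  geo <- FeatureMapGeometry(10)
  cfg <- simConfig(learningRate = 0.02, maxEpochs = 20000L, threshold = 0.01)
  rs <- runCase("smpdiou", gt, pred0, cfg, geometry = geo)
  es <- convergedEpochs(rs)
  expect_false(is.na(es))
  rg <- runCase("giou", gt, pred0, cfg, geometry = geo)
  eg <- convergedEpochs(rg)
  expect_true(is.na(eg) || eg > 5 * es)
})

test_that("transposing a whole configuration transposes its trajectory", {
  # x/y symmetry of every loss on a square canvas: swapping the two axes
  # of both boxes must give the identical convergence epoch
  geo <- FeatureMapGeometry(10)
  cfg <- simConfig(maxEpochs = 20000L, threshold = 0.01)
  gt <- BBox(1, 1, 0.5, 0.5)
  for (nm in c("eiou", "mpdiou", "smpdiou")) {
    r1 <- runCase(nm, gt, BBox(7, 1, 1, 2), cfg, geometry = geo)
    r2 <- runCase(nm, gt, BBox(1, 7, 2, 1), cfg, geometry = geo)
    expect_identical(convergedEpochs(r1), convergedEpochs(r2), label = nm)
  }
})

test_that("experiment 1 reports per-case epochs and speedups", {
  cfg <- simConfig(maxEpochs = 50000L, threshold = 0.01)
  e1 <- experiment1(c("mpdiou", "smpdiou"), config = cfg)
  expect_setequal(e1$case, rep(c("horizontal", "diagonal", "vertical"), 2))
  expect_true(all(!is.na(e1$convergedEpoch)))
  sp <- speedupRatios(e1, "mpdiou")
  expect_true(all(sp$speedup[sp$loss == "mpdiou"] == 1))
  expect_true(all(sp$speedup[sp$loss == "smpdiou"] > 1))
})

test_that("the randomised population follows the stated recipe", {
  cs <- generateExperiment2Cases(40, seed = 5)
  expect_identical(length(cs$gt), 50L * 7L * 7L * 5L * 7L)   # 85,750
  expect_identical(length(cs$pred0), length(cs$gt))
  # all centers inside the stated circle
  R <- 20
  din <- function(b) sqrt((boxX(b) - R)^2 + (boxY(b) - R)^2)
  expect_true(all(din(cs$gt) <= R + 1e-9))
  expect_true(all(din(cs$pred0) <= R + 1e-9))
  # every ground-truth box has area 1
  expect_true(all(abs(boxW(cs$gt) * boxH(cs$gt) - 1) < 1e-9))
  # the 7 x 7 pred grid: areas are the 7 scales
  areas <- sort(unique(round(boxW(cs$pred0) * boxH(cs$pred0), 9)))
  expect_equal(areas, c(0.5, 0.67, 0.75, 1, 1.33, 1.5, 2))
  # bit-reproducible from the seed
  cs2 <- generateExperiment2Cases(40, seed = 5)
  expect_identical(as.data.frame(cs$pred0), as.data.frame(cs2$pred0))
  cs3 <- generateExperiment2Cases(40, seed = 6)
  expect_false(identical(as.data.frame(cs$pred0), as.data.frame(cs3$pred0)))
})

test_that("population runs share initialisation and freeze converged cases", {
  cfg <- simConfig(maxEpochs = 400L, threshold = 0.5, seed = 9L)
  res <- experiment2(c("eiou", "smpdiou"), mapSize = 20, config = cfg,
                     nCases = 150)
  c1 <- gapCurve(res$eiou); c2 <- gapCurve(res$smpdiou)
  expect_identical(c1[1], c2[1])          # same initial population
  expect_true(all(is.finite(c1)) && all(is.finite(c2)))
  # frozen cases keep a final gap below the threshold
  for (r in res) {
    conv <- !is.na(convergedEpochs(r))
    if (any(conv)) expect_true(all(finalGaps(r)[conv] < 0.5))
    expect_true(all(convergedEpochs(r)[conv] <= 400L))
  }
})

test_that("frozen parameters never change after convergence", {
  set.seed(13)
  G <- cbind(runif(5, 8, 12), runif(5, 8, 12), 1, 1)
  P0 <- G + cbind(runif(5, 0.3, 0.8), runif(5, 0.3, 0.8), 0.2, 0.2)
  r <- smpdiou:::.runPopulation("smpdiou", G, P0, W = 20, H = 20,
                                scaleVal = 5, maxEpochs = 300L,
                                threshold = 0.5, trajectory = TRUE)
  for (i in seq_len(5)) {
    e <- r$convergedEpoch[i]
    if (!is.na(e) && e < 300L) {
      later <- vapply(r$trajectory[(e + 1L):301L],
                      function(M) all(M[i, ] == r$trajectory[[e + 1L]][i, ]),
                      TRUE)
      expect_true(all(later))
    }
  }
})

test_that("total-gap curves are finite and non-increasing over windows", {
  cfg <- simConfig(maxEpochs = 1200L, threshold = 0.5, seed = 21L)
  res <- experiment2(c("diou", "smpdiou"), mapSize = 20, config = cfg,
                     nCases = 200)
  for (r in res) {
    cv <- gapCurve(r)
    expect_true(all(is.finite(cv)))
    # windowed monotonicity with a small allowance for transient
    # shape-growth phases
    w <- 500L
    idx <- seq_len(length(cv) - w)
    expect_true(all(cv[idx + w] <= cv[idx] * 1.02 + 1e-9))
  }
})
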