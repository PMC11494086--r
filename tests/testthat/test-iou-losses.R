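geo20 <- FeatureMapGeometry(20)
geo40 <- FeatureMapGeometry(40)

test_that("every metric equals exactly 1 on identical boxes", {
  b <- BBox(5, 5, 2, 3)
  for (nm in lossNames())
    expect_identical(iouMetric(nm, b, b, geo20), 1, label = nm)
})

test_that("GIoU matches hand arithmetic and stays in (-1, 1]", {
  d1 <- boxFromCorners(c(4, 4), c(6, 6))
  d2 <- boxFromCorners(c(8, 4), c(10, 6))
  expect_equal(giou(d1, d2), -1 / 3)
  a <- boxFromCorners(c(0, 0), c(2, 2))
  b <- boxFromCorners(c(1, 1), c(3, 3))
  expect_equal(giou(a, b), 1 / 7 - 2 / 9)
  set.seed(11)
  r1 <- randomBoxes(200); r2 <- randomBoxes(200)
  g <- giou(r1, r2)
  expect_true(all(g > -1 & g <= 1))
})

test_that("DIoU penalises center distance and reduces to IoU when concentric", {
  d1 <- boxFromCorners(c(4, 4), c(6, 6))
  d2 <- boxFromCorners(c(8, 4), c(10, 6))
  expect_equal(diou(d1, d2), -0.4)
  conc1 <- BBox(5, 5, 2, 2); conc2 <- BBox(5, 5, 4, 3)
  expect_equal(diou(conc1, conc2), boxIoU(conc1, conc2))
})

test_that("CIoU folds the aspect-consistency term", {
  # equal aspect ratio (both square): nu = 0, so ciou == diou
  s1 <- BBox(3, 4, 2, 2); s2 <- BBox(6, 5, 5, 5)
  expect_equal(ciou(s1, s2), diou(s1, s2))
  # gt 2x1 vs pred 1x2, same center: nu = (4/pi^2)(atan 2 - atan 1/2)^2
  nu <- 0.1678258    # frozen from independent scalar evaluation
  gt <- BBox(0, 0, 2, 1); pr <- BBox(0, 0, 1, 2)
  iouV <- 1 / 3                       # overlap 1, union 3
  alpha <- nu / (1 - iouV + nu)
  expect_equal(ciou(gt, pr), iouV - alpha * nu, tolerance = 1e-5)
})

test_that("EIoU adds width/height gap terms to DIoU", {
  d1 <- boxFromCorners(c(4, 4), c(6, 6))
  d2 <- boxFromCorners(c(8, 4), c(10, 6))
  expect_equal(eiou(d1, d2), diou(d1, d2))   # same-size boxes: terms vanish
  expect_equal(eiou(d1, d2), -0.4)
  # concentric 2x2 vs 4x4: IoU 1/4, each size term (2/4)^2
  c1 <- BBox(0, 0, 2, 2); c2 <- BBox(0, 0, 4, 4)
  expect_equal(eiou(c1, c2), 1 / 4 - 1 / 4 - 1 / 4)
  expect_equal(boxIoU(c1, c2), rasterIoU(c1, c2), tolerance = 1e-3)
})

test_that("SIoU reproduces the frozen golden value and its axis extremes", {
  a <- boxFromCorners(c(0, 0), c(2, 2))
  b <- boxFromCorners(c(1, 1), c(3, 3))
  expect_equal(siou(a, b), 0.037696460, tolerance = 1e-6)
  # centers aligned on the x axis: angle cost at its extremum, gamma = 2;
  # independent scalar evaluation of the reference formulas
  g <- BBox(2, 5, 2, 2); p <- BBox(8, 5, 2, 4)
  iouV <- boxIoU(g, p)
  cw <- 8; ch <- 4                       # enclosing box of the pair
  Delta <- (1 - exp(-2 * (6 / cw)^2)) + (1 - exp(-2 * 0))
  Omega <- (1 - exp(0))^4 + (1 - exp(-2 / 4))^4
  expect_equal(siou(g, p), iouV - (Delta + Omega) / 2)
})

test_that("MPDIoU normalises corner distances by the map diagonal", {
  d1 <- boxFromCorners(c(4, 4), c(6, 6))
  d2 <- boxFromCorners(c(8, 4), c(10, 6))
  expect_equal(mpdiou(d1, d2, geo20), 0 - 16 / 800 - 16 / 800)
  a <- boxFromCorners(c(0, 0), c(2, 2))
  b <- boxFromCorners(c(1, 1), c(3, 3))
  expect_equal(mpdiou(a, b, geo40), 1 / 7 - 2 / 3200 - 2 / 3200)
  expect_error(mpdiou(a, b), "geometry")
})

test_that("the center angle and baseline follow the angle branches", {
  expect_equal(smpdiouAlpha(BBox(5, 5, 1, 1), BBox(9, 5, 1, 1)), 0)
  expect_equal(smpdiouAlpha(BBox(1, 1, 1, 1), BBox(1, 7, 1, 1)), pi / 2)
  expect_equal(smpdiouAlpha(BBox(1, 1, 1, 1), BBox(7, 7, 1, 1)), pi / 4)
  expect_true(is.na(smpdiouAlpha(BBox(1, 1, 1, 1), BBox(1, 1, 2, 2))))

  expect_equal(smpdiouBaseline(0, geo20), 20)
  expect_equal(smpdiouBaseline(pi / 2, geo20), 20)
  expect_equal(smpdiouBaseline(pi / 4, geo20), sqrt(2) * 20)
  expect_equal(smpdiouBaseline(NA_real_, geo20), sqrt(800))
})

test_that("the scale factor is log2 of the downsampling ratio", {
  expect_identical(scaleFactor(FeatureMapGeometry(80)), 3)
  expect_identical(scaleFactor(geo40), 4)
  expect_identical(scaleFactor(geo20), 5)
  expect_identical(scaleFactor(FeatureMapGeometry(640)), 0)
  expect_error(scaleFactor(FeatureMapGeometry(1280)), "downsample")
})

test_that("S-MPDIoU matches hand arithmetic through the angle branches", {
  d1 <- boxFromCorners(c(4, 4), c(6, 6))
  d2 <- boxFromCorners(c(8, 4), c(10, 6))
  expect_equal(smpdiou(d1, d2, geo20), 0 - 5 * (16 / 400 + 16 / 400))
  a <- boxFromCorners(c(0, 0), c(2, 2))
  b <- boxFromCorners(c(1, 1), c(3, 3))
  expect_equal(smpdiou(a, b, geo40), 1 / 7 - 4 * (2 / 3200 + 2 / 3200))
})

test_that("S-MPDIoU with forced diagonal baseline and unit scale is MPDIoU", {
  set.seed(19)
  a <- randomBoxes(1000); b <- randomBoxes(1000)
  p <- smpdiou:::.pairmats(a, b)
  forced <- smpdiou:::.metricGrad("smpdiou", p$A, p$B, W = 20, H = 20,
                                  fixed = list(alpha = pi / 4, scale = 1),
                                  wantGrad = FALSE)$metric
  expect_equal(forced, mpdiou(a, b, geo20), tolerance = 1e-14)
})

test_that("no metric ever exceeds plain IoU", {
  set.seed(23)
  a <- randomBoxes(300); b <- randomBoxes(300)
  iouV <- boxIoU(a, b)
  for (nm in setdiff(lossNames(), "iou"))
    expect_true(all(iouMetric(nm, a, b, geo20) <= iouV + 1e-12), label = nm)
})

test_that("corner-distance metrics fall monotonically under radial retreat", {
  gt <- BBox(5, 5, 1, 1)
  for (dir in list(c(1, 0), c(0, 1), c(1, 1) / sqrt(2), c(2, 1) / sqrt(5))) {
    d <- seq(3, 12, by = 0.5)   # disjoint regime throughout
    pred <- BBox(5 + d * dir[1], 5 + d * dir[2], 1, 1)
    m <- mpdiou(gt, pred, geo20)
    s <- smpdiou(gt, pred, geo20)
    expect_true(all(diff(m) < 0))
    expect_true(all(diff(s) < 0))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  n <- 100
  G <- cbind(runif(n, 2, 18), runif(n, 2, 18), runif(n, 0.5, 6), runif(n, 0.5, 6))
  P <- cbind(runif(n, 2, 18), runif(n, 2, 18), runif(n, 0.5, 6), runif(n, 0.5, 6))
  for (nm in lossNames()) {
    sv <- if (nm == "smpdiou") scaleFactor(geo20) else NA_real_
    ga <- -smpdiou:::.metricGrad(nm, G, P, W = 20, H = 20,
                                 scaleVal = sv)$grad
    gf <- fdLossGradient(nm, G, P, geo20)
    rel <- abs(ga - gf) / pmax(abs(ga), abs(gf), 1)
    expect_lt(max(rel), 1e-4, label = nm)
  }
})

test_that("loss and gradient vanish at the optimum for every spec", {
  b <- BBox(5, 5, 2, 3)
  for (nm in lossNames()) {
    lg <- lossAndGradient(nm, b, b, geo20)
    expect_identical(lg$loss, 0, label = nm)
    expect_identical(max(abs(lg$gradient)), 0, label = nm)
  }
})

test_that("the scale factor is a pure constant multiplier of the penalty", {
  # disjoint pair: the IoU term is flat, so the whole gradient is the
  # penalty's and must scale linearly with the scale constant
  gt <- BBox(1, 1, 0.5, 0.5); pred <- BBox(7, 7, 1, 2)
  p <- smpdiou:::.pairmats(gt, pred)
  full <- smpdiou:::.metricGrad("smpdiou", p$A, p$B, W = 20, H = 20,
                                scaleVal = scaleFactor(geo20))
  unit <- smpdiou:::.metricGrad("smpdiou", p$A, p$B, W = 20, H = 20,
                                fixed = list(scale = 1))
  expect_equal(full$grad, scaleFactor(geo20) * unit$grad, tolerance = 1e-14)
})

test_that("loss specs validate their configuration", {
  expect_error(lossSpec("mpdiou"), "FeatureMapGeometry")
  expect_error(lossSpec("nosuch"))
  expect_s4_class(lossSpec("giou"), "LossSpec")
  expect_warning(FeatureMapGeometry(20, 40), "non-square")
})
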