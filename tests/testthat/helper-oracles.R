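# shared fixtures and independent oracles

# random valid boxes inside a frame (centers away from the border so the
# boxes stay inside)
randomBoxes <- function(n, frame = 20) {
  BBox(runif(n, 2, frame - 2), runif(n, 2, frame - 2),
       runif(n, 0.5, 6), runif(n, 0.5, 6))
}

# rasterisation IoU oracle: count grid-cell centers falling inside each
# box on an nGrid x nGrid lattice over the pair's union (enclosing) frame.
# Axis-aligned boxes make the count separable per axis, so the lattice is
# never materialised in 2-d.
rasterIoU <- function(a, b, nGrid = 3000) {
  ca <- corners(a); cb <- corners(b)
  fx <- range(ca$topLeft[, 1], ca$bottomRight[, 1],
              cb$topLeft[, 1], cb$bottomRight[, 1])
  fy <- range(ca$topLeft[, 2], ca$bottomRight[, 2],
              cb$topLeft[, 2], cb$bottomRight[, 2])
  gx <- fx[1] + (seq_len(nGrid) - 0.5) * diff(fx) / nGrid
  gy <- fy[1] + (seq_len(nGrid) - 0.5) * diff(fy) / nGrid
  inAxis <- function(g, lo, hi) sum(g >= lo & g <= hi)
  cellsIn <- function(cc) {
    inAxis(gx, cc$topLeft[1, 1], cc$bottomRight[1, 1]) *
      inAxis(gy, cc$topLeft[1, 2], cc$bottomRight[1, 2])
  }
  interX <- inAxis(gx, max(ca$topLeft[1, 1], cb$topLeft[1, 1]),
                   min(ca$bottomRight[1, 1], cb$bottomRight[1, 1]))
  interY <- inAxis(gy, max(ca$topLeft[1, 2], cb$topLeft[1, 2]),
                   min(ca$bottomRight[1, 2], cb$bottomRight[1, 2]))
  inter <- interX * interY
  inter / (cellsIn(ca) + cellsIn(cb) - inter)
}

# central finite-difference gradient of loss = 1 - metric w.r.t. the
# predicted box, independent of the analytic path.  Quantities that are
# constants by contract (CIoU's trade-off alpha) are pinned at the
# evaluation point so the oracle differentiates the same function.
fdLossGradient <- function(name, G, P, geometry = NULL, eps = 1e-5) {
  W <- if (is.null(geometry)) NA_real_ else mapWidth(geometry)
  H <- if (is.null(geometry)) NA_real_ else mapHeight(geometry)
  sv <- if (name == "smpdiou") scaleFactor(geometry) else NA_real_
  fixed <- list()
  if (name == "ciou") {
    iou0 <- smpdiou:::.metricGrad("iou", G, P, wantGrad = FALSE)$metric
    datan <- atan(G[, 3] / G[, 4]) - atan(P[, 3] / P[, 4])
    v <- 4 / pi^2 * datan^2
    fixed$ciouAlpha <- ifelse(v == 0, 0, v / (1 - iou0 + v))
  }
  f <- function(M) {
    1 - smpdiou:::.metricGrad(name, G, M, W = W, H = H, scaleVal = sv,
                              fixed = fixed, wantGrad = FALSE)$metric
  }
  g <- matrix(0, nrow(P), 4)
  for (j in 1:4) {
    Pp <- P; Pm <- P
    Pp[, j] <- Pp[, j] + eps; Pm[, j] <- Pm[, j] - eps
    g[, j] <- (f(Pp) - f(Pm)) / (2 * eps)
  }
  g
}

# small synthetic slide with known per-patch counts (fast fixture)
smallSlide <- function(seed, side = 192L, patch = 64L, nFoci = 2L) {
  set.seed(seed + 1000L)
  foci <- data.frame(
    x = runif(nFoci, 30, side - 30), y = runif(nFoci, 30, side - 30),
    radius = runif(nFoci, 15, 25), n = sample(20:60, nFoci, replace = TRUE))
  makeSyntheticSlide(side, side, foci = foci, cellSize = c(1.5, 3),
                     patchSize = patch, seed = seed)
}
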