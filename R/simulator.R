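#' Simulation configuration
#'
#' Settings for the gradient-descent box-regression simulator.  Plain
#' per-parameter gradient descent with a fixed learning rate is used
#' throughout (no momentum, no weight decay); a case counts as converged at
#' the first epoch where its L1 parameter gap ([l1Gap()]) drops below the
#' threshold, and converged cases are frozen by default (their parameters
#' stop updating; their residual gap still accumulates in the curve).
#'
#' @param learningRate positive step size (default 0.02).
#' @param maxEpochs positive integer epoch budget.
#' @param threshold positive convergence threshold on the L1 gap
#'   (0.01 for the three-case experiment, 0.5 for the population
#'   experiment).
#' @param freezeConverged logical, freeze cases once converged.
#' @param seed optional integer seed for case generation.
#' @return a list of class \code{"simConfig"}.
#' @export
simConfig <- function(learningRate = 0.02, maxEpochs = 100000L,
                      threshold = 0.01, freezeConverged = TRUE,
                      seed = NULL) {
  stopifnot(learningRate > 0, maxEpochs >= 1, threshold > 0)
  structure(list(learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs),
                 threshold = threshold,
                 freezeConverged = isTRUE(freezeConverged),
                 seed = seed),
            class = "simConfig")
}

# floor on predicted width/height after each step, preserving BBox validity
.SIZE_FLOOR <- 1e-4

#' One gradient-descent step on a predicted box
#'
#' Updates the predicted box by \eqn{\theta \leftarrow \theta -
#' lr \, \nabla_\theta (1 - m)} on its four parameters, using the analytic
#' gradient of [lossAndGradient()].  After the step, width and height are
#' clamped to a floor of \code{1e-4} so the box stays valid.
#'
#' @param spec a [LossSpec-class] or metric name.
#' @param gt ground-truth [BBox-class].
#' @param pred predicted [BBox-class].
#' @param learningRate positive step size.
#' @param geometry optional geometry when \code{spec} is a name.
#' @return the updated predicted [BBox-class].
#' @export
gdStep <- function(spec, gt, pred, learningRate = 0.02, geometry = NULL) {
  lg <- lossAndGradient(spec, gt, pred, geometry)
  m <- .boxmat(pred) - learningRate * lg$gradient
  m[, 3] <- pmax(m[, 3], .SIZE_FLOOR)
  m[, 4] <- pmax(m[, 4], .SIZE_FLOOR)
  .matbox(m)
}

# vectorised population runner.  G, P0: n x 4 matrices.  Returns converged
# epochs (NA if never), final parameters, final gaps, and the total-gap
# curve (index 1 = epoch 0) padded with its last value if every case froze
# before the budget ran out.
.runPopulation <- function(name, G, P0, W = NA_real_, H = NA_real_,
                           scaleVal = NA_real_, lr = 0.02,
                           maxEpochs = 100000L, threshold = 0.01,
                           freeze = TRUE, trajectory = FALSE) {
  n <- nrow(P0)
  P <- P0
  conv <- rep(NA_integer_, n)
  gap <- rowSums(abs(G - P))
  conv[gap < threshold] <- 0L
  curve <- numeric(maxEpochs + 1L)
  curve[1L] <- sum(gap)
  active <- if (freeze) is.na(conv) else rep(TRUE, n)
  traj <- if (trajectory) vector("list", maxEpochs + 1L)
  if (trajectory) traj[[1L]] <- P
  lastEpoch <- 0L
  for (e in seq_len(maxEpochs)) {
    if (!any(active)) break
    idx <- which(active)
    r <- .metricGrad(name, G[idx, , drop = FALSE], P[idx, , drop = FALSE],
                     W = W, H = H, scaleVal = scaleVal)
    if (any(!is.finite(r$grad)))
      stop("divergent case under loss '", name, "' at epoch ", e,
           ": non-finite gradient (first case index ",
           idx[which(!is.finite(rowSums(r$grad)))[1L]], ")", call. = FALSE)
    Pn <- P[idx, , drop = FALSE] + lr * r$grad   # descend on 1 - metric
    Pn[, 3] <- pmax(Pn[, 3], .SIZE_FLOOR)
    Pn[, 4] <- pmax(Pn[, 4], .SIZE_FLOOR)
    P[idx, ] <- Pn
    gap[idx] <- rowSums(abs(G[idx, , drop = FALSE] - Pn))
    hit <- idx[gap[idx] < threshold & is.na(conv[idx])]
    conv[hit] <- e
    if (freeze) active[hit] <- FALSE
    curve[e + 1L] <- sum(gap)
    if (trajectory) traj[[e + 1L]] <- P
    lastEpoch <- e
  }
  if (lastEpoch < maxEpochs)           # all cases frozen early
    curve[(lastEpoch + 2L):(maxEpochs + 1L)] <- curve[lastEpoch + 1L]
  list(convergedEpoch = conv, final = P, finalGap = gap, curve = curve,
       trajectory = if (trajectory) traj)
}

#' Optimise one regression case
#'
#' Runs plain gradient descent on a single (ground truth, initial
#' prediction) pair under the given loss, recording the first epoch at
#' which the L1 parameter gap falls below the threshold.
#'
#' @param spec a [LossSpec-class] or metric name.
#' @param gt ground-truth [BBox-class] (length 1).
#' @param pred0 initial predicted [BBox-class] (length 1).
#' @param config a [simConfig()] list.
#' @param geometry optional geometry when \code{spec} is a name.
#' @param trajectory logical; record the full parameter trajectory
#'   (one 1 x 4 matrix per epoch) for plotting.
#' @return a [SimResult-class] (with the trajectory in
#'   \code{config$trajectory} when requested).
#' @export
runCase <- function(spec, gt, pred0, config = simConfig(),
                    geometry = NULL, trajectory = FALSE) {
  if (is.character(spec)) spec <- lossSpec(spec, geometry)
  stopifnot(is(spec, "LossSpec"), length(gt) == 1L, length(pred0) == 1L)
  sa <- .specArgs(spec)
  r <- .runPopulation(spec@name, .boxmat(gt), .boxmat(pred0),
                      W = sa$W, H = sa$H, scaleVal = sa$scaleVal,
                      lr = config$learningRate, maxEpochs = config$maxEpochs,
                      threshold = config$threshold,
                      freeze = config$freezeConverged,
                      trajectory = trajectory)
  new("SimResult", lossName = spec@name, convergedEpoch = r$convergedEpoch,
      finalGap = r$finalGap, curve = r$curve,
      config = c(unclass(config), list(trajectory = r$trajectory)))
}

# the three fixed configurations: gt center [1,1] with w = h = 0.5;
# predicted box w = 1, h = 2 centered at [7,1], [7,7], [1,7]
.experiment1Cases <- function() {
  list(gt = BBox(1, 1, 0.5, 0.5),
       pred0 = BBox(c(7, 7, 1), c(1, 7, 7), 1, 2),
       case = c("horizontal", "diagonal", "vertical"))
}

#' Three-case convergence experiment
#'
#' Runs the three fixed box-regression configurations (horizontal,
#' diagonal, and vertical center alignment; ground truth centered at
#' \code{[1, 1]} with width and height 0.5, predicted box of width 1 and
#' height 2 centered at \code{[7, 1]}, \code{[7, 7]}, \code{[1, 7]}) under
#' each requested loss and reports the epoch at which each case converged.
#' The canvas is a 10 x 10 feature map with reference input 640 by default
#' (scale factor 6); both are configurable through \code{geometry}.
#'
#' @param losses character vector of metric names (default: the whole
#'   family).
#' @param config a [simConfig()]; defaults to learning rate 0.02,
#'   threshold 0.01, budget 100,000 epochs.
#' @param geometry the canvas [FeatureMapGeometry-class].
#' @return a data.frame with columns \code{loss}, \code{case},
#'   \code{convergedEpoch} (\code{NA} when the budget ran out) and
#'   \code{finalGap}.
#' @seealso [speedupRatios()]
#' @export
experiment1 <- function(losses = lossNames(),
                        config = simConfig(learningRate = 0.02,
                                           maxEpochs = 100000L,
                                           threshold = 0.01),
                        geometry = FeatureMapGeometry(10, inputRef = 640)) {
  losses <- vapply(losses, function(l) match.arg(l, lossNames()), "")
  cs <- .experiment1Cases()
  G <- .boxmat(cs$gt)[rep(1L, 3L), , drop = FALSE]
  P0 <- .boxmat(cs$pred0)
  out <- lapply(losses, function(nm) {
    sv <- if (nm == "smpdiou") scaleFactor(geometry) else NA_real_
    r <- .runPopulation(nm, G, P0, W = geometry@W, H = geometry@H,
                        scaleVal = sv, lr = config$learningRate,
                        maxEpochs = config$maxEpochs,
                        threshold = config$threshold,
                        freeze = config$freezeConverged)
    data.frame(loss = nm, case = cs$case,
               convergedEpoch = r$convergedEpoch, finalGap = r$finalGap)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convergence speedup ratios
#'
#' Per-case ratios \code{epochs(reference) / epochs(loss)} from an
#' [experiment1()] table: how many times faster each loss converged than
#' the reference.
#'
#' @param epochs data.frame as returned by [experiment1()].
#' @param reference reference loss name (default \code{"mpdiou"}).
#' @return a data.frame with columns \code{loss}, \code{case},
#'   \code{speedup} (\code{NA} where either run failed to converge).
#' @export
speedupRatios <- function(epochs, reference = "mpdiou") {
  stopifnot(reference %in% epochs$loss)
  ref <- epochs[epochs$loss == reference, c("case", "convergedEpoch")]
  names(ref)[2] <- "refEpoch"
  m <- merge(epochs, ref, by = "case", sort = FALSE)
  m$speedup <- m$refEpoch / m$convergedEpoch
  m[order(match(m$loss, lossNames())), c("loss", "case", "speedup")]
}

#' Generate the randomised regression population
#'
#' Builds the case population of the second convergence experiment on a
#' square feature map of side 20 or 40: inside the circle of radius
#' \code{mapSize / 2} centered on the map, 50 predicted-box centers and 5
#' ground-truth centers are drawn uniformly.  Ground-truth boxes have area
#' 1 with the 7 aspect ratios 7:1, 4:1, 2:1, 1:1, 1:2, 1:4, 1:7; predicted
#' boxes take the same 7 ratios and additionally 7 area scales 0.5, 0.67,
#' 0.75, 1, 1.33, 1.5, 2.  The full cross-product is returned:
#' \eqn{50 \cdot 7 \cdot 7 \cdot 5 \cdot 7 = 85{,}750} cases.
#'
#' @param mapSize 20 or 40.
#' @param seed integer seed; generation is bit-reproducible from it.
#' @return a list with \code{gt} and \code{pred0} ([BBox-class] of equal
#'   length), \code{geometry} (a [FeatureMapGeometry-class] with reference
#'   input 640), and bookkeeping vectors in \code{meta}.
#' @export
generateExperiment2Cases <- function(mapSize = c(40, 20), seed = 1L) {
  mapSize <- as.numeric(mapSize)[1L]
  stopifnot(mapSize %in% c(20, 40))
  set.seed(as.integer(seed))
  R <- mapSize / 2
  unifDisc <- function(n) {
    r <- R * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    cbind(x = R + r * cos(th), y = R + r * sin(th))
  }
  predC <- unifDisc(50L)
  gtC <- unifDisc(5L)
  ratios <- c(7, 4, 2, 1, 1 / 2, 1 / 4, 1 / 7)
  scales <- c(0.5, 0.67, 0.75, 1, 1.33, 1.5, 2)
  # cross product: pred center x pred ratio x pred scale x gt center x gt ratio
  idx <- expand.grid(gtRatio = seq_along(ratios), gtCenter = seq_len(5L),
                     scale = seq_along(scales), predRatio = seq_along(ratios),
                     predCenter = seq_len(50L))
  gtR <- ratios[idx$gtRatio]
  gt <- BBox(gtC[idx$gtCenter, 1L], gtC[idx$gtCenter, 2L],
             sqrt(gtR), sqrt(1 / gtR))
  pr <- ratios[idx$predRatio]; sc <- scales[idx$scale]
  pred0 <- BBox(predC[idx$predCenter, 1L], predC[idx$predCenter, 2L],
                sqrt(sc * pr), sqrt(sc / pr))
  list(gt = gt, pred0 = pred0,
       geometry = FeatureMapGeometry(mapSize, inputRef = 640),
       meta = idx)
}

#' Population convergence experiment
#'
#' Optimises the whole randomised case population under each requested
#' loss by vectorised gradient descent, freezing converged cases, and
#' records the per-epoch total L1 gap curve and the converged fraction.
#'
#' @param losses character vector of metric names.
#' @param mapSize 20 or 40 (passed to [generateExperiment2Cases()]).
#' @param config a [simConfig()]; defaults to learning rate 0.02,
#'   threshold 0.5, budget 10,000 epochs, with \code{config$seed}
#'   (default 42) seeding the population.
#' @param nCases optional case-count override for desk-scale runs: cases
#'   are subsampled deterministically (first \code{nCases} after a seeded
#'   shuffle).
#' @return a named list of [SimResult-class], one per loss.
#' @export
experiment2 <- function(losses = lossNames(), mapSize = 40,
                        config = simConfig(learningRate = 0.02,
                                           maxEpochs = 10000L,
                                           threshold = 0.5, seed = 42L),
                        nCases = NULL) {
  losses <- vapply(losses, function(l) match.arg(l, lossNames()), "")
  seed <- if (is.null(config$seed)) 42L else as.integer(config$seed)
  cases <- generateExperiment2Cases(mapSize, seed)
  G <- .boxmat(cases$gt); P0 <- .boxmat(cases$pred0)
  if (!is.null(nCases) && nCases < nrow(G)) {
    set.seed(seed)
    keep <- sample.int(nrow(G))[seq_len(nCases)]
    G <- G[keep, , drop = FALSE]; P0 <- P0[keep, , drop = FALSE]
  }
  geo <- cases$geometry
  res <- lapply(losses, function(nm) {
    sv <- if (nm == "smpdiou") scaleFactor(geo) else NA_real_
    r <- .runPopulation(nm, G, P0, W = geo@W, H = geo@H, scaleVal = sv,
                        lr = config$learningRate,
                        maxEpochs = config$maxEpochs,
                        threshold = config$threshold,
                        freeze = config$freezeConverged)
    new("SimResult", lossName = nm, convergedEpoch = r$convergedEpoch,
        finalGap = r$finalGap, curve = r$curve,
        config = c(unclass(config),
                   list(mapSize = mapSize, nCases = nrow(G))))
  })
  names(res) <- losses
  res
}

#' Accessors for simulation results
#'
#' @param result a [SimResult-class].
#' @return \code{convergedEpochs}: integer vector (NA = not converged);
#'   \code{finalGaps}: numeric vector; \code{gapCurve}: numeric vector of
#'   per-epoch total gaps (element 1 is epoch 0); \code{convergedFraction}:
#'   scalar in \code{[0, 1]}.
#' @name simResultAccessors
NULL

#' @rdname simResultAccessors
#' @export
convergedEpochs <- function(result) result@convergedEpoch

#' @rdname simResultAccessors
#' @export
finalGaps <- function(result) result@finalGap

#' @rdname simResultAccessors
#' @export
gapCurve <- function(result) result@curve

#' @rdname simResultAccessors
#' @export
convergedFraction <- function(result) {
  mean(!is.na(result@convergedEpoch))
}
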