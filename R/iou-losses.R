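#' The IoU metric family
#'
#' Each function returns the similarity metric \eqn{m \le 1} for pairs of
#' boxes (use \code{1 - m} as the training loss).  All members equal 1
#' exactly on identical boxes and never exceed plain IoU, since every
#' penalty term is nonnegative:
#' \describe{
#'   \item{\code{giou}}{IoU minus the enclosing-box slack ratio
#'     \eqn{(|C| - |A \cup B|)/|C|}; range \eqn{(-1, 1]}.}
#'   \item{\code{diou}}{IoU minus the squared center distance over the
#'     squared enclosing-box diagonal.}
#'   \item{\code{ciou}}{DIoU minus \eqn{\alpha\nu}, where \eqn{\nu}
#'     measures aspect-ratio consistency and the trade-off
#'     \eqn{\alpha = \nu / (1 - IoU + \nu)} is evaluated at the current IoU.}
#'   \item{\code{eiou}}{DIoU minus the squared width and height gaps, each
#'     normalised by the squared enclosing width/height.}
#'   \item{\code{siou}}{IoU minus half the sum of an angle-modulated
#'     distance cost and a shape cost (exponent 4).}
#'   \item{\code{mpdiou}}{IoU minus the squared top-left and bottom-right
#'     corner distances, each over the squared feature-map diagonal
#'     \eqn{W^2 + H^2}.}
#'   \item{\code{smpdiou}}{as \code{mpdiou}, but the corner distances are
#'     normalised by the squared angle-dependent baseline \eqn{C^2} and the
#'     penalty is amplified by the feature-map scale factor; see
#'     [smpdiouBaseline()] and [scaleFactor()].}
#' }
#'
#' @param a ground-truth boxes, a [BBox-class].
#' @param b predicted boxes, a [BBox-class] (recycled against \code{a}).
#' @param geometry a [FeatureMapGeometry-class]; required by \code{mpdiou}
#'   and \code{smpdiou}.
#' @return numeric vector of metric values (\eqn{\le 1}).
#' @examples
#' a <- boxFromCorners(c(4, 4), c(6, 6))
#' b <- boxFromCorners(c(8, 4), c(10, 6))
#' giou(a, b)                                  # -1/3
#' diou(a, b)                                  # -0.4
#' mpdiou(a, b, FeatureMapGeometry(20))        # -0.04
#' @name iouFamily
NULL

.metricByName <- function(name, a, b, geometry = NULL, fixed = list()) {
  p <- .pairmats(a, b)
  if (name %in% c("mpdiou", "smpdiou")) {
    if (!is(geometry, "FeatureMapGeometry"))
      stop("loss '", name, "' requires a FeatureMapGeometry", call. = FALSE)
    sv <- if (name == "smpdiou") scaleFactor(geometry) else NA_real_
    .metricGrad(name, p$A, p$B, W = geometry@W, H = geometry@H,
                scaleVal = sv, fixed = fixed, wantGrad = FALSE)$metric
  } else {
    .metricGrad(name, p$A, p$B, fixed = fixed, wantGrad = FALSE)$metric
  }
}

#' @rdname iouFamily
#' @export
giou <- function(a, b) .metricByName("giou", a, b)

#' @rdname iouFamily
#' @export
diou <- function(a, b) .metricByName("diou", a, b)

#' @rdname iouFamily
#' @export
ciou <- function(a, b) .metricByName("ciou", a, b)

#' @rdname iouFamily
#' @export
eiou <- function(a, b) .metricByName("eiou", a, b)

#' @rdname iouFamily
#' @export
siou <- function(a, b) .metricByName("siou", a, b)

#' @rdname iouFamily
#' @export
mpdiou <- function(a, b, geometry) .metricByName("mpdiou", a, b, geometry)

#' @rdname iouFamily
#' @export
smpdiou <- function(a, b, geometry) .metricByName("smpdiou", a, b, geometry)

#' Evaluate a metric by name
#'
#' Dispatch wrapper over the family in [iouFamily]: evaluates the metric
#' named by a [LossSpec-class] (or a character name) on box pairs.
#'
#' @param spec a [LossSpec-class], or a character metric name (in which
#'   case \code{geometry} supplies the feature-map frame when needed).
#' @param a,b ground-truth and predicted [BBox-class] objects.
#' @param geometry optional [FeatureMapGeometry-class] when \code{spec} is
#'   a character name.
#' @return numeric vector of metric values.
#' @export
iouMetric <- function(spec, a, b, geometry = NULL) {
  if (is.character(spec)) spec <- lossSpec(spec, geometry)
  stopifnot(is(spec, "LossSpec"))
  if (spec@name == "iou") boxIoU(a, b)
  else .metricByName(spec@name, a, b, spec@geometry)
}

#' Center angle for the S-MPDIoU baseline
#'
#' The angle \eqn{\alpha = \arctan(C_h / C_w)} between the two box centers,
#' computed with the two-argument arctangent of the absolute center offsets
#' so that a vertical alignment (\eqn{C_w = 0}) cleanly yields \eqn{\pi/2}.
#' Coincident centers leave the angle undefined; the value is \code{NA} and
#' the baseline falls back to the full feature-map diagonal.
#'
#' @param a,b [BBox-class] objects (recycled).
#' @return numeric vector of angles in \eqn{[0, \pi/2]}; \code{NA} for
#'   coincident centers.
#' @export
smpdiouAlpha <- function(a, b) {
  off <- centerOffsets(a, b)
  ang <- atan2(off$Ch, off$Cw)
  ang[off$Cw == 0 & off$Ch == 0] <- NA_real_
  ang
}

#' Angle-dependent baseline length
#'
#' The baseline \eqn{C} normalising the S-MPDIoU corner distances.  For a
#' center angle below \eqn{\pi/4} the baseline spans the full map width:
#' \eqn{w_1 = W}, \eqn{h_1 = W \tan\alpha}; at or above \eqn{\pi/4} it spans
#' the full map height: \eqn{w_1 = H / \tan\alpha}, \eqn{h_1 = H}; in both
#' cases \eqn{C = \sqrt{w_1^2 + h_1^2}}.  The boundary \eqn{\alpha = \pi/4}
#' is assigned to the height branch; on a square map both branches agree
#' there and \eqn{C} equals the full diagonal \eqn{\sqrt{W^2 + H^2}}, the
#' fixed baseline of MPDIoU.  An undefined angle (\code{NA}, coincident
#' centers) also falls back to the full diagonal, the continuous limit
#' along \eqn{\alpha = \pi/4}.
#'
#' @param alpha numeric vector of angles in \eqn{[0, \pi/2]} (\code{NA} for
#'   the degenerate coincident-center case).
#' @param geometry a [FeatureMapGeometry-class].
#' @return numeric vector of baseline lengths (cells).
#' @examples
#' g <- FeatureMapGeometry(20)
#' smpdiouBaseline(0, g)          # 20: horizontal baseline is the map width
#' smpdiouBaseline(pi / 4, g)     # sqrt(2) * 20: the full diagonal
#' @export
smpdiouBaseline <- function(alpha, geometry) {
  stopifnot(is(geometry, "FeatureMapGeometry"))
  W <- geometry@W; H <- geometry@H
  out <- numeric(length(alpha))
  deg <- is.na(alpha)
  low <- !deg & alpha < pi / 4
  high <- !deg & !low
  out[deg] <- sqrt(W^2 + H^2)
  # C = W * sec(alpha) below pi/4, H / sin(alpha) at or above
  out[low] <- W * sqrt(1 + tan(alpha[low])^2)
  out[high] <- H * sqrt(1 / tan(alpha[high])^2 + 1)
  out
}

#' Feature-map scale factor
#'
#' \eqn{scale = \log_2(downsample)} with \eqn{downsample = inputRef / W}:
#' the constant that amplifies the S-MPDIoU penalty so it keeps providing
#' gradient when the two boxes are close but not yet overlapping.  It is a
#' constant multiplier: no gradient flows through it.
#'
#' @param geometry a [FeatureMapGeometry-class] with
#'   \code{downsample >= 1}.
#' @return nonnegative scalar.
#' @examples
#' scaleFactor(FeatureMapGeometry(80, inputRef = 640))  # 3
#' @export
scaleFactor <- function(geometry) {
  stopifnot(is(geometry, "FeatureMapGeometry"))
  ds <- downsample(geometry)
  if (ds < 1)
    stop("downsample = inputRef / W is ", ds,
         " < 1: feature map larger than the reference input", call. = FALSE)
  log2(ds)
}

#' Loss value and analytic gradient
#'
#' Evaluates \code{loss = 1 - metric} for the metric named by \code{spec}
#' together with its gradient with respect to the predicted box's four
#' parameters \code{(x, y, w, h)}, from closed-form differentiation of the
#' metric.  Constants by contract receive no gradient: the S-MPDIoU scale
#' factor, its angle-branch selection, and the CIoU trade-off \eqn{\alpha}.
#' Where a term is flat (the IoU of two disjoint boxes) its gradient
#' contribution is exactly zero, and at min/max kinks the symmetric
#' subgradient is returned (it matches the central finite difference).
#'
#' @param spec a [LossSpec-class] or metric name.
#' @param gt ground-truth [BBox-class].
#' @param pred predicted [BBox-class] (gradients are w.r.t. this box).
#' @param geometry optional [FeatureMapGeometry-class] when \code{spec} is
#'   a character name.
#' @return a list with \code{loss} (numeric vector) and \code{gradient}
#'   (n x 4 matrix, columns \code{x}, \code{y}, \code{w}, \code{h}).
#'   Non-finite gradients abort: they indicate an implementation fault,
#'   never a valid state.
#' @examples
#' g <- FeatureMapGeometry(20)
#' lossAndGradient("smpdiou", BBox(1, 1, 0.5, 0.5), BBox(7, 1, 1, 2), g)
#' @export
lossAndGradient <- function(spec, gt, pred, geometry = NULL) {
  if (is.character(spec)) spec <- lossSpec(spec, geometry)
  stopifnot(is(spec, "LossSpec"))
  p <- .pairmats(gt, pred)
  sa <- .specArgs(spec)
  r <- .metricGrad(spec@name, p$A, p$B, W = sa$W, H = sa$H,
                   scaleVal = sa$scaleVal)
  grad <- -r$grad
  if (any(!is.finite(grad)))
    stop("non-finite gradient for loss '", spec@name,
         "': implementation fault", call. = FALSE)
  colnames(grad) <- c("x", "y", "w", "h")
  list(loss = 1 - r$metric, gradient = grad)
}
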