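#' Corner coordinates of boxes
#'
#' Derives the top-left and bottom-right corners from the center/size
#' parameterisation.  "Top-left" is the minimum-coordinate corner
#' (image convention); distances between corners do not depend on the
#' y-axis orientation.
#'
#' @param box a [BBox-class].
#' @return a list with matrices \code{topLeft} and \code{bottomRight}
#'   (n x 2, columns \code{x}, \code{y}).
#' @examples
#' corners(BBox(5, 5, 2, 2))   # TL (4,4), BR (6,6)
#' @export
corners <- function(box) {
  stopifnot(is(box, "BBox"))
  list(topLeft = cbind(x = box@x - box@w / 2, y = box@y - box@h / 2),
       bottomRight = cbind(x = box@x + box@w / 2, y = box@y + box@h / 2))
}

#' Rebuild boxes from corner coordinates
#'
#' Inverse of [corners()]: given the two extreme corners, recenters to the
#' center/size parameterisation.
#'
#' @param topLeft,bottomRight n x 2 matrices (or length-2 vectors) of
#'   corner coordinates; \code{topLeft} must be strictly below
#'   \code{bottomRight} on both axes.
#' @return a [BBox-class].
#' @export
boxFromCorners <- function(topLeft, bottomRight) {
  tl <- rbind(topLeft); br <- rbind(bottomRight)
  BBox(x = (tl[, 1] + br[, 1]) / 2, y = (tl[, 2] + br[, 2]) / 2,
       w = br[, 1] - tl[, 1], h = br[, 2] - tl[, 2])
}

# internal vectorised geometry on n x 4 matrices (columns x, y, w, h);
# the hot path of the loss engine and the simulator.
.geom <- function(A, B) {
  la <- A[, 1] - A[, 3] / 2; ra <- A[, 1] + A[, 3] / 2
  ta <- A[, 2] - A[, 4] / 2; ba <- A[, 2] + A[, 4] / 2
  lb <- B[, 1] - B[, 3] / 2; rb <- B[, 1] + B[, 3] / 2
  tb <- B[, 2] - B[, 4] / 2; bb <- B[, 2] + B[, 4] / 2
  iw <- pmin(ra, rb) - pmax(la, lb); iw[iw < 0] <- 0
  ih <- pmin(ba, bb) - pmax(ta, tb); ih[ih < 0] <- 0
  inter <- iw * ih
  union <- A[, 3] * A[, 4] + B[, 3] * B[, 4] - inter
  list(la = la, ra = ra, ta = ta, ba = ba,
       lb = lb, rb = rb, tb = tb, bb = bb,
       iw = iw, ih = ih, inter = inter, union = union,
       iou = inter / union,
       cw = pmax(ra, rb) - pmin(la, lb),
       ch = pmax(ba, bb) - pmin(ta, tb))
}

#' Intersection over Union
#'
#' The ratio of the intersection area to the union area of two axis-aligned
#' boxes: 1 for identical boxes, 0 for disjoint ones.  Vectorised over box
#' pairs (the shorter argument is recycled).
#'
#' @param a,b [BBox-class] objects.
#' @return numeric vector in \code{[0, 1]}.
#' @examples
#' a <- boxFromCorners(c(0, 0), c(2, 2))
#' b <- boxFromCorners(c(1, 1), c(3, 3))
#' boxIoU(a, b)   # 1/7
#' @export
boxIoU <- function(a, b) {
  p <- .pairmats(a, b)
  unname(.geom(p$A, p$B)$iou)
}

# recycle two BBoxes to a common length and return matrices
.pairmats <- function(a, b) {
  stopifnot(is(a, "BBox"), is(b, "BBox"))
  n <- max(length(a), length(b))
  A <- .boxmat(a); B <- .boxmat(b)
  if (nrow(A) < n) A <- A[rep_len(seq_len(nrow(A)), n), , drop = FALSE]
  if (nrow(B) < n) B <- B[rep_len(seq_len(nrow(B)), n), , drop = FALSE]
  list(A = A, B = B)
}

#' Smallest enclosing box
#'
#' The minimum axis-aligned box covering both arguments (the "C" box of the
#' GIoU/DIoU penalty terms).
#'
#' @param a,b [BBox-class] objects (recycled to a common length).
#' @return a [BBox-class].
#' @export
enclosingBox <- function(a, b) {
  p <- .pairmats(a, b); g <- .geom(p$A, p$B)
  boxFromCorners(cbind(pmin(g$la, g$lb), pmin(g$ta, g$tb)),
                 cbind(pmax(g$ra, g$rb), pmax(g$ba, g$bb)))
}

#' Absolute center offsets
#'
#' The horizontal and vertical gaps between the two box centers,
#' \eqn{C_w = |x_c^a - x_c^b|} and \eqn{C_h = |y_c^a - y_c^b|}; these define
#' the center angle used by the S-MPDIoU baseline.
#'
#' @param a,b [BBox-class] objects (recycled).
#' @return a list with numeric vectors \code{Cw} and \code{Ch}.
#' @export
centerOffsets <- function(a, b) {
  p <- .pairmats(a, b)
  list(Cw = unname(abs(p$A[, 1] - p$B[, 1])),
       Ch = unname(abs(p$A[, 2] - p$B[, 2])))
}

#' Corner distances
#'
#' Euclidean distances between the top-left corners (\code{d1}) and between
#' the bottom-right corners (\code{d2}) of two boxes; both are zero iff the
#' boxes coincide.
#'
#' @param a,b [BBox-class] objects (recycled).
#' @return a list with numeric vectors \code{d1} and \code{d2}.
#' @export
cornerDistances <- function(a, b) {
  p <- .pairmats(a, b); g <- .geom(p$A, p$B)
  list(d1 = unname(sqrt((g$la - g$lb)^2 + (g$ta - g$tb)^2)),
       d2 = unname(sqrt((g$ra - g$rb)^2 + (g$ba - g$bb)^2)))
}

#' L1 parameter gap between two boxes
#'
#' Sum of absolute differences of the four box parameters
#' \eqn{|x^a-x^b| + |y^a-y^b| + |w^a-w^b| + |h^a-h^b|}; the convergence
#' criterion of the regression simulator.
#'
#' @param a,b [BBox-class] objects (recycled).
#' @return nonnegative numeric vector; 0 iff the boxes are identical.
#' @export
l1Gap <- function(a, b) {
  p <- .pairmats(a, b)
  rowSums(abs(p$A - p$B))
}
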