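#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Axis-aligned bounding boxes in feature-map coordinates
#'
#' \code{BBox} stores one or more axis-aligned boxes parameterised by their
#' center and size: \code{x}, \code{y} are the center coordinates and
#' \code{w}, \code{h} the (strictly positive) width and height, all in
#' continuous feature-map cell units.  Corners are always derived from the
#' center/size parameterisation, never stored, so the two views can never
#' disagree.  The class is vectorised: all four slots have equal length and
#' a \code{BBox} of length n holds n boxes.
#'
#' @slot x,y numeric, box center coordinates (cells).
#' @slot w,h numeric, box width and height (cells); must be finite and > 0.
#'
#' @seealso [corners()], [boxIoU()], [enclosingBox()]
#' @examples
#' b <- BBox(x = 5, y = 5, w = 2, h = 2)
#' corners(b)
#' @export
setClass("BBox",
  representation(x = "numeric", y = "numeric", w = "numeric", h = "numeric"),
  validity = function(object) {
    n <- length(object@x)
    if (length(object@y) != n || length(object@w) != n || length(object@h) != n)
      return("x, y, w, h must have equal length")
    v <- c(object@x, object@y, object@w, object@h)
    if (length(v) && any(!is.finite(v)))
      return("box parameters must be finite")
    if (any(object@w <= 0) || any(object@h <= 0))
      return("degenerate box: w and h must be > 0")
    TRUE
  })

#' Construct bounding boxes
#'
#' @param x,y numeric vectors of center coordinates (feature-map cells).
#' @param w,h numeric vectors of widths and heights (> 0).
#' @return a [BBox-class] object of length \code{max(length(x), ...)};
#'   scalar arguments are recycled.
#' @export
BBox <- function(x, y, w, h) {
  n <- max(length(x), length(y), length(w), length(h))
  new("BBox",
      x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
      w = rep_len(as.numeric(w), n), h = rep_len(as.numeric(h), n))
}

#' Detection feature-map geometry
#'
#' Describes the frame of one detection feature map: its width \code{W} and
#' height \code{H} in cells, and the reference network input size in pixels
#' from which the downsampling ratio \code{inputRef / W} derives.  The
#' downsample ratio feeds the scale factor \code{log2(downsample)} used by
#' the S-MPDIoU penalty.
#'
#' @slot W,H positive numeric, feature-map width and height (cells).
#' @slot inputRef positive numeric, reference input size (pixels), default 640.
#' @seealso [scaleFactor()], [smpdiou()]
#' @examples
#' g <- FeatureMapGeometry(80)          # 80 x 80 map of a 640 input
#' downsample(g)                        # 8
#' scaleFactor(g)                       # 3
#' @export
setClass("FeatureMapGeometry",
  representation(W = "numeric", H = "numeric", inputRef = "numeric"),
  validity = function(object) {
    if (length(object@W) != 1 || length(object@H) != 1 ||
        length(object@inputRef) != 1)
      return("W, H, inputRef must be scalars")
    if (!all(is.finite(c(object@W, object@H, object@inputRef))))
      return("geometry values must be finite")
    if (object@W <= 0 || object@H <= 0 || object@inputRef <= 0)
      return("W, H, inputRef must be positive")
    TRUE
  })

#' @param W,H feature-map width and height in cells (\code{H} defaults to
#'   \code{W}; a non-square map is accepted with a warning since the
#'   angle-branch threshold \eqn{\pi/4} is calibrated for square maps).
#' @param inputRef reference input size in pixels (default 640).
#' @rdname FeatureMapGeometry-class
#' @export
FeatureMapGeometry <- function(W, H = W, inputRef = 640) {
  g <- new("FeatureMapGeometry", W = as.numeric(W), H = as.numeric(H),
           inputRef = as.numeric(inputRef))
  if (g@W != g@H)
    warning("non-square feature map: the pi/4 angle branch threshold is ",
            "calibrated for square maps", call. = FALSE)
  g
}

#' Loss-function specification
#'
#' Names one member of the IoU metric family and carries the feature-map
#' geometry required by the corner-distance members (\code{mpdiou},
#' \code{smpdiou}); the geometry is ignored by the others.
#'
#' @slot name one of \code{"iou"}, \code{"giou"}, \code{"diou"},
#'   \code{"ciou"}, \code{"eiou"}, \code{"siou"}, \code{"mpdiou"},
#'   \code{"smpdiou"}.
#' @slot geometry a [FeatureMapGeometry-class] or \code{NULL}.
#' @seealso [lossAndGradient()]
#' @export
setClass("LossSpec",
  representation(name = "character", geometry = "ANY"),
  validity = function(object) {
    if (length(object@name) != 1 || !object@name %in% lossNames())
      return(paste("name must be one of:", paste(lossNames(), collapse = ", ")))
    if (object@name %in% c("mpdiou", "smpdiou")) {
      if (!is(object@geometry, "FeatureMapGeometry"))
        return(paste0("loss '", object@name,
                      "' requires a FeatureMapGeometry"))
    } else if (!is.null(object@geometry) &&
               !is(object@geometry, "FeatureMapGeometry")) {
      return("geometry must be a FeatureMapGeometry or NULL")
    }
    TRUE
  })

#' Supported loss names
#'
#' @return character vector of the eight metric names, in the conventional
#'   family order.
#' @export
lossNames <- function() {
  c("iou", "giou", "diou", "ciou", "eiou", "siou", "mpdiou", "smpdiou")
}

#' @param name metric name (see [lossNames()]).
#' @param geometry a [FeatureMapGeometry-class]; required for
#'   \code{mpdiou} and \code{smpdiou}.
#' @rdname LossSpec-class
#' @export
lossSpec <- function(name, geometry = NULL) {
  new("LossSpec", name = match.arg(name, lossNames()), geometry = geometry)
}

#' Result of one simulated regression run
#'
#' Convergence accounting for a population of box-regression cases optimised
#' by gradient descent under one loss: the epoch at which each case first
#' dropped below the convergence threshold on the L1 parameter gap
#' (\code{NA} if never), the final gap per case, and the per-epoch total gap
#' curve summed over the population.
#'
#' @slot lossName character, the loss optimised.
#' @slot convergedEpoch integer vector, first epoch with gap below the
#'   threshold per case; \code{NA} when the budget was exhausted first.
#' @slot finalGap numeric vector, L1 parameter gap per case after the run.
#' @slot curve numeric vector, total L1 gap over all cases at each epoch
#'   (element 1 is epoch 0, the initial population).
#' @slot config list, the resolved simulation configuration.
#' @export
setClass("SimResult",
  representation(lossName = "character", convergedEpoch = "integer",
                 finalGap = "numeric", curve = "numeric", config = "list"))

setMethod("show", "BBox", function(object) {
  n <- length(object@x)
  cat("BBox of length", n, "\n")
  if (n) {
    k <- min(n, 6L)
    df <- data.frame(x = object@x[1:k], y = object@y[1:k],
                     w = object@w[1:k], h = object@h[1:k])
    print(df)
    if (n > k) cat("... and", n - k, "more\n")
  }
})

setMethod("show", "FeatureMapGeometry", function(object) {
  ds <- downsample(object)
  cat(sprintf("FeatureMapGeometry: %g x %g cells (input %g px, downsample %g, scale %g)\n",
              object@W, object@H, object@inputRef, ds, log2(ds)))
})

setMethod("show", "LossSpec", function(object) {
  cat("LossSpec:", object@name)
  if (is(object@geometry, "FeatureMapGeometry"))
    cat(sprintf(" on a %g x %g map", object@geometry@W, object@geometry@H))
  cat("\n")
})

setMethod("show", "SimResult", function(object) {
  n <- length(object@convergedEpoch)
  cat(sprintf("SimResult (%s): %d case(s), %d converged, %d epoch(s) run\n",
              object@lossName, n, sum(!is.na(object@convergedEpoch)),
              length(object@curve) - 1L))
})

setMethod("length", "BBox", function(x) length(x@x))

setMethod("[", "BBox", function(x, i, j, ..., drop = TRUE) {
  BBox(x@x[i], x@y[i], x@w[i], x@h[i])
})

#' @export
as.data.frame.BBox <- function(x, ...) {
  data.frame(x = x@x, y = x@y, w = x@w, h = x@h)
}

#' Accessors for box and geometry slots
#'
#' @param box a [BBox-class].
#' @return numeric vectors of center coordinates or sizes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
boxX <- function(box) box@x
#' @rdname accessors
#' @export
boxY <- function(box) box@y
#' @rdname accessors
#' @export
boxW <- function(box) box@w
#' @rdname accessors
#' @export
boxH <- function(box) box@h

#' @param geometry a [FeatureMapGeometry-class].
#' @rdname accessors
#' @export
mapWidth <- function(geometry) geometry@W
#' @rdname accessors
#' @export
mapHeight <- function(geometry) geometry@H
#' @rdname accessors
#' @export
inputRef <- function(geometry) geometry@inputRef

#' @rdname accessors
#' @export
downsample <- function(geometry) geometry@inputRef / geometry@W

# internal: BBox -> n x 4 matrix with columns x, y, w, h
.boxmat <- function(box) {
  cbind(x = box@x, y = box@y, w = box@w, h = box@h)
}

# internal: n x 4 matrix -> BBox
.matbox <- function(m) BBox(m[, 1], m[, 2], m[, 3], m[, 4])
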