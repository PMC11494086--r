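#' Adaptive 1-D convolution kernel size
#'
#' Chooses the channel-attention kernel width from the channel count with
#' the adaptive rule \eqn{k = \mathrm{odd}(\log_2(C)/\gamma + b/\gamma)}
#' (\eqn{\gamma = 2}, \eqn{b = 1} by default): the nearest odd integer,
#' with ties between adjacent odd integers resolved downward, floored at 1.
#'
#' @param C channel count (>= 1).
#' @param gamma,b rule constants.
#' @return an odd positive integer.
#' @examples
#' adaptiveKernelSize(256)  # 5
#' adaptiveKernelSize(2)    # 1
#' @export
adaptiveKernelSize <- function(C, gamma = 2, b = 1) {
  stopifnot(C >= 1)
  t <- log2(C) / gamma + b / gamma
  lower <- 2 * floor((t - 1) / 2) + 1        # largest odd <= t
  k <- ifelse(t - lower > 2 - (t - lower), lower + 2, lower)
  as.integer(max(1, k))
}

#' Multi-Dimensional Attention parameters
#'
#' The whole MDA operator learns exactly \code{k} scalars: the weights of
#' the bias-free 1-D convolution of its channel-attention stage.  The two
#' directional stages are parameter-free.
#'
#' @slot k odd positive integer, kernel width.
#' @slot weights numeric vector of length \code{k}.
#' @slot gamma,b the kernel-size rule constants used to derive \code{k}.
#' @seealso [mdaForward()], [adaptiveKernelSize()]
#' @export
setClass("MDAParams",
  representation(k = "integer", weights = "numeric",
                 gamma = "numeric", b = "numeric"),
  validity = function(object) {
    if (object@k < 1 || object@k %% 2 == 0)
      return("k must be an odd positive integer")
    if (length(object@weights) != object@k)
      return("weights must have length k")
    if (any(!is.finite(object@weights)))
      return("weights must be finite")
    TRUE
  })

#' @param C channel count the operator will be applied to.
#' @param weights optional explicit kernel weights (length
#'   \code{adaptiveKernelSize(C)}); overrides \code{init}.
#' @param init \code{"zero"} (default; the untrained operator is then a
#'   benign x0.5 channel scaler) or \code{"random"} (N(0, 0.1), seeded).
#' @param seed seed for random initialisation.
#' @param gamma,b kernel-size rule constants.
#' @rdname MDAParams-class
#' @export
mdaParams <- function(C, weights = NULL, init = c("zero", "random"),
                      seed = 0L, gamma = 2, b = 1) {
  k <- adaptiveKernelSize(C, gamma, b)
  if (is.null(weights)) {
    init <- match.arg(init)
    weights <- if (init == "zero") numeric(k) else {
      set.seed(as.integer(seed)); stats::rnorm(k, sd = 0.1)
    }
  }
  new("MDAParams", k = k, weights = as.numeric(weights),
      gamma = as.numeric(gamma), b = as.numeric(b))
}

setMethod("show", "MDAParams", function(object) {
  cat(sprintf("MDAParams: k = %d (gamma = %g, b = %g), %d parameter(s)\n",
              object@k, object@gamma, object@b, parameterCount(object)))
})

#' Learned-parameter count of the operator
#'
#' @param params an [MDAParams-class].
#' @return integer: \code{k}, the kernel width.  The count is independent
#'   of the spatial extent of the input; compare a squeeze-excitation
#'   block's \eqn{2C^2/r} parameters.
#' @export
parameterCount <- function(params) {
  stopifnot(is(params, "MDAParams"))
  params@k
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.checkFeatureMap <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a 3-d array (C x H x W)", call. = FALSE)
  if (any(!is.finite(x)))
    stop("feature map contains non-finite values", call. = FALSE)
  invisible(dim(x))
}

#' Channel-attention stage
#'
#' Average-pools the C x H x W input over its spatial extent to a length-C
#' vector, runs a same-length zero-padded 1-D convolution (width \code{k},
#' no bias) across the channel axis, squashes through a sigmoid, and
#' rescales each input channel by its weight.  Shape is preserved.
#'
#' @param x 3-d numeric array, dimensions (C, H, W), finite.
#' @param params an [MDAParams-class] with \code{k <=} suitable for C
#'   (by construction [mdaParams()] ties k to C's rule).
#' @return array of the same shape: the refined feature map.
#' @export
channelAttention <- function(x, params) {
  d <- .checkFeatureMap(x)
  stopifnot(is(params, "MDAParams"))
  C <- d[1L]
  s <- rowMeans(matrix(x, nrow = C))           # spatial average pool, C x 1 x 1
  p <- (params@k - 1L) %/% 2L
  spad <- c(numeric(p), s, numeric(p))
  conv <- vapply(seq_len(C),
                 function(i) sum(params@weights * spad[i:(i + params@k - 1L)]),
                 0)
  wch <- .sigmoid(conv)
  x * wch                                       # recycles along the channel axis
}

#' Width- and height-direction attention stage
#'
#' Average-pools the refined map over (channel, height) to a length-W
#' vector and over (channel, width) to a length-H vector, passes both
#' through a sigmoid, and multiplies the refined map elementwise by the
#' two broadcast directional weights, applied in parallel.  The stage has
#' no learned parameters.
#'
#' @param refined 3-d numeric array (C, H, W), typically the output of
#'   [channelAttention()].
#' @return array of the same shape.
#' @export
directionalAttention <- function(refined) {
  d <- .checkFeatureMap(refined)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  wv <- apply(refined, 3L, mean)               # 1 x W x 1
  hv <- apply(refined, 2L, mean)               # 1 x 1 x H
  sw <- .sigmoid(wv); sh <- .sigmoid(hv)
  refined * rep(sh, each = C) * rep(sw, each = C * H)
}

#' Multi-Dimensional Attention forward pass
#'
#' The full MDA operator: channel attention (spatial pooling + adaptive
#' 1-D convolution + sigmoid rescaling) followed by the parallel width-
#' and height-direction attention.  Shape-preserving, sign-preserving, and
#' contractive: every attention weight lies strictly in (0, 1), so output
#' magnitudes never exceed the input's.
#'
#' @inheritParams channelAttention
#' @return array of the same shape as \code{x}.
#' @examples
#' x <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
#' p <- mdaParams(4)
#' dim(mdaForward(x, p))   # 4 5 6
#' @export
mdaForward <- function(x, params) {
  directionalAttention(channelAttention(x, params))
}

#' Serialise MDA parameters to JSON
#'
#' Writes/reads the flat weight vector plus the kernel-size rule constants;
#' a round-trip restores exactly the \code{k} learned scalars.
#'
#' @param params an [MDAParams-class].
#' @param path file path.
#' @return \code{readMDAParams} returns an [MDAParams-class];
#'   \code{writeMDAParams} returns \code{path} invisibly.
#' @export
writeMDAParams <- function(params, path) {
  stopifnot(is(params, "MDAParams"))
  jsonlite::write_json(list(k = params@k, gamma = params@gamma, b = params@b,
                            weights = params@weights),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMDAParams
#' @export
readMDAParams <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MDAParams", k = as.integer(j$k), weights = as.numeric(j$weights),
      gamma = as.numeric(j$gamma), b = as.numeric(j$b))
}
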