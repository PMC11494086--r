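#' Patch grid over a slide
#'
#' Regular, by default non-overlapping, tiling of a slide into fixed-size
#' square patches; edge remainders are dropped so every patch is exactly
#' \code{patchSize} x \code{patchSize}.  Patches whose tissue fraction
#' (under the background mask) falls below \code{minTissue} are removed.
#'
#' @slot patchSize,stride integer pixels.
#' @slot minTissue numeric in [0, 1], minimum tissue fraction kept.
#' @slot patches data.frame with one row per surviving patch: \code{row},
#'   \code{col} (1-based grid indices), \code{x0}, \code{y0} (0-based pixel
#'   offsets of the top-left corner) and \code{tissueFraction}.
#' @export
setClass("PatchGrid",
  representation(patchSize = "integer", stride = "integer",
                 minTissue = "numeric", patches = "data.frame"))

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patch(es) of %d px (stride %d, minTissue %g)\n",
              nrow(object@patches), object@patchSize, object@stride,
              object@minTissue))
})

setMethod("length", "PatchGrid", function(x) nrow(x@patches))

#' Triage result
#'
#' Per-patch lymphocyte counts and flags.  A patch is flagged when its
#' count strictly exceeds the threshold; patches whose detector call
#' failed are marked invalid (count and flag \code{NA}) rather than
#' silently counted as zero.
#'
#' @slot grid the [PatchGrid-class] counted over.
#' @slot counts integer vector, one per patch (\code{NA} = invalid).
#' @slot flags logical vector, \code{count > threshold}.
#' @slot invalid logical vector, detector failures.
#' @slot threshold numeric, the flagging threshold.
#' @export
setClass("TriageResult",
  representation(grid = "PatchGrid", counts = "integer", flags = "logical",
                 invalid = "logical", threshold = "numeric"),
  validity = function(object) {
    n <- nrow(object@grid@patches)
    if (length(object@counts) != n || length(object@flags) != n ||
        length(object@invalid) != n)
      return("counts, flags, invalid must match the number of patches")
    ok <- !object@invalid
    if (!identical(object@flags[ok],
                   object@counts[ok] > object@threshold))
      return("flags must equal counts > threshold on valid patches")
    TRUE
  })

setMethod("show", "TriageResult", function(object) {
  cat(sprintf(
    "TriageResult: %d patch(es), %d flagged (threshold %g), %d invalid\n",
    length(object@counts), sum(object@flags, na.rm = TRUE),
    object@threshold, sum(object@invalid)))
})

#' @param result a [TriageResult-class].
#' @rdname TriageResult-class
#' @export
patchCounts <- function(result) result@counts

#' @rdname TriageResult-class
#' @export
patchFlags <- function(result) result@flags

.slideDims <- function(slide) {
  d <- dim(slide)
  if (length(d) != 3L || d[3L] != 3L)
    stop("slide must be a width x height x 3 RGB raster", call. = FALSE)
  d
}

#' Background filtering by saturation thresholding
#'
#' Separates stained tissue from the (near-white) slide background.  The
#' HSV saturation channel is computed per pixel; a global threshold is
#' chosen automatically by Otsu's method on a downsampled copy, and the
#' mask keeps pixels whose saturation exceeds it.  A slide with no
#' saturated content at all (maximum saturation below 0.05) yields an
#' empty mask.
#'
#' @param slide an RGB raster: an \code{EBImage::Image} in color mode or a
#'   width x height x 3 array with values in [0, 1].
#' @param downsampleFactor integer, downsampling used only for threshold
#'   selection (the mask itself is full resolution).
#' @return logical matrix (width x height): \code{TRUE} on tissue.
#' @export
filterBackground <- function(slide, downsampleFactor = 8L) {
  d <- .slideDims(slide)
  px <- as.numeric(slide)
  dim(px) <- d
  mx <- pmax(px[, , 1L], px[, , 2L], px[, , 3L])
  mn <- pmin(px[, , 1L], px[, , 2L], px[, , 3L])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  if (max(sat) < 0.05)
    return(matrix(FALSE, d[1L], d[2L]))
  small <- EBImage::resize(EBImage::Image(sat),
                           w = max(16L, ceiling(d[1L] / downsampleFactor)))
  thr <- EBImage::otsu(small, range = c(0, 1))
  sat > thr
}

#' Tile a slide into fixed-size patches
#'
#' @param slide RGB raster (see [filterBackground()]), or \code{NULL} if
#'   \code{dims} is given.
#' @param mask optional logical tissue mask from [filterBackground()];
#'   \code{NULL} treats the whole slide as tissue.
#' @param patchSize patch side in pixels (default 640).
#' @param stride grid stride in pixels; the default (= \code{patchSize})
#'   gives non-overlapping tiles.
#' @param minTissue minimum tissue fraction for a patch to be kept
#'   (default 0.05).
#' @param dims optional \code{c(width, height)} instead of \code{slide}.
#' @return a [PatchGrid-class].
#' @export
tileSlide <- function(slide = NULL, mask = NULL, patchSize = 640L,
                      stride = patchSize, minTissue = 0.05, dims = NULL) {
  if (is.null(dims)) dims <- .slideDims(slide)[1:2]
  patchSize <- as.integer(patchSize); stride <- as.integer(stride)
  if (dims[1L] < patchSize || dims[2L] < patchSize)
    stop("slide (", dims[1L], " x ", dims[2L],
         ") is smaller than one patch", call. = FALSE)
  x0 <- seq(0L, dims[1L] - patchSize, by = stride)
  y0 <- seq(0L, dims[2L] - patchSize, by = stride)
  g <- expand.grid(col = seq_along(x0), row = seq_along(y0))
  df <- data.frame(row = g$row, col = g$col,
                   x0 = x0[g$col], y0 = y0[g$row])
  df$tissueFraction <- if (is.null(mask)) 1 else
    vapply(seq_len(nrow(df)), function(i) {
      mean(mask[df$x0[i] + seq_len(patchSize),
                df$y0[i] + seq_len(patchSize)])
    }, 0)
  df <- df[df$tissueFraction >= minTissue, , drop = FALSE]
  rownames(df) <- NULL
  new("PatchGrid", patchSize = patchSize, stride = stride,
      minTissue = minTissue, patches = df)
}

#' Count cells per patch through a pluggable detector
#'
#' Feeds each patch raster to the detector and collects one nonnegative
#' count per patch, in grid order.  The detector is any function
#' \code{function(patch, info)} mapping a patch raster (width x height x 3
#' array) and its grid row (\code{info$x0}, \code{info$y0}, ...) to a
#' count.  A detector error marks the patch invalid (\code{NA}) instead of
#' silently reporting zero.
#'
#' @param slide RGB raster.
#' @param grid a [PatchGrid-class].
#' @param detector the per-patch counter; see [oracleDetector()] for the
#'   shipped synthetic-fixture oracle.  An adapter around a trained
#'   detection network plugs in through the same contract.
#' @return list with \code{counts} (integer, \code{NA} = invalid) and
#'   \code{invalid} (logical).
#' @export
countPatches <- function(slide, grid, detector) {
  stopifnot(is(grid, "PatchGrid"), is.function(detector))
  d <- .slideDims(slide)
  px <- as.numeric(slide); dim(px) <- d
  ps <- grid@patchSize
  n <- nrow(grid@patches)
  counts <- integer(n); invalid <- logical(n)
  for (i in seq_len(n)) {
    info <- grid@patches[i, ]
    patch <- px[info$x0 + seq_len(ps), info$y0 + seq_len(ps), , drop = FALSE]
    ct <- tryCatch(detector(patch, info), error = function(e) e)
    if (inherits(ct, "error") || !is.numeric(ct) || length(ct) != 1L ||
        is.na(ct) || ct < 0) {
      invalid[i] <- TRUE; counts[i] <- NA_integer_
    } else counts[i] <- as.integer(ct)
  }
  list(counts = counts, invalid = invalid)
}

#' Oracle detector backed by a fixture ledger
#'
#' Builds a detector for [countPatches()] that reads the ground-truth cell
#' ledger of a synthetic slide (see [makeSyntheticSlide()]) and counts the
#' generated cell centers falling inside each patch's half-open pixel
#' extent.  It ignores the patch raster: it is the fixture's own ground
#' truth, used to exercise the pipeline without a trained network.
#'
#' @param ledger data.frame with cell centers in columns \code{x},
#'   \code{y} (slide pixel coordinates).
#' @param patchSize patch side in pixels (must match the grid).
#' @return a detector function.
#' @export
oracleDetector <- function(ledger, patchSize = 640L) {
  force(ledger); ps <- as.integer(patchSize)
  function(patch, info) {
    sum(ledger$x >= info$x0 & ledger$x < info$x0 + ps &
        ledger$y >= info$y0 & ledger$y < info$y0 + ps)
  }
}

#' Flag patches whose count exceeds the threshold
#'
#' Strict "exceeding": a patch is flagged when \code{count > threshold};
#' a count equal to the threshold is not flagged.
#'
#' @param counts integer vector or the list returned by [countPatches()].
#' @param threshold positive integer (default 50; configuration, not a
#'   fixed clinical value).
#' @param grid the [PatchGrid-class] the counts belong to.
#' @return a [TriageResult-class].
#' @export
flagPatches <- function(counts, threshold = 50L, grid) {
  stopifnot(threshold >= 1, is(grid, "PatchGrid"))
  invalid <- logical(length(if (is.list(counts)) counts$counts else counts))
  if (is.list(counts)) { invalid <- counts$invalid; counts <- counts$counts }
  new("TriageResult", grid = grid, counts = as.integer(counts),
      flags = counts > threshold, invalid = invalid,
      threshold = as.numeric(threshold))
}

#' Generate a synthetic stained slide with a known cell ledger
#'
#' Draws an H&E-like synthetic slide: a white background, eosin-pink
#' tissue disks, and hematoxylin-purple cell ellipses clustered in foci —
#' the dense focal aggregates the triage pipeline is meant to flag.  The
#' slide is deterministic in the seed, and every generated cell ellipse is
#' returned in a ledger together with per-patch expected counts, so the
#' whole pipeline is testable end to end without any external data.  This
#' is a synthetic stand-in for a scanned slide, not rendered tissue.
#'
#' @param width,height slide size in pixels.
#' @param foci data.frame with one row per cell focus: center \code{x},
#'   \code{y}, spread \code{radius} (pixels) and cell count \code{n}.
#' @param tissue optional data.frame of tissue disks (\code{x}, \code{y},
#'   \code{radius}); defaults to one disk per focus of twice its spread.
#' @param cellSize range of ellipse semi-axes in pixels.
#' @param patchSize patch side used for the expected-count table.
#' @param seed integer seed.
#' @return list with \code{image} (an \code{EBImage::Image}, color),
#'   \code{ledger} (data.frame: \code{focus}, \code{x}, \code{y}, semi-axes
#'   \code{a}, \code{b}, \code{angle}), and \code{expected} (data.frame of
#'   per-patch expected counts over the full, unfiltered grid).
#' @examples
#' s <- makeSyntheticSlide(256, 256,
#'        foci = data.frame(x = 64, y = 64, radius = 30, n = 20),
#'        patchSize = 128, seed = 1)
#' nrow(s$ledger)   # 20
#' @export
makeSyntheticSlide <- function(width = 1280L, height = 1280L,
                               foci = data.frame(x = 320, y = 320,
                                                 radius = 150, n = 80),
                               tissue = NULL, cellSize = c(2, 4),
                               patchSize = 640L, seed = 1L) {
  set.seed(as.integer(seed))
  width <- as.integer(width); height <- as.integer(height)
  px <- array(1, dim = c(width, height, 3L))    # white background
  if (is.null(tissue))
    tissue <- data.frame(x = foci$x, y = foci$y, radius = 2 * foci$radius)
  cx <- seq_len(width) - 0.5; cy <- seq_len(height) - 0.5
  eosin <- c(0.91, 0.65, 0.78)
  for (i in seq_len(nrow(tissue))) {
    inx <- which(abs(cx - tissue$x[i]) <= tissue$radius[i])
    iny <- which(abs(cy - tissue$y[i]) <= tissue$radius[i])
    if (!length(inx) || !length(iny)) next
    m <- outer((cx[inx] - tissue$x[i])^2, (cy[iny] - tissue$y[i])^2, "+") <=
      tissue$radius[i]^2
    for (ch in 1:3) {
      sub <- px[inx, iny, ch]
      sub[m] <- eosin[ch]
      px[inx, iny, ch] <- sub
    }
  }
  hema <- c(0.36, 0.20, 0.50)
  ledgers <- lapply(seq_len(nrow(foci)), function(i) {
    n <- foci$n[i]
    r <- foci$radius[i] * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    data.frame(focus = i,
               x = pmin(pmax(foci$x[i] + r * cos(th), 1), width - 1),
               y = pmin(pmax(foci$y[i] + r * sin(th), 1), height - 1),
               a = stats::runif(n, cellSize[1L], cellSize[2L]),
               b = stats::runif(n, cellSize[1L], cellSize[2L]),
               angle = stats::runif(n, 0, pi))
  })
  ledger <- do.call(rbind, ledgers)
  for (i in seq_len(nrow(ledger))) {
    a <- ledger$a[i]; b <- ledger$b[i]; ang <- ledger$angle[i]
    rmax <- max(a, b)
    inx <- which(abs(cx - ledger$x[i]) <= rmax)
    iny <- which(abs(cy - ledger$y[i]) <= rmax)
    if (!length(inx) || !length(iny)) next
    dx <- outer(cx[inx] - ledger$x[i], rep(1, length(iny)))
    dy <- outer(rep(1, length(inx)), cy[iny] - ledger$y[i])
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    m <- (u / a)^2 + (v / b)^2 <= 1
    for (ch in 1:3) {
      sub <- px[inx, iny, ch]
      sub[m] <- hema[ch]
      px[inx, iny, ch] <- sub
    }
  }
  expected <- NULL
  if (width >= patchSize && height >= patchSize) {
    grid <- tileSlide(dims = c(width, height), patchSize = patchSize,
                      minTissue = 0)
    det <- oracleDetector(ledger, patchSize)
    expected <- grid@patches[, c("row", "col", "x0", "y0")]
    expected$count <- vapply(seq_len(nrow(expected)),
                             function(i) det(NULL, expected[i, ]), 0)
  }
  list(image = EBImage::Image(px, colormode = "Color"),
       ledger = ledger, expected = expected)
}

#' Render the triage overlay
#'
#' Returns a copy of the slide with every flagged patch outlined in red
#' and lightly tinted; unflagged patches are untouched, so a result with
#' no flags renders pixel-identically to the input.  Rendering is a pure
#' function of (slide, result): re-rendering is byte-identical.
#'
#' @param slide RGB raster.
#' @param result a [TriageResult-class].
#' @param borderWidth outline width in pixels.
#' @param tint tint strength in [0, 1] blended over flagged patches.
#' @return an \code{EBImage::Image} of the same dimensions.
#' @export
renderOverlay <- function(slide, result, borderWidth = 3L, tint = 0.15) {
  stopifnot(is(result, "TriageResult"))
  d <- .slideDims(slide)
  px <- as.numeric(slide); dim(px) <- d
  ps <- result@grid@patchSize
  red <- c(1, 0, 0)
  flagged <- which(!is.na(result@flags) & result@flags)
  for (i in flagged) {
    info <- result@grid@patches[i, ]
    ix <- info$x0 + seq_len(ps); iy <- info$y0 + seq_len(ps)
    for (ch in 1:3)
      px[ix, iy, ch] <- (1 - tint) * px[ix, iy, ch] + tint * red[ch]
    bw <- min(borderWidth, ps %/% 2)
    edge <- c(seq_len(bw), ps - seq_len(bw) + 1L)
    for (ch in 1:3) {
      px[ix[edge], iy, ch] <- red[ch]
      px[ix, iy[edge], ch] <- red[ch]
    }
  }
  EBImage::Image(px, colormode = "Color")
}

#' Run the whole triage pipeline
#'
#' Background filtering, tiling, per-patch counting and threshold
#' flagging in one call.
#'
#' @inheritParams tileSlide
#' @inheritParams countPatches
#' @inheritParams flagPatches
#' @return a [TriageResult-class].
#' @export
runTriage <- function(slide, detector, patchSize = 640L,
                      stride = patchSize, threshold = 50L,
                      minTissue = 0.05) {
  mask <- filterBackground(slide)
  grid <- tileSlide(slide, mask, patchSize = patchSize, stride = stride,
                    minTissue = minTissue)
  flagPatches(countPatches(slide, grid, detector), threshold, grid)
}
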