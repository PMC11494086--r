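#' Read and write boxes
#'
#' Boxes are serialised either as JSON (an array of objects with fields
#' \code{x}, \code{y}, \code{w}, \code{h}) or as 4-column CSV with the
#' same header; the format is inferred from the file extension unless
#' given explicitly.
#'
#' @param box a [BBox-class].
#' @param path file path (\code{.json} or \code{.csv}).
#' @param format \code{"auto"}, \code{"json"} or \code{"csv"}.
#' @return \code{readBoxes} returns a [BBox-class]; \code{writeBoxes}
#'   returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeBoxes(BBox(1, 1, 0.5, 0.5), f)
#' readBoxes(f)
#' @export
writeBoxes <- function(box, path, format = c("auto", "json", "csv")) {
  stopifnot(is(box, "BBox"))
  format <- .boxFormat(match.arg(format), path)
  df <- as.data.frame(box)
  if (format == "json")
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  else
    utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBoxes
#' @export
readBoxes <- function(path, format = c("auto", "json", "csv")) {
  format <- .boxFormat(match.arg(format), path)
  df <- if (format == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else utils::read.csv(path)
  stopifnot(all(c("x", "y", "w", "h") %in% names(df)))
  BBox(df$x, df$y, df$w, df$h)
}

.boxFormat <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}
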