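#' Read a net elemental map from disk
#'
#' Accepts single-channel TIFF (IEEE float — values, including negatives, are
#' read exactly — or 8/16-bit integer, read as raw counts) and delimited text
#' matrices (`.csv` comma-separated, otherwise whitespace/tab).
#'
#' @param path file path.
#' @param element element symbol to record on the map.
#' @return A [net_map()] with provenance `"file"`.
#' @export
read_map <- function(path, element = c("other", "N", "P")) {
  element <- match.arg(element)
  net_map(read_matrix(path), element = element, provenance = "file")
}

# shared matrix reader for maps and masks
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) tiff::readTIFF(path))
    if (length(dim(x)) == 3L)
      stop("multi-channel TIFF (", dim(x)[3],
           " channels): only single-channel elemental maps are supported: ", path)
    return(x)
  }
  sep <- if (ext == "csv") "," else ""
  x <- as.matrix(read.table(path, sep = sep, header = FALSE))
  if (!is.numeric(x)) stop("non-numeric values in text matrix: ", path)
  dimnames(x) <- NULL
  x
}

#' Read region masks from disk
#'
#' @param cell path to the cell mask (nonzero = cell pixel); TIFF or text.
#' @param compartments optional path to the integer compartment label image.
#' @param legend optional path to a JSON file mapping label numbers to
#'   compartment names, e.g. `{"1": "vacuole", "2": "cytosol"}`; required with
#'   `compartments`.
#' @param roi optional path to a region-of-interest mask.
#' @return A [region_mask()].
#' @export
read_region_mask <- function(cell, compartments = NULL, legend = NULL, roi = NULL) {
  cm <- read_matrix(cell) != 0
  comp <- lg <- roim <- NULL
  if (!is.null(compartments)) {
    comp <- round(read_matrix(compartments))
    storage.mode(comp) <- "integer"
    if (is.null(legend)) stop("compartment labels need a JSON legend file")
    lg <- unlist(jsonlite::read_json(legend))
  }
  if (!is.null(roi)) roim <- read_matrix(roi) != 0
  region_mask(cm, compartments = comp, legend = lg, roi = roim)
}

#' Write a net map as a text matrix
#'
#' Signed float intensities round-trip exactly through the text format
#' (written with full precision); 8-bit TIFF output is reserved for grey
#' images and masks, see [write_grey_tiff()].
#'
#' @param map a [net_map()].
#' @param path output path (`.csv` for comma-separated, anything else
#'   tab-separated).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "net_map"))
  sep <- if (tolower(file_ext(path)) == "csv") "," else "\t"
  utils::write.table(format(map$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write an 8-bit grey image or binary mask as TIFF
#'
#' @param img a `grey_image`, `binary_mask`, or logical/integer matrix with
#'   values in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grey_tiff <- function(img, path) {
  x <- if (inherits(img, "grey_image")) img$levels else unclass(img)
  if (is.logical(x)) x <- x * 255L
  tiff::writeTIFF(x / 255, path, bits.per.sample = 8L)
  invisible(path)
}
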