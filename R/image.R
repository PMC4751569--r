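#' Grayscale image container
#'
#' A minimal container for a single-channel micrograph: a numeric matrix of
#' intensities in native units (never rescaled to \[0, 1\]) plus the bit
#' depth of the source file. Rows are y (top to bottom), columns are x.
#'
#' @param pixels numeric matrix, rows = y, columns = x; all values finite.
#' @param bit_depth one of `8`, `16`, or `"float"` (source metadata only;
#'   the pixel values themselves are always stored as doubles).
#' @return An object of class `mpl_image` with fields `pixels`, `height`,
#'   `width`, `bit_depth`.
#' @export
mpl_image <- function(pixels, bit_depth = "float") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("zero-size image")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite intensity values")
  bd <- as.character(bit_depth)
  if (!bd %in% c("8", "16", "float"))
    stop("bit_depth must be 8, 16 or \"float\"")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         bit_depth = bd),
    class = "mpl_image")
}

#' @export
print.mpl_image <- function(x, ...) {
  cat(sprintf("<mpl_image> %d x %d px (%s-bit source), range [%g, %g]\n",
              x$width, x$height, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a grayscale micrograph
#'
#' Reads a single-channel TIFF or PNG into an [mpl_image]. Values are kept
#' in native units: a pixel stored as 131 in an 8-bit file loads as 131.0.
#' RGB files whose three channels are identical are collapsed to one
#' channel; genuinely multi-channel files are rejected.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return An [mpl_image]; `bit_depth` records the source sample format.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image '%s': file does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    ti <- read_tiff_gray(path)
    img <- mpl_image(ti$pixels, ti$bit_depth)
  } else if (ext == "png") {
    img <- read_png_gray(path)
  } else {
    stop(sprintf("cannot read image '%s': unsupported extension '%s' (TIFF or PNG expected)",
                 path, ext))
  }
  if (img$bit_depth %in% c("8", "16") && any(img$pixels < 0))
    stop("negative intensities in an integer-typed file")  # cannot happen for well-formed files
  img
}

#' Write a grayscale micrograph
#'
#' Writes an [mpl_image] to TIFF (8-bit, 16-bit, or 32-bit float) or PNG
#' (8-bit or 16-bit). For integer bit depths, values are rounded
#' half-away-from-zero and clipped to the representable range, so e.g.
#' 99.6 stores as 100 and -10 stores as 0. Float TIFF preserves values
#' exactly (to 32-bit precision; integers up to 2^24 are exact).
#'
#' @param img an [mpl_image].
#' @param path output path; `.tif`/`.tiff` or `.png`.
#' @param bit_depth `8`, `16`, or `"float"` (float is TIFF-only).
#' @param compression for TIFF: `"none"` or `"deflate"`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bit_depth = 8, compression = "none") {
  stopifnot(inherits(img, "mpl_image"))
  bd <- as.character(bit_depth)
  if (!bd %in% c("8", "16", "float"))
    stop("bit_depth must be 8, 16 or \"float\"")
  ext <- tolower(tools::file_ext(path))
  px <- img$pixels
  if (bd != "float")
    px <- clip_quantize(px, if (bd == "8") 255 else 65535)
  if (ext %in% c("tif", "tiff")) {
    write_tiff_gray(px, path, bd, compression = compression)
  } else if (ext == "png") {
    if (bd == "float")
      stop("float bit depth requires TIFF output")
    if (bd == "8") {
      png::writePNG(px / 255, path)
    } else {
      write_png16_gray(px, path)
    }
  } else {
    stop(sprintf("unsupported output extension '%s'", ext))
  }
  invisible(path)
}

# round half away from zero, then clip to [0, vmax]
clip_quantize <- function(x, vmax) {
  q <- trunc(x + 0.5 * sign(x))
  pmin(pmax(q, 0), vmax)
}

# ---- PNG reading (via the png package; undo its [0,1] rescaling) ----

read_png_gray <- function(path) {
  arr <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e)
                    stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e))))
  info <- attr(arr, "info")
  depth <- info$bit.depth
  scale <- 2^depth - 1
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    ch <- if (nc %in% c(2L, 4L)) nc - 1L else nc  # last channel is alpha
    if (nc %in% c(2L, 4L) && any(arr[, , nc] != 1))
      stop(sprintf("'%s' has a non-trivial alpha channel: not grayscale", path))
    if (ch > 1L) {
      for (k in seq_len(ch - 1L))
        if (any(arr[, , k] != arr[, , k + 1L]))
          stop(sprintf("'%s' has unequal color channels: not grayscale", path))
    }
    arr <- arr[, , 1L]
  }
  # readPNG returns k/scale for stored integer k; recover k exactly
  px <- round(arr * scale)
  attributes(px) <- list(dim = dim(px))
  mpl_image(px, bit_depth = as.character(depth))
}
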