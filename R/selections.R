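#' Line selections of standards and fibrils
#'
#' A selection set replaces interactive picking: each record designates one
#' straight segment along a filament's long axis, labelled either
#' `"standard"` (known-MPL calibrant, e.g. TMV) or `"fibril"` (unknown),
#' with the band width to integrate over. Coordinates are 0-based pixel
#' centers, x = column, y = row. Segments of one curved fibril may be
#' chained by sharing a fibril id before a `":"` in the label, e.g.
#' `"F1:a"`, `"F1:b"`.
#'
#' @param lines a data.frame with columns `kind`, `label`, `x0`, `y0`,
#'   `x1`, `y1`, `width` (one row per selection; may have zero rows).
#' @param image_ref optional file name the selections apply to.
#' @return An object of class `selection_set`.
#' @export
selection_set <- function(lines = NULL, image_ref = NA_character_) {
  if (is.null(lines))
    lines <- data.frame(kind = character(), label = character(),
                        x0 = numeric(), y0 = numeric(),
                        x1 = numeric(), y1 = numeric(), width = numeric(),
                        stringsAsFactors = FALSE)
  need <- c("kind", "label", "x0", "y0", "x1", "y1", "width")
  if (!all(need %in% names(lines)))
    stop("selection lines need columns: ", paste(need, collapse = ", "))
  lines <- lines[, need, drop = FALSE]
  lines$kind <- as.character(lines$kind)
  lines$label <- as.character(lines$label)
  for (cn in need[3:7]) lines[[cn]] <- as.numeric(lines[[cn]])
  rownames(lines) <- NULL
  validate_selection_lines(lines)
  structure(list(image_ref = image_ref, lines = lines), class = "selection_set")
}

validate_selection_lines <- function(lines) {
  bad_kind <- setdiff(unique(lines$kind), c("standard", "fibril"))
  if (length(bad_kind))
    stop(sprintf("unknown selection kind '%s' (expected 'standard' or 'fibril')",
                 bad_kind[1]))
  for (i in seq_len(nrow(lines))) {
    ln <- lines[i, ]
    L <- sqrt((ln$x1 - ln$x0)^2 + (ln$y1 - ln$y0)^2)
    if (L == 0)
      stop(sprintf("selection '%s': zero-length segment", ln$label))
    if (L < 2)
      stop(sprintf("selection '%s': axial length %.3g px is below the 2 px minimum",
                   ln$label, L))
    if (!is.finite(ln$width) || ln$width <= 0)
      stop(sprintf("selection '%s': width must be positive", ln$label))
    if (ln$width < 1)
      stop(sprintf("selection '%s': width %.3g px is below the 1 px minimum",
                   ln$label, ln$width))
  }
  for (k in unique(lines$kind)) {
    labs <- lines$label[lines$kind == k]
    if (anyDuplicated(labs))
      stop(sprintf("duplicate %s label '%s'", k, labs[duplicated(labs)][1]))
  }
  invisible(lines)
}

#' @export
print.selection_set <- function(x, ...) {
  cat(sprintf("<selection_set> %d standard(s), %d fibril segment(s)%s\n",
              sum(x$lines$kind == "standard"), sum(x$lines$kind == "fibril"),
              if (is.na(x$image_ref)) "" else paste0(" for ", x$image_ref)))
  if (nrow(x$lines)) print(x$lines)
  invisible(x)
}

SELECTION_COLS <- c("kind", "label", "x0", "y0", "x1", "y1", "width")

#' Parse a selection file
#'
#' Reads the plain-text selection format: tab-separated records
#' `kind label x0 y0 x1 y1 width`, `#` starting a comment, blank lines
#' ignored, optional header auto-detected (non-numeric third field).
#' CRLF line endings and trailing whitespace are tolerated. A `.json` file
#' holding an array of objects with the same fields is accepted as a
#' machine-oriented mirror of the format.
#'
#' @param path path to a `.tsv`/`.txt` selection file or its `.json` mirror.
#' @return A [selection_set]; records keep file order.
#' @export
parse_selections <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read selections '%s': file does not exist", path))
  if (tolower(tools::file_ext(path)) == "json") {
    recs <- jsonlite::fromJSON(path)
    if (length(recs) == 0) return(selection_set())
    return(selection_set(as.data.frame(recs, stringsAsFactors = FALSE)))
  }
  raw_lines <- readLines(path, warn = FALSE)
  raw_lines <- sub("\r$", "", raw_lines)
  raw_lines <- sub("#.*$", "", raw_lines)
  raw_lines <- sub("[ \t]+$", "", raw_lines)
  keep <- which(nzchar(trimws(raw_lines)))
  if (!length(keep)) return(selection_set())

  first <- strsplit(raw_lines[keep[1]], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
    keep <- keep[-1]  # header row
  if (!length(keep)) return(selection_set())

  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(raw_lines[i], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) != 7L)
      stop(sprintf("parse error at line %d of '%s': expected 7 tab-separated fields, got %d",
                   i, path, length(f)))
    nums <- suppressWarnings(as.numeric(f[3:7]))
    if (any(is.na(nums)))
      stop(sprintf("parse error at line %d of '%s': non-numeric coordinate or width",
                   i, path))
    recs[[j]] <- data.frame(kind = f[1], label = f[2],
                            x0 = nums[1], y0 = nums[2], x1 = nums[3],
                            y1 = nums[4], width = nums[5],
                            stringsAsFactors = FALSE)
  }
  selection_set(do.call(rbind, recs), image_ref = NA_character_)
}

#' Write a selection file
#'
#' Writes the TSV dialect read by [parse_selections()] (or its JSON mirror
#' when `path` ends in `.json`). `parse_selections(write_selections(x, p))`
#' reproduces `x` field-for-field; float coordinates survive exactly.
#'
#' @param sel a [selection_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selections <- function(sel, path) {
  stopifnot(inherits(sel, "selection_set"))
  if (tolower(tools::file_ext(path)) == "json") {
    ok <- tryCatch({
      jsonlite::write_json(sel$lines, path, dataframe = "rows", digits = NA)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("cannot write '%s'", path))
    return(invisible(path))
  }
  num <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
                  sel$lines$kind, sel$lines$label,
                  num(sel$lines$x0), num(sel$lines$y0),
                  num(sel$lines$x1), num(sel$lines$y1), num(sel$lines$width))
  out <- c(paste(SELECTION_COLS, collapse = "\t"), body)
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write '%s'", path))
  invisible(path)
}

# fibril id shared by chained segments: label text before the first ":"
fibril_id <- function(label) sub(":.*$", "", label)
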