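#' Bilinear intensity sampling
#'
#' Samples image intensity at arbitrary (possibly fractional) pixel
#' coordinates by bilinear interpolation of the four surrounding pixel
#' centers; at integer coordinates this returns the stored pixel value
#' exactly. Points outside `[0, width-1] x [0, height-1]` yield `NA`
#' (the caller discards affected slices rather than zero-filling).
#'
#' @param img an [mpl_image].
#' @param x,y numeric vectors of 0-based coordinates (x = column, y = row).
#' @return Numeric vector of interpolated intensities, `NA` where outside.
#' @export
sample_point <- function(img, x, y) {
  stopifnot(inherits(img, "mpl_image"), length(x) == length(y))
  W <- img$width; H <- img$height; p <- img$pixels
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmax(pmin(floor(xs), W - 2L), 0L)   # W == 1 collapses to column 0
  y0 <- pmax(pmin(floor(ys), H - 2L), 0L)
  fx <- xs - x0; fy <- ys - y0
  x1 <- pmin(x0 + 1, W - 1L); y1 <- pmin(y0 + 1, H - 1L)
  idx <- function(xx, yy) p[yy + 1L + xx * H]   # column-major linear index
  out[ok] <- (1 - fx) * (1 - fy) * idx(x0, y0) + fx * (1 - fy) * idx(x1, y0) +
             (1 - fx) * fy       * idx(x0, y1) + fx * fy       * idx(x1, y1)
  out
}

#' Extract a per-slice line profile
#'
#' Walks a selection in 1-px axial steps and, at each step, samples three
#' one-pixel-thick bands perpendicular to the axis: the signal band of
#' width `w` centered on the axis, and two flanking background bands of
#' the same width offset laterally by `w + gap`. Each band is summed into
#' one slice record. The fractional width is rounded to an integer sample
#' count `nw = round(w)`; sample offsets along the normal are
#' `-(nw-1)/2, ..., (nw-1)/2`. Slices with any of the `3 nw` sample points
#' outside the image are discarded (never zero-filled) and counted in
#' `n_dropped`; axial steps run `s = 0, ..., floor(L)` so a selection of
#' length 10 attempts 11 slices.
#'
#' @param img an [mpl_image].
#' @param sel one selection: a single row of a [selection_set]'s `lines`
#'   data.frame (or any list with fields `kind`, `label`, `x0`, `y0`,
#'   `x1`, `y1`, `width`).
#' @param gap lateral clearance in px between the signal band edge and the
#'   start of each background band (default 2, to avoid filament-edge
#'   bleed).
#' @return An object of class `line_profile`: list with `selection`, a
#'   `slices` data.frame (`slice_index`, `x`, `y`, `I`, `B_left`,
#'   `B_right`, `n_samples`), and `n_dropped`.
#' @export
extract_profile <- function(img, sel, gap = 2) {
  stopifnot(inherits(img, "mpl_image"), gap >= 0)
  sel <- as.list(sel)
  dx <- sel$x1 - sel$x0; dy <- sel$y1 - sel$y0
  L <- sqrt(dx^2 + dy^2)
  if (L == 0) stop(sprintf("selection '%s': zero-length segment", sel$label))
  u <- c(dx, dy) / L
  nv <- c(-u[2], u[1])                       # +90 deg rotation, y-down coords
  nw <- as.integer(round(sel$width))
  if (nw < 1L) stop(sprintf("selection '%s': width must round to >= 1 px", sel$label))
  tk <- seq(-(nw - 1) / 2, (nw - 1) / 2, by = 1)
  offs <- c(tk, tk - (nw + gap), tk + (nw + gap))   # signal, left bg, right bg
  s <- 0:floor(L)
  cx <- sel$x0 + s * u[1]; cy <- sel$y0 + s * u[2]
  px <- outer(cx, offs * nv[1], `+`)
  py <- outer(cy, offs * nv[2], `+`)
  vals <- matrix(sample_point(img, as.vector(px), as.vector(py)),
                 nrow = length(s))
  keep <- rowSums(is.na(vals)) == 0L
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop(sprintf("selection '%s' outside usable area: all %d slices dropped",
                 sel$label, length(s)))
  v <- vals[keep, , drop = FALSE]
  bands <- seq_len(nw)
  slices <- data.frame(
    slice_index = s[keep], x = cx[keep], y = cy[keep],
    I       = rowSums(v[, bands, drop = FALSE]),
    B_left  = rowSums(v[, bands + nw, drop = FALSE]),
    B_right = rowSums(v[, bands + 2L * nw, drop = FALSE]),
    n_samples = nw)
  structure(list(selection = sel, slices = slices, n_dropped = n_dropped),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %s '%s': %d slices (%d dropped at borders), w = %g px\n",
              x$selection$kind, x$selection$label, nrow(x$slices), x$n_dropped,
              x$selection$width))
  invisible(x)
}

#' Extract profiles for a whole selection set
#'
#' @param img an [mpl_image].
#' @param sel a [selection_set].
#' @param gap background-band clearance in px, passed to [extract_profile()].
#' @param width optional global width override in px applied to every
#'   selection (the per-selection widths in the file are kept otherwise).
#' @return Named list of `line_profile` objects, keyed by label, in file
#'   order.
#' @export
extract_profiles <- function(img, sel, gap = 2, width = NULL) {
  stopifnot(inherits(sel, "selection_set"))
  lines <- sel$lines
  if (!nrow(lines)) stop("selection set is empty")
  if (!is.null(width)) {
    if (width < 1) stop("global width override must be >= 1 px")
    lines$width <- width
  }
  profs <- lapply(seq_len(nrow(lines)),
                  function(i) extract_profile(img, lines[i, ], gap = gap))
  names(profs) <- lines$label
  profs
}

profiles_of_kind <- function(profiles, kind)
  Filter(function(p) p$selection$kind == kind, profiles)
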