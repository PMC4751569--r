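#' Specify a synthetic bar phantom
#'
#' Describes the validation image used throughout the package's test
#' machinery: vertical bars of exact integer width on a uniform (default
#' black) background with additive i.i.d. Gaussian noise. The default
#' reproduces the canonical three-bar layout: a 131-valued bar standing in
#' for the TMV standard plus two fibril bars of intensity 100 ("A") and
#' 200 ("B"), each 25 px wide, noise SD 25, on a 512 x 512 black field.
#' Noise is added in floating point and not clipped unless `clip_to_8bit`
#' is set, because truncating the noise floor at 0 biases background
#' estimates upward (a documented effect of real 8-bit conversion that
#' the clipped mode exists to demonstrate).
#'
#' @param height,width image size in px.
#' @param bars data.frame with columns `center_x`, `width`, `value`,
#'   `label`, `kind`; widths are integer px, values in intensity units.
#' @param background_level background intensity.
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param seed RNG seed for the noise field.
#' @param clip_to_8bit round and clip the final image to \[0, 255\].
#' @param sel_width band width in px for the generated selections.
#' @param sel_offset lateral shift in px applied to generated selections
#'   (emulates imperfect centering by the user; default 0).
#' @param sel_inset endpoint inset from top/bottom edges in px.
#' @param gap background-band clearance assumed when checking that bars
#'   (with their background bands) stay clear of one another.
#' @param mod_amplitude,mod_period optional sinusoidal intensity
#'   modulation along the axis of fibril bars, `v * (1 + A sin(2 pi y /
#'   period))` - emulates structural heterogeneity along a fibril.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 512, width = 512,
                         bars = data.frame(
                           center_x = c(100, 256, 412),
                           width = 25,
                           value = c(131, 100, 200),
                           label = c("TMV1", "A", "B"),
                           kind = c("standard", "fibril", "fibril"),
                           stringsAsFactors = FALSE),
                         background_level = 0, noise_sd = 25, seed = 1,
                         clip_to_8bit = FALSE, sel_width = 30,
                         sel_offset = 0, sel_inset = 5, gap = 2,
                         mod_amplitude = 0, mod_period = 64) {
  stopifnot(height >= 1, width >= 1, nrow(bars) >= 1, noise_sd >= 0,
            all(bars$width >= 1), mod_amplitude >= 0, mod_period > 0)
  bars$width <- as.integer(round(bars$width))
  ord <- order(bars$center_x)
  b <- bars[ord, ]
  margin <- 2 * (sel_width + gap)
  if (nrow(b) > 1) {
    edge_gap <- (b$center_x[-1] - b$width[-1] / 2) -
                (b$center_x[-nrow(b)] + b$width[-nrow(b)] / 2)
    if (any(edge_gap < margin))
      stop(sprintf("bars overlap within the %g px background-band margin", margin))
  }
  structure(list(height = height, width = width, bars = bars,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = seed, clip_to_8bit = clip_to_8bit,
                 sel_width = sel_width, sel_offset = sel_offset,
                 sel_inset = sel_inset, gap = gap,
                 mod_amplitude = mod_amplitude, mod_period = mod_period),
            class = "phantom_spec")
}

# run code under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate a bar phantom and its selections
#'
#' Renders the bars of a [phantom_spec()] (exact integer width, centered
#' at `center_x`; even widths extend one extra column to the right), adds
#' seeded Gaussian noise in floating point, and builds the matching
#' [selection_set]: one full-height selection per bar at `center_x +
#' sel_offset`, endpoints inset `sel_inset` px from the top and bottom
#' edges.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `image` ([mpl_image]) and `selections`
#'   ([selection_set]). A fixed seed gives a bit-identical image.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  px <- matrix(spec$background_level, H, W)
  y <- 0:(H - 1)
  for (i in seq_len(nrow(spec$bars))) {
    bar <- spec$bars[i, ]
    cols <- bar$center_x - floor((bar$width - 1) / 2) + 0:(bar$width - 1)
    if (any(cols < 0 | cols > W - 1)) stop(sprintf("bar '%s' exceeds the image", bar$label))
    v <- rep(bar$value, H)
    if (spec$mod_amplitude > 0 && bar$kind == "fibril")
      v <- bar$value * (1 + spec$mod_amplitude * sin(2 * pi * y / spec$mod_period))
    px[, cols + 1L] <- v
  }
  if (spec$noise_sd > 0)
    px <- px + with_local_seed(spec$seed,
                               matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W))
  depth <- "float"
  if (spec$clip_to_8bit) {
    px <- clip_quantize(px, 255)
    depth <- "8"
  }
  sel <- selection_set(data.frame(
    kind = spec$bars$kind, label = spec$bars$label,
    x0 = spec$bars$center_x + spec$sel_offset, y0 = spec$sel_inset,
    x1 = spec$bars$center_x + spec$sel_offset, y1 = H - 1 - spec$sel_inset,
    width = spec$sel_width, stringsAsFactors = FALSE))
  list(image = mpl_image(px, depth), selections = sel)
}

#' Width-robustness sweep
#'
#' Repeats the full measurement pipeline on fresh noise realisations while
#' varying the band width applied to one target bar, reproducing the
#' classic robustness experiment: MPL is systematically underestimated
#' while `w` is below the true bar width and plateaus at nominal once `w`
#' comfortably exceeds it. The standards keep the spec's `sel_width`
#' (sweeping the standard too would cancel the bias being demonstrated).
#' Replicate r uses seed `spec$seed + r - 1`; slices are pooled across
#' replicates per width.
#'
#' @param spec a [phantom_spec()].
#' @param target_label label of the bar whose width is swept.
#' @param widths vector of band widths in px.
#' @param replicates noise realisations per width.
#' @param K calibration constant in kDa/nm.
#' @return data.frame with `width`, `mean_mpl`, `sem`, `n_slices`.
#' @export
width_sweep <- function(spec, target_label, widths, replicates = 1, K = 131) {
  stopifnot(inherits(spec, "phantom_spec"), length(widths) >= 1, replicates >= 1)
  if (!target_label %in% spec$bars$label)
    stop(sprintf("no bar labelled '%s' in the phantom spec", target_label))
  rows <- lapply(widths, function(w) {
    mpls <- unlist(lapply(seq_len(replicates), function(r) {
      sp <- spec; sp$seed <- spec$seed + r - 1
      ph <- generate_phantom(sp)
      lines <- ph$selections$lines
      lines$width[lines$label == target_label] <- w
      profs <- extract_profiles(ph$image, selection_set(lines), gap = spec$gap)
      cal <- calibrate(profiles_of_kind(profs, "standard"), K = K)
      mpl_per_slice(profs[[target_label]]$slices, cal)
    }))
    data.frame(width = w, mean_mpl = mean(mpls),
               sem = if (length(mpls) > 1) stats::sd(mpls) / sqrt(length(mpls)) else 0,
               n_slices = length(mpls))
  })
  do.call(rbind, rows)
}

#' Generate a curved-fibril phantom
#'
#' Renders a ribbon whose axis follows `x = center + A sin(2 pi y /
#' period)` with constant integrated intensity per unit arc length (row
#' values are scaled by the local axis obliquity), plus a straight
#' standard bar, and chains short straight selection segments along the
#' curve sharing the fibril id `"F"` (labels `F:01`, `F:02`, ...). This
#' exercises the multi-segment selection strategy for non-straight
#' fibrils: with segments no longer than about `period/8`, chord-vs-arc
#' error keeps the recovered MPL within a few percent of nominal.
#'
#' @param amplitude sine amplitude in px (0 gives a straight bar).
#' @param period sine period in px.
#' @param height,width image size in px.
#' @param ribbon_center_x,ribbon_width,ribbon_value ribbon geometry and
#'   intensity (width need not be integer; edge pixels get fractional
#'   coverage).
#' @param standard_center_x,standard_width,standard_value straight
#'   standard bar as in [generate_phantom()].
#' @param background_level,noise_sd,seed as in [phantom_spec()].
#' @param sel_width selection band width in px.
#' @param seg_len segment length in rows (default `period / 8`).
#' @param sel_inset top/bottom inset in px.
#' @param gap background-band clearance used for the geometry check.
#' @return List with `image`, `selections`, and `nominal_mpl` (the MPL in
#'   kDa/nm that an ideal measurement recovers, `ribbon_width *
#'   ribbon_value / (standard_width * standard_value) * 131`).
#' @export
generate_curved_phantom <- function(amplitude, period, height = 512, width = 512,
                                    ribbon_center_x = 160, ribbon_width = 15,
                                    ribbon_value = 150,
                                    standard_center_x = 400, standard_width = 25,
                                    standard_value = 131,
                                    background_level = 0, noise_sd = 0, seed = 1,
                                    sel_width = 30, seg_len = period / 8,
                                    sel_inset = 5, gap = 2) {
  stopifnot(amplitude >= 0, period > 0, seg_len >= 2)
  H <- height; W <- width
  reach <- 1.5 * sel_width + gap          # farthest background-band sample offset
  rib_max <- ribbon_center_x + amplitude + ribbon_width / 2
  rib_min <- ribbon_center_x - amplitude - ribbon_width / 2
  std_min <- standard_center_x - standard_width / 2
  if (rib_min - reach < 0 || rib_max + reach > W - 1 ||
      rib_max + reach > std_min - reach)
    stop("geometry overflow: ribbon or its background bands leave the image or touch the standard")

  px <- matrix(background_level, H, W)
  std_cols <- standard_center_x - floor((standard_width - 1) / 2) + 0:(standard_width - 1)
  px[, std_cols + 1L] <- standard_value

  xs <- 0:(W - 1)
  for (yi in 0:(H - 1)) {
    cx <- ribbon_center_x + amplitude * sin(2 * pi * yi / period)
    slope <- amplitude * (2 * pi / period) * cos(2 * pi * yi / period)
    val <- ribbon_value * sqrt(1 + slope^2)   # keeps mass per unit arc constant
    cover <- pmax(0, pmin(xs + 0.5, cx + ribbon_width / 2) -
                     pmax(xs - 0.5, cx - ribbon_width / 2))
    hit <- cover > 0
    px[yi + 1L, hit] <- px[yi + 1L, hit] + val * cover[hit]
  }
  if (noise_sd > 0)
    px <- px + with_local_seed(seed, matrix(stats::rnorm(H * W, 0, noise_sd), H, W))

  ys <- seq(sel_inset, H - 1 - sel_inset, by = seg_len)
  if (tail(ys, 1) < H - 1 - sel_inset) ys <- c(ys, H - 1 - sel_inset)
  ax <- ribbon_center_x + amplitude * sin(2 * pi * ys / period)
  nseg <- length(ys) - 1L
  seg <- data.frame(
    kind = "fibril", label = sprintf("F:%02d", seq_len(nseg)),
    x0 = ax[-length(ax)], y0 = ys[-length(ys)],
    x1 = ax[-1L], y1 = ys[-1L], width = sel_width,
    stringsAsFactors = FALSE)
  std <- data.frame(kind = "standard", label = "TMV1",
                    x0 = standard_center_x, y0 = sel_inset,
                    x1 = standard_center_x, y1 = H - 1 - sel_inset,
                    width = sel_width, stringsAsFactors = FALSE)
  list(image = mpl_image(px, "float"),
       selections = selection_set(rbind(std, seg)),
       nominal_mpl = ribbon_width * ribbon_value /
                     (standard_width * standard_value) * 131)
}
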