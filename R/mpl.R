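#' Calibrate against in-image standards
#'
#' Pools every retained slice of every standard profile and averages the
#' background-corrected intensity `I - (B_left + B_right)/2` into a single
#' calibration constant `C_std`, the per-slice intensity corresponding to
#' `K` kDa/nm. Pooling slices (rather than per-standard means) weights
#' long standards more; set `per_standard_mean = TRUE` for equal weight
#' per standard molecule instead.
#'
#' @param standard_profiles list of `line_profile` objects for standard
#'   selections (see [extract_profile()]).
#' @param K MPL of the standard in kDa/nm; 131 for tobacco mosaic virus.
#' @param per_standard_mean average per-standard means instead of pooling
#'   slices.
#' @return An object of class `standard_calibration`: `K`, `C_std`,
#'   `sd_std`, `n_std_lines`, `n_std_slices`.
#' @export
calibrate <- function(standard_profiles, K = 131, per_standard_mean = FALSE) {
  if (!length(standard_profiles))
    stop("no standard selections: at least one standard is required for calibration")
  stopifnot(K > 0)
  corr <- lapply(standard_profiles, function(p)
    p$slices$I - (p$slices$B_left + p$slices$B_right) / 2)
  all_corr <- unlist(corr, use.names = FALSE)
  if (!length(all_corr)) stop("calibration error: standards contributed no slices")
  C_std <- if (per_standard_mean) mean(vapply(corr, mean, 0)) else mean(all_corr)
  if (C_std <= 0)
    stop("calibration error: standard darker than background - check beam tilt/selections")
  structure(list(K = K, C_std = C_std,
                 sd_std = if (length(all_corr) > 1) stats::sd(all_corr) else 0,
                 n_std_lines = length(standard_profiles),
                 n_std_slices = length(all_corr)),
            class = "standard_calibration")
}

#' @export
print.standard_calibration <- function(x, ...) {
  cat(sprintf("<standard_calibration> K = %g kDa/nm, C_std = %.4g (sd %.4g) from %d standard(s), %d slices\n",
              x$K, x$C_std, x$sd_std, x$n_std_lines, x$n_std_slices))
  invisible(x)
}

#' Per-slice MPL
#'
#' Applies the calibrated densitometry ratio to slice measurements:
#' `MPL = (I - (B_left + B_right)/2) / C_std * K`. Negative values are
#' possible on noise and deliberately retained: clipping them would bias
#' the mean upward.
#'
#' @param slices a slice data.frame from a `line_profile` (or one row).
#' @param cal a `standard_calibration` from [calibrate()].
#' @return Numeric vector of per-slice MPL values in kDa/nm.
#' @export
mpl_per_slice <- function(slices, cal) {
  stopifnot(inherits(cal, "standard_calibration"))
  (slices$I - (slices$B_left + slices$B_right) / 2) / cal$C_std * cal$K
}

#' Measure one fibril profile
#'
#' @param profile a `line_profile`.
#' @param cal a `standard_calibration`.
#' @return An object of class `mpl_measurement`: `label`, `slice_mpls`,
#'   `mean_mpl`, `sd_mpl`, `sem_mpl`, `n_slices`. With a single slice, sd
#'   and sem are reported as 0 (n = 1 is visible in `n_slices`).
#' @export
measure_fibril <- function(profile, cal) {
  stopifnot(inherits(profile, "line_profile"))
  m <- mpl_per_slice(profile$slices, cal)
  if (!length(m)) stop(sprintf("profile '%s' has no slices", profile$selection$label))
  s <- if (length(m) > 1) stats::sd(m) else 0
  structure(list(label = profile$selection$label, slice_mpls = m,
                 mean_mpl = mean(m), sd_mpl = s, sem_mpl = s / sqrt(length(m)),
                 n_slices = length(m)),
            class = "mpl_measurement")
}

#' Merge chained segments of one fibril
#'
#' Concatenates the slices of several profiles (segments sharing a fibril
#' id) into one profile so that statistics treat them as a single fibril.
#' Consecutive-slice pairing for [fluctuation_analysis()] must use the
#' original per-segment profiles, not the merged one.
#'
#' @param profiles list of `line_profile` objects.
#' @param label label for the merged profile.
#' @return A `line_profile` whose slices are the segments' slices in
#'   order, with `slice_index` renumbered consecutively per segment block.
#' @export
merge_profiles <- function(profiles, label) {
  stopifnot(length(profiles) >= 1)
  sl <- do.call(rbind, lapply(profiles, function(p) p$slices))
  sl$slice_index <- seq_len(nrow(sl)) - 1L
  sel <- profiles[[1]]$selection
  sel$label <- label
  structure(list(selection = sel, slices = sl,
                 n_dropped = sum(vapply(profiles, function(p) p$n_dropped, 0L))),
            class = "line_profile")
}

#' Aggregate fibril measurements
#'
#' Emits both aggregation conventions side by side: pooled statistics over
#' all slices of all fibrils (every 1-px measurement weighted equally -
#' the headline number) and fibril-level statistics over per-fibril means.
#' Which of these a published "mean +/- x" refers to is often ambiguous,
#' so neither is guessed: all are named explicitly.
#'
#' @param measurements list of `mpl_measurement` objects.
#' @return An object of class `mpl_summary`: `per_fibril` (data.frame),
#'   `pooled_mean`, `pooled_sd`, `fibril_mean`, `fibril_sd`, `fibril_sem`,
#'   `n_fibrils`, `n_measurements`.
#' @export
summarize_mpl <- function(measurements) {
  if (!length(measurements)) stop("no fibril measurements to summarize")
  stopifnot(all(vapply(measurements, inherits, TRUE, "mpl_measurement")))
  all_m <- unlist(lapply(measurements, function(m) m$slice_mpls), use.names = FALSE)
  fm <- vapply(measurements, function(m) m$mean_mpl, 0)
  per <- data.frame(
    label = vapply(measurements, function(m) m$label, ""),
    n_slices = vapply(measurements, function(m) m$n_slices, 0L),
    mean_mpl = fm,
    sd_mpl = vapply(measurements, function(m) m$sd_mpl, 0),
    sem_mpl = vapply(measurements, function(m) m$sem_mpl, 0),
    row.names = NULL)
  structure(list(
    per_fibril = per,
    pooled_mean = mean(all_m),
    pooled_sd = if (length(all_m) > 1) stats::sd(all_m) else 0,
    fibril_mean = mean(fm),
    fibril_sd = if (length(fm) > 1) stats::sd(fm) else 0,
    fibril_sem = if (length(fm) > 1) stats::sd(fm) / sqrt(length(fm)) else 0,
    n_fibrils = length(measurements),
    n_measurements = length(all_m)),
    class = "mpl_summary")
}

#' @export
print.mpl_summary <- function(x, ...) {
  cat(sprintf("<mpl_summary> pooled mean MPL %.4g kDa/nm (sd %.3g); fibril-level mean %.4g (sd %.3g, sem %.3g); n = %d fibrils, %d measurements\n",
              x$pooled_mean, x$pooled_sd, x$fibril_mean, x$fibril_sd,
              x$fibril_sem, x$n_fibrils, x$n_measurements))
  invisible(x)
}

#' Background-fluctuation error statistic
#'
#' Quantifies measurement noise from consecutive-slice differences, 1 px
#' apart along the axis: `sd_bg_diff` is the SD of `B(s) - B(s+1)` where
#' `B = (B_left + B_right)/2`, and `sd_fibril_diff` the same statistic on
#' the background-corrected signal `I - B`. Pairs are formed only between
#' consecutive retained `slice_index` values within one selection - never
#' across selections or across gaps left by dropped slices. An excess of
#' `sd_fibril_diff` over `sd_bg_diff` signals intensity variation beyond
#' background noise, e.g. structural heterogeneity along the fibril.
#' About-mean SDs of the two series are emitted as secondary statistics.
#'
#' @param profiles list of `line_profile` objects (typically the fibril
#'   profiles of a run).
#' @return An object of class `fluctuation_report`: `sd_bg_diff`,
#'   `sd_fibril_diff`, `n_pairs_bg`, `n_pairs_fibril`, plus secondary
#'   `sd_bg_about_mean`, `sd_fibril_about_mean`.
#' @export
fluctuation_analysis <- function(profiles) {
  if (!length(profiles)) stop("no profiles for fluctuation analysis")
  d_bg <- list(); d_fib <- list(); bg_all <- list(); fib_all <- list()
  for (p in profiles) {
    sl <- p$slices
    B <- (sl$B_left + sl$B_right) / 2
    C <- sl$I - B
    bg_all[[length(bg_all) + 1L]] <- B
    fib_all[[length(fib_all) + 1L]] <- C
    if (nrow(sl) < 2) next
    consec <- which(diff(sl$slice_index) == 1L)  # skip gaps from dropped slices
    if (!length(consec)) next
    d_bg[[length(d_bg) + 1L]] <- B[consec] - B[consec + 1L]
    d_fib[[length(d_fib) + 1L]] <- C[consec] - C[consec + 1L]
  }
  d_bg <- unlist(d_bg); d_fib <- unlist(d_fib)
  if (length(d_bg) < 2)
    stop("fluctuation analysis needs at least 2 consecutive-slice pairs")
  bg_all <- unlist(bg_all); fib_all <- unlist(fib_all)
  structure(list(
    sd_bg_diff = stats::sd(d_bg), sd_fibril_diff = stats::sd(d_fib),
    n_pairs_bg = length(d_bg), n_pairs_fibril = length(d_fib),
    sd_bg_about_mean = stats::sd(bg_all), sd_fibril_about_mean = stats::sd(fib_all)),
    class = "fluctuation_report")
}

#' @export
print.fluctuation_report <- function(x, ...) {
  cat(sprintf("<fluctuation_report> sd(B1-B2) = %.4g (%d pairs); sd of corrected fibril diffs = %.4g (%d pairs)\n",
              x$sd_bg_diff, x$n_pairs_bg, x$sd_fibril_diff, x$n_pairs_fibril))
  invisible(x)
}

#' Text histogram of slice MPL values
#'
#' @param mpls numeric vector of per-slice MPL values.
#' @param bin_width bin width in kDa/nm (default 5).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`; bins aligned to
#'   multiples of `bin_width`, closed on the left.
#' @export
mpl_histogram <- function(mpls, bin_width = 5) {
  stopifnot(length(mpls) >= 1, bin_width > 0)
  lo <- floor(min(mpls) / bin_width) * bin_width
  hi <- ceiling(max(mpls) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- pmin(findInterval(mpls, breaks), length(breaks) - 1L)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             count = tabulate(idx, nbins = length(breaks) - 1L))
}
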