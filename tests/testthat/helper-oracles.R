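# Shared fixtures and independent oracles, built in code at test time.

# brute-force band sums for a vertical selection at integer x with odd
# integer w: direct pixel sums, no interpolation
brute_vertical_bands <- function(px, x, ys, w, gap) {
  hw <- (w - 1) / 2
  sig <- (x - hw):(x + hw)
  t(vapply(ys, function(y) c(
    I = sum(px[y + 1, sig + 1]),
    B_left = sum(px[y + 1, sig - (w + gap) + 1]),
    B_right = sum(px[y + 1, sig + (w + gap) + 1])), c(I = 0, B_left = 0, B_right = 0)))
}

# one-selection set around a vertical segment
vsel <- function(x, y0, y1, width, kind = "fibril", label = "F1")
  data.frame(kind = kind, label = label, x0 = x, y0 = y0, x1 = x, y1 = y1,
             width = width, stringsAsFactors = FALSE)

rand_image <- function(h, w, seed = 42, lo = 0, hi = 255) {
  set.seed(seed)
  mpl_image(matrix(runif(h * w, lo, hi), h, w))
}

# calibration object with a chosen C_std, for formula-level tests
fake_cal <- function(C_std, K = 131)
  structure(list(K = K, C_std = C_std, sd_std = 0,
                 n_std_lines = 1L, n_std_slices = 1L),
            class = "standard_calibration")

# a line_profile with given slice indices and band values, for unit tests
fake_profile <- function(slice_index, I, B_left = 0, B_right = 0,
                         label = "F1", kind = "fibril") {
  structure(list(
    selection = list(kind = kind, label = label, x0 = 0, y0 = 0, x1 = 0,
                     y1 = length(slice_index), width = 1),
    slices = data.frame(slice_index = slice_index, x = 0, y = slice_index,
                        I = I, B_left = B_left, B_right = B_right,
                        n_samples = 1L),
    n_dropped = 0L), class = "line_profile")
}
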