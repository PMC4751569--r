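test_that("calibration pools background-corrected standard slices", {
  # 22-px bar of value 131; an even-width bar's true center is at a
  # half-integer column, so the selection sits at center + 0.5 and every
  # slice sums to exactly 22 * 131 = 2882
  px <- matrix(0, 40, 121)
  px[, (60 - 10):(60 + 11) + 1] <- 131
  img <- mpl_image(px)
  pr <- extract_profile(img, vsel(60.5, 5, 34, width = 22, kind = "standard",
                                  label = "TMV1"), gap = 2)
  expect_true(all(pr$slices$I == 2882))
  cal <- calibrate(list(pr), K = 131)
  expect_equal(cal$C_std, 2882)
  expect_equal(cal$sd_std, 0)
  expect_identical(cal$n_std_lines, 1L)
  expect_identical(cal$n_std_slices, 30L)

  # two standards with equal slice counts average to (a + b)/2
  p1 <- fake_profile(0:9, I = rep(2000, 10), kind = "standard")
  p2 <- fake_profile(0:9, I = rep(3000, 10), kind = "standard")
  expect_equal(calibrate(list(p1, p2))$C_std, 2500)
  # pooling weights by slice count; per-standard mean weights molecules equally
  p3 <- fake_profile(0:29, I = rep(3000, 30), kind = "standard")
  expect_equal(calibrate(list(p1, p3))$C_std, (10 * 2000 + 30 * 3000) / 40)
  expect_equal(calibrate(list(p1, p3), per_standard_mean = TRUE)$C_std, 2500)

  # a standard no brighter than its background cannot calibrate
  pz <- fake_profile(0:9, I = rep(50, 10), B_left = 50, B_right = 50)
  expect_error(calibrate(list(pz)), "darker than background")
  expect_error(calibrate(list()), "no standard selections")
  expect_error(calibrate(list(p1), K = -1))
})

test_that("per-slice MPL is the calibrated background-corrected ratio", {
  cal <- fake_cal(C_std = 2882, K = 131)
  sl <- data.frame(I = c(2882, 0, 2 * 2882, 1441 + 100),
                   B_left = c(0, 0, 0, 150), B_right = c(0, 0, 0, 50))
  expect_equal(mpl_per_slice(sl, cal), c(131, 0, 262, 1441 / 2882 * 131))
  # negative corrected intensities pass through un-clipped
  expect_lt(mpl_per_slice(data.frame(I = 0, B_left = 10, B_right = 10), cal), 0)
})

test_that("fibril measurement and summary statistics follow their definitions", {
  cal <- fake_cal(C_std = 1, K = 1)   # slice MPL = corrected intensity
  m <- measure_fibril(fake_profile(0:2, I = c(100, 102, 98)), cal)
  expect_equal(m$mean_mpl, 100)
  expect_equal(m$sd_mpl, 2)
  expect_equal(m$sem_mpl, 2 / sqrt(3))
  expect_identical(m$n_slices, 3L)

  # permutation invariance of the mean
  m2 <- measure_fibril(fake_profile(0:2, I = c(98, 100, 102)), cal)
  expect_equal(m2$mean_mpl, m$mean_mpl)

  # single-slice: sd and sem reported as 0, n = 1 flags it
  m1 <- measure_fibril(fake_profile(0L, I = 7), cal)
  expect_identical(m1$n_slices, 1L)
  expect_identical(m1$sd_mpl, 0)

  # pooled vs fibril-level means: (1 x 100, 3 x 200) -> 175 vs 150
  ms <- list(measure_fibril(fake_profile(0L, I = 100), cal),
             measure_fibril(fake_profile(0:2, I = rep(200, 3)), cal))
  s <- summarize_mpl(ms)
  expect_equal(s$pooled_mean, 175)
  expect_equal(s$fibril_mean, 150)
  expect_identical(s$n_fibrils, 2L)
  expect_identical(s$n_measurements, 4L)
  expect_identical(sum(s$per_fibril$n_slices), s$n_measurements)
  expect_error(summarize_mpl(list()), "no fibril measurements")

  # all slices identical
  s1 <- summarize_mpl(list(measure_fibril(fake_profile(0:4, I = rep(50, 5)), cal)))
  expect_equal(s1$pooled_mean, 50)
  expect_equal(s1$pooled_sd, 0)
  expect_equal(s1$fibril_mean, 50)
})

test_that("fluctuation pairs only consecutive retained slices", {
  # constant background: both difference SDs are zero
  p <- fake_profile(0:9, I = rep(100, 10), B_left = rep(20, 10), B_right = rep(20, 10))
  f <- fluctuation_analysis(list(p))
  expect_equal(f$sd_bg_diff, 0)
  expect_equal(f$sd_fibril_diff, 0)
  expect_identical(f$n_pairs_bg, 9L)

  # a dropped slice breaks the chain: {3,4,6} yields exactly one pair
  pg <- fake_profile(c(3L, 4L, 6L), I = c(1, 2, 3),
                     B_left = c(4, 8, 1), B_right = c(4, 8, 1))
  # need >= 2 pairs overall, so add a second profile
  f2 <- fluctuation_analysis(list(pg, p))
  expect_identical(f2$n_pairs_bg, 1L + 9L)

  expect_error(fluctuation_analysis(list(fake_profile(c(0L, 2L, 4L), I = 1:3))),
               "at least 2 consecutive-slice pairs")
  expect_error(fluctuation_analysis(list()), "no profiles")

  # pairing never crosses selections: two 1-slice profiles give no pairs
  expect_error(fluctuation_analysis(list(fake_profile(0L, I = 1),
                                         fake_profile(0L, I = 2))))
})

test_that("per-slice MPL is invariant to intensity scaling and offset", {
  sp <- phantom_spec(noise_sd = 25, seed = 8)
  ph <- generate_phantom(sp)
  run <- function(img) {
    profs <- extract_profiles(img, ph$selections, gap = 2)
    cal <- calibrate(profiles_of_kind(profs, "standard"))
    lapply(profiles_of_kind(profs, "fibril"),
           function(p) mpl_per_slice(p$slices, cal))
  }
  base <- run(ph$image)
  scaled <- run(mpl_image(ph$image$pixels * 3.7))
  shifted <- run(mpl_image(ph$image$pixels + 55))
  both <- run(mpl_image(ph$image$pixels * 0.21 + 400))
  for (lab in names(base)) {
    expect_equal(scaled[[lab]], base[[lab]], tolerance = 1e-12)
    expect_equal(shifted[[lab]], base[[lab]], tolerance = 1e-12)
    expect_equal(both[[lab]], base[[lab]], tolerance = 1e-12)
  }
})

test_that("integer magnification of image plus selections preserves mean MPL", {
  sp <- phantom_spec(noise_sd = 25, seed = 13)
  ph <- generate_phantom(sp)
  measure_mean <- function(img, sel) {
    profs <- extract_profiles(img, sel, gap = 2)
    cal <- calibrate(profiles_of_kind(profs, "standard"))
    summarize_mpl(lapply(profiles_of_kind(profs, "fibril"),
                         measure_fibril, cal))$pooled_mean
  }
  base <- measure_mean(ph$image, ph$selections)

  up <- mpl_image(ph$image$pixels[rep(seq_len(512), each = 2),
                                  rep(seq_len(512), each = 2)])
  lines2 <- ph$selections$lines
  for (cn in c("x0", "y0", "x1", "y1")) lines2[[cn]] <- 2 * lines2[[cn]] + 0.5
  lines2$width <- 2 * lines2$width
  up_mean <- measure_mean(up, selection_set(lines2))
  expect_lt(abs(up_mean - base) / base, 0.01)
})

test_that("merging segments preserves slices and groups by fibril id", {
  a <- fake_profile(0:4, I = 1:5, label = "F1:a")
  b <- fake_profile(0:2, I = 6:8, label = "F1:b")
  m <- merge_profiles(list(a, b), "F1")
  expect_identical(nrow(m$slices), 8L)
  expect_identical(m$slices$I, c(1:5, 6:8))
  expect_identical(m$slices$slice_index, 0:7)
  expect_identical(fibril_id(c("F1:a", "F1:b", "G")), c("F1", "F1", "G"))
})
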