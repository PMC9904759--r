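# Welch PSD, notch-band interpolation, band powers, power ratio

test_that("Welch grid spacing is 1/window_s and zero signals give zero PSD", {
  pr <- welch_psd(numeric(5000), fs = 250, window_s = 2)
  expect_equal(pr$freqs[2] - pr$freqs[1], 0.5)
  expect_true(all(pr$psd == 0))
  pr4 <- welch_psd(rnorm(5000), fs = 250, window_s = 4)
  expect_equal(pr4$freqs[2] - pr4$freqs[1], 0.25)
})

test_that("PSD integral honors Parseval for a sinusoid (2%) and white noise (5%)", {
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  pr <- welch_psd(x, fs)
  f <- pr$freqs
  sel <- f >= 1 & f <= 100
  p <- sum(diff(f[sel]) * (pr$psd[sel][-1] + pr$psd[sel][-sum(sel)]) / 2)
  expect_lt(abs(p - 0.5) / 0.5, 0.02)

  set.seed(6)
  w <- rnorm(length(t), sd = 3)
  pw <- welch_psd(w, fs)
  tot <- sum(diff(pw$freqs) * (pw$psd[-1] + pw$psd[-length(pw$psd)]) / 2)
  expect_lt(abs(tot - var(w)) / var(w), 0.05)
})

test_that("Welch segments never straddle masked samples", {
  fs <- 250
  x <- rnorm(20 * fs)
  x[2000:2100] <- 1e5                       # gross contamination
  mask <- rep(FALSE, length(x)); mask[2000:2100] <- TRUE
  pr <- welch_psd(x, fs, mask = mask)
  clean <- x[-(2000:2100)]
  expect_lt(max(pr$psd), 1e4)               # contamination leaked nowhere
  expect_error(welch_psd(x, fs, mask = rep(TRUE, length(x))), "artifact-free")
})

test_that("notch-band interpolation flattens a 60 Hz spike and touches nothing else", {
  f <- seq(0, 125, by = 0.5)
  p <- rep(2, length(f))
  p[f == 60] <- 50
  pr <- psd_result(f, p, 1)
  out <- interpolate_notch_band(pr)
  in_band <- f >= 58 & f <= 62
  expect_equal(out$psd[in_band], rep(2, sum(in_band)), tolerance = 1e-9)
  expect_identical(out$psd[!in_band], p[!in_band])   # bit-for-bit outside
  expect_equal(out$interpolated_range, c(58, 62))

  # an exact straight line is a fixed point of the replacement
  lin <- 1 + 0.03 * f
  out2 <- interpolate_notch_band(psd_result(f, lin, 1))
  expect_equal(out2$psd, lin, tolerance = 1e-12)

  # flank-means variant agrees on flat background
  out3 <- interpolate_notch_band(pr, method = "flank_means")
  expect_equal(out3$psd[in_band], rep(2, sum(in_band)), tolerance = 1e-9)

  short <- psd_result(seq(55, 65, 0.5), rep(1, 21), 1)
  expect_error(interpolate_notch_band(short), "flanking")
})

test_that("band powers on a flat PSD match analytic integrals and sum exactly to the total", {
  f <- seq(0, 125, by = 0.5)
  c0 <- 3.2
  bt <- band_powers(psd_result(f, rep(c0, length(f)), 1))
  expect_equal(bt$absolute_power[bt$name == "delta"], 3 * c0)
  expect_equal(bt$absolute_power[bt$name == "high_gamma"], 50 * c0)
  expect_equal(bt$relative_power[bt$name == "high_gamma"], 50 / 99)
  expect_equal(sum(bt$absolute_power), attr(bt, "total_power_1_100"))
  expect_equal(sum(bt$relative_power), 1, tolerance = 1e-9)
  expect_equal(power_ratio(bt), 0.34)
})

test_that("a pure 2 Hz tone concentrates >= 95% of relative power in delta", {
  fs <- 500
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  pr <- welch_psd(sin(2 * pi * 2 * t), fs)
  bt <- band_powers(pr)
  expect_gte(bt$relative_power[bt$name == "delta"], 0.95)
})

test_that("the power ratio is identical from absolute and relative PSD and scale-invariant", {
  set.seed(7)
  pr <- welch_psd(rnorm(60 * 250, sd = 40), 250)
  bt_abs <- band_powers(pr)
  bt_rel <- band_powers(relative_psd(pr))
  expect_equal(power_ratio(bt_rel), power_ratio(bt_abs), tolerance = 1e-14)
  pr7 <- pr; pr7$psd <- pr$psd * 7
  expect_equal(power_ratio(band_powers(pr7)), power_ratio(bt_abs),
               tolerance = 1e-14)
  # relative PSD integrates to 1 over 1-100 Hz and is scale invariant
  rp <- relative_psd(pr)
  f <- rp$freqs; sel <- f >= 1 & f <= 100
  integral <- sum(diff(f[sel]) * (rp$psd[sel][-1] + rp$psd[sel][-sum(sel)]) / 2)
  expect_equal(integral, 1, tolerance = 1e-9)
  expect_equal(relative_psd(pr7)$psd, rp$psd)
})

test_that("degenerate spectra raise errors instead of NaN tables", {
  f <- seq(0, 125, by = 0.5)
  expect_error(band_powers(psd_result(f, rep(0, length(f)), 1)), "zero total")
  expect_error(relative_psd(psd_result(f, rep(0, length(f)), 1)), "zero total")
  p <- rep(0, length(f)); p[f >= 1 & f <= 4] <- 1
  expect_error(power_ratio(band_powers(psd_result(f, p, 1))), "high-gamma")
  expect_error(band_powers(psd_result(seq(0, 50, 0.5), rep(1, 101), 1)),
               "cover 1-100")
})

test_that("all power in 50-100 Hz drives the ratio to ~0", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  pr <- welch_psd(sin(2 * pi * 75 * t), fs)
  bt <- band_powers(pr)
  expect_lt(power_ratio(bt), 0.01)
})
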