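test_that("baseline deduction recovers a pure smooth continuum to < 1% of peak", {
  w <- seq(200, 900, by = 0.25)
  cp <- list(peak_wavelength = 360, peak_amplitude = 200, width = 130, offset = 20)
  sp <- list(wavelength = w, intensity = continuum_intensity(w, cp))
  ded <- deduct_baseline(sp)
  expect_lt(max(abs(ded$intensity)), 0.01 * 200)
  expect_equal(attr(ded, "reference"), 200, tolerance = 0.01)
  # input untouched (functional contract)
  expect_equal(sp$intensity, continuum_intensity(w, cp))
})

test_that("a flat constant continuum is removed exactly", {
  w <- seq(500, 700, by = 0.25)
  sp <- list(wavelength = w, intensity = rep(42, length(w)))
  ded <- deduct_baseline(sp)
  expect_equal(ded$intensity, rep(0, length(w)))
})

test_that("baseline deduction preserves an injected line to within 2%", {
  w <- seq(200, 900, by = 0.25)
  cp <- list(peak_wavelength = 360, peak_amplitude = 200, width = 130, offset = 20)
  sp <- generate_spectrum(w, data.frame(center = 765, amplitude = 37, fwhm = 0.7),
                          continuum_params = cp, noise_sd = 0)
  ded <- deduct_baseline(sp)
  peak <- max(ded$intensity[abs(w - 765) < 1])
  expect_equal(peak, 37, tolerance = 0.02)
})

test_that("all-zero spectra warn on deduction and are rejected at normalization", {
  w <- seq(500, 700, by = 0.25)
  sp <- list(wavelength = w, intensity = rep(0, length(w)))
  expect_warning(ded <- deduct_baseline(sp), "all-zero")
  expect_equal(ded$intensity, sp$intensity)
  expect_error(normalize_to_baseline_peak(ded), "unquantifiable")
  prof <- suppressWarnings(process_spectrum(sp))
  expect_identical(prof$qc_flag, "zero_reference")
})

test_that("normalization divides by the reference and is scale invariant", {
  sp <- flat_spectrum(data.frame(center = 600, amplitude = 400, fwhm = 0.7),
                      continuum = 0, wavelength = seq(500, 700, 0.25))
  norm <- normalize_to_baseline_peak(sp, reference = 200)
  expect_equal(max(norm$intensity), 2.0, tolerance = 1e-9)

  w <- seq(200, 900, by = 0.25)
  cp <- list(peak_wavelength = 360, peak_amplitude = 150, width = 130, offset = 20)
  set.seed(1)
  raw <- generate_spectrum(w, data.frame(center = c(765, 547),
                                         amplitude = c(50, 90), fwhm = 0.7),
                           continuum_params = cp, noise_sd = 1)
  p1 <- process_spectrum(raw)
  p2 <- process_spectrum(list(wavelength = w, intensity = raw$intensity * 3.7))
  expect_equal(p2$k_emission, p1$k_emission, tolerance = 1e-12)
  expect_equal(p2$soluble_ca, p1$soluble_ca, tolerance = 1e-12)
  expect_equal(p2$ca_k_ratio, p1$ca_k_ratio, tolerance = 1e-12)
})

test_that("peak areas match the closed-form Gaussian integral over 4 orders of magnitude", {
  expect_equal(unclass(peak_area(flat_spectrum(), 765, 2)), 0,
               ignore_attr = TRUE)
  for (A in 10^seq(-2, 2)) {
    sp <- flat_spectrum(data.frame(center = 765, amplitude = A, fwhm = 0.7))
    a <- peak_area(sp, 765, 2)
    expect_equal(unclass(a), oracle_gauss_area(A, 0.7),
                 tolerance = 0.01, ignore_attr = TRUE)
  }
})

test_that("adjacent line windows are separated and out-of-grid windows error", {
  sp <- flat_spectrum(data.frame(center = 765, amplitude = 2, fwhm = 0.7))
  own <- unclass(peak_area(sp, 765, 2))
  other <- unclass(peak_area(sp, 770, 2))
  expect_lt(other, 0.01 * own)
  expect_error(peak_area(sp, 199, 2), "199")
  expect_error(processing_config(window_halfwidth = 3), "overlap")
})

test_that("peak areas are additive over a window partition with a fixed background", {
  set.seed(8)
  w <- seq(760, 770, by = 0.25)
  y <- 5 + 0.3 * (w - 760) + rnorm(length(w), 0, 0.2) +
    4 * exp(-0.5 * ((w - 765) / 0.3)^2)
  idx <- seq_along(w)
  bg <- y[1] + (y[length(y)] - y[1]) * (w - w[1]) / (w[length(w)] - w[1])
  r <- y - bg
  total <- sum(diff(w) * (r[-length(r)] + r[-1]) / 2)
  cut <- 21L
  left <- sum(diff(w[1:cut]) * (r[1:(cut - 1)] + r[2:cut]) / 2)
  right <- sum(diff(w[cut:length(w)]) * (r[cut:(length(w) - 1)] + r[(cut + 1):length(w)]) / 2)
  expect_equal(left + right, total, tolerance = 1e-12)
})

test_that("electrolyte profiles combine line areas as documented", {
  # only the two K lines: Ca = 0 and the ratio is 0
  spk <- flat_spectrum(data.frame(center = c(765, 770), amplitude = 2, fwhm = 0.7))
  pk <- electrolyte_profile(spk)
  expect_gt(pk$k_emission, 0)
  expect_equal(pk$soluble_ca, 0, tolerance = 1e-10)
  expect_equal(pk$ca_k_ratio, 0, tolerance = 1e-8)
  # equal-amplitude lines at all five centers: Ca : K = 3 : 2
  sp5 <- flat_spectrum(data.frame(center = c(765, 770, 547, 596, 610),
                                  amplitude = 2, fwhm = 0.7))
  p5 <- electrolyte_profile(sp5)
  expect_equal(p5$ca_k_ratio, 1.5, tolerance = 1e-6)
  # zero K flags the ratio as undefined
  spc <- flat_spectrum(data.frame(center = 547, amplitude = 2, fwhm = 0.7))
  pc <- electrolyte_profile(spc)
  expect_identical(pc$qc_flag, "undefined_ratio")
  expect_true(is.na(pc$ca_k_ratio))
})

test_that("per-position aggregation is the component-wise median", {
  prof <- data.frame(spot_id = 1L, shot_index = 1:3,
                     k_emission = c(1, 2, 100), soluble_ca = c(4, 6, 5),
                     ca_k_ratio = c(4, 3, 0.05), qc_flag = "", n_clipped = 0L)
  agg <- aggregate_position(prof)
  expect_equal(agg$k_emission, 2)
  expect_equal(agg$soluble_ca, 5)
  expect_equal(agg$ca_k_ratio, 5 / 2)
  expect_equal(aggregate_position(prof[1, ])$k_emission, 1)
  expect_error(aggregate_position(prof[0, ]), "empty")
  expect_error(aggregate_position(transform(prof, spot_id = 1:3)), "share")
})

test_that("median aggregation over 30 shots beats small-subset means", {
  set.seed(42)
  # compact grid keeps the Monte-Carlo loop fast; heavy shot noise makes the
  # sampling error dominate any residual baseline bias
  w <- seq(450, 850, by = 0.5)
  cp <- list(peak_wavelength = 550, peak_amplitude = 200, width = 130, offset = 40)
  lines <- function(a) data.frame(center = c(765, 770), amplitude = a, fwhm = 0.7)
  unit <- process_spectrum(generate_spectrum(w, lines(1), cp, noise_sd = 0))
  true_k <- 2.0
  amp <- true_k / unit$k_emission
  n_spots <- 100L
  wins <- 0L
  for (i in seq_len(n_spots)) {
    ks <- vapply(1:30, function(j) {
      # occasional aberrant shots (heterogeneous ablation) inflate the line
      a <- if (runif(1) < 0.15) 3 * amp else amp
      sp <- generate_spectrum(w, lines(a), cp, noise_sd = 2)
      process_spectrum(sp)$k_emission
    }, numeric(1))
    med_err <- abs(median(ks) - true_k)
    sub_err <- abs(mean(ks[1:5]) - true_k)
    wins <- wins + (med_err <= sub_err)
  }
  expect_gte(wins / n_spots, 0.6)
})
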