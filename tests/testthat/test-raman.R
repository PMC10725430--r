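# Baseline subtraction and redox ratio metrics.

test_that("baseline subtraction reproduces lines and absorbs constants", {
  sh <- 600:1800
  sp <- raman_spectrum(sh, 0.01 * sh + 3)
  cor <- subtract_baseline(sp)
  expect_lt(max(abs(cor$intensities)), 1e-9 * max(abs(sp$intensities)))

  set.seed(1)
  sp1 <- raman_spectrum(sh, rnorm(length(sh)) + 5)
  sp2 <- raman_spectrum(sh, sp1$intensities + 42)
  expect_equal(subtract_baseline(sp1)$intensities,
               subtract_baseline(sp2)$intensities, tolerance = 1e-12)
})

test_that("spline baseline matches the tridiagonal natural-spline oracle", {
  set.seed(7)
  sh <- 600:1800
  for (rep in 1:5) {
    nk <- sample(5:12, 1)
    repeat {
      kx <- sort(round(runif(nk, 605, 1795)))
      if (all(diff(kx) >= 15)) break
    }
    sp <- raman_spectrum(sh, rnorm(length(sh), sd = 2) + 0.002 * sh)
    bl <- baseline_spec(kx, neighborhood_halfwidth = 2)
    cor <- subtract_baseline(sp, bl)
    heights <- gliaquant:::knot_heights(sh, sp$intensities, kx, 2)
    fitted <- sp$intensities - cor$intensities
    orc <- natural_spline_eval(kx, heights, sh)
    expect_lt(max(abs(fitted - orc)) / max(abs(orc)), 1e-9)
  }
})

test_that("cubic background with an off-knot peak is recovered", {
  u <- (600:1800 - 1200) / 600
  base <- 5 + 2 * u - 3 * u^2 + 1.5 * u^3
  A <- 2
  peak <- A * exp(-(600:1800 - 750)^2 / (2 * 6^2))
  sp <- raman_spectrum(600:1800, base + peak)
  cor <- subtract_baseline(sp)
  expect_equal(peak_intensity(cor, 750), A, tolerance = 0.02)
  # fmm end conditions are exact for a cubic background (point-sampled knot
  # heights: a neighborhood average of a cubic is biased by its curvature)
  spb <- raman_spectrum(600:1800, base)
  bl0 <- baseline_spec(default_baseline()$knot_positions,
                       neighborhood_halfwidth = 0)
  corb <- subtract_baseline(spb, bl0, method = "fmm")
  expect_lt(max(abs(corb$intensities)), 1e-9 * max(abs(base)))
})

test_that("baseline input validation", {
  expect_error(baseline_spec(c(700, 900, 1200)), "at least 4")
  sp <- raman_spectrum(600:1800, rep(1, 1201))
  expect_error(subtract_baseline(sp, baseline_spec(c(100, 700, 900, 1200))),
               "outside the spectral range")
})

test_that("peak intensity is the window maximum", {
  sh <- 600:1800
  A <- 3.2
  g <- function(c0, a, w) a * exp(-(sh - c0)^2 / (2 * w^2))
  sp <- raman_spectrum(sh, g(1440, A, 7))
  expect_equal(peak_intensity(sp, 1440), A, tolerance = 1e-6)
  # maximum at 752 is found from a query at 750
  sp2 <- raman_spectrum(sh, g(752, A, 4))
  expect_equal(peak_intensity(sp2, 750, window = 5), sp2$intensities[sh == 752])
  # overlapping peaks: equals a linear scan over the window
  sp3 <- raman_spectrum(sh, g(740, 2, 5) + g(755, 1.5, 5))
  sel <- sh >= 745 & sh <= 755
  expect_equal(peak_intensity(sp3, 750, 5), max(sp3$intensities[sel]))
  expect_error(peak_intensity(sp, 1790, window = 5), NA)
  expect_error(peak_intensity(sp, 5000, window = 5), "no grid points")
})

test_that("band sums use the closed native-grid interval", {
  sp <- raman_spectrum(600:1800, rep(1, 1201))
  expect_equal(band_intensity_sum(sp, 1550, 1580), 31)
  sp0 <- raman_spectrum(600:1800, rep(0, 1201))
  expect_equal(band_intensity_sum(sp0, 1550, 1580), 0)
  set.seed(3)
  spr <- raman_spectrum(600:1800, rnorm(1201))
  manual <- 0
  for (i in seq_along(spr$shifts))
    if (spr$shifts[i] >= 700 && spr$shifts[i] <= 900)
      manual <- manual + spr$intensities[i]
  expect_equal(band_intensity_sum(spr, 700, 900), manual)
  expect_error(band_intensity_sum(sp, 900, 700), "lo must be < hi")
})

test_that("532 nm metrics recover generating amplitude ratios", {
  sh <- 600:1800
  g <- function(c0, a) a * exp(-(sh - c0)^2 / (2 * 8^2))
  equal <- raman_spectrum(sh, g(750, 1) + g(1126, 1) + g(1440, 1) + g(1660, 1))
  m <- metrics_532(equal)
  expect_equal(m$protein_to_lipid, 1, tolerance = 1e-4)
  expect_equal(m$red_cyt_cb_per_protein, 1, tolerance = 1e-4)
  expect_equal(m$c_to_b, 1, tolerance = 1e-4)

  sp <- gen_raman(data.frame(center = c(750, 1126, 1440, 1660),
                             amplitude = c(2, 1, 4, 2),
                             width = c(8, 8, 10, 9)),
                  baseline_coeffs = c(10, -3, 2, 1.5), noise_sd = 0, seed = 1)
  m <- metrics_532(sp)
  expect_equal(m$protein_to_lipid, 0.5, tolerance = 0.02)
  expect_equal(m$red_cyt_cb_per_protein, 1.0, tolerance = 0.02)
  expect_equal(m$c_to_b, 2.0, tolerance = 0.02)

  # missing cytochrome-b peak is an error naming the peak
  sp2 <- gen_raman(data.frame(center = c(750, 1440, 1660),
                              amplitude = c(2, 4, 2), width = c(8, 10, 9)),
                   noise_sd = 0, seed = 1)
  expect_error(suppressWarnings(metrics_532(sp2)), "1126")
  expect_error(metrics_532(raman_spectrum(sh, rep(1, 1201), laser_nm = 633)),
               "532")
})

test_that("633 nm metric uses band sums and flags a zero denominator", {
  sh <- 600:1800
  # off-band knots see zeros, so the fitted baseline is identically zero and
  # the corrected intensity is constant over both bands: the ratio is the
  # point-count ratio 31/11
  band <- ifelse(sh >= 1500 & sh <= 1720, 2, 0)
  spb <- raman_spectrum(sh, band, laser_nm = 633)
  knots <- baseline_spec(c(620, 800, 1000, 1200, 1350, 1460, 1780))
  m <- metrics_633(spb, knots)
  expect_equal(m$red_cyt_a_ratio, 31 / 11, tolerance = 1e-9)

  spg <- gen_raman(data.frame(center = c(1565, 1660),
                              amplitude = c(3, 2), width = c(14, 4)),
                   baseline_coeffs = c(2, 1), noise_sd = 0, seed = 2,
                   laser_nm = 633)
  m2 <- metrics_633(spg)
  # oracle: band sums of the generating Gaussians on the same grid
  g <- function(c0, a, w) a * exp(-(sh - c0)^2 / (2 * w^2))
  truth <- sum((g(1565, 3, 14) + g(1660, 2, 4))[sh >= 1550 & sh <= 1580]) /
    sum((g(1565, 3, 14) + g(1660, 2, 4))[sh >= 1655 & sh <= 1665])
  expect_equal(m2$red_cyt_a_ratio, truth, tolerance = 0.02)

  spz <- gen_raman(data.frame(center = 1565, amplitude = 3, width = 10),
                   noise_sd = 0, seed = 3, laser_nm = 633)
  expect_error(metrics_633(spz), "1655-1665")
})

test_that("ratio metrics are invariant to positive rescaling", {
  sp <- gen_raman(data.frame(center = c(750, 1126, 1440, 1660),
                             amplitude = c(1.5, 1, 4, 3),
                             width = c(8, 8, 10, 9)),
                  baseline_coeffs = c(5, -2, 1), noise_sd = 0.05, seed = 4)
  m1 <- metrics_532(sp)
  sp2 <- sp
  sp2$intensities <- 3.7 * sp$intensities
  m2 <- metrics_532(sp2)
  expect_equal(m1$protein_to_lipid, m2$protein_to_lipid, tolerance = 1e-10)
  expect_equal(m1$c_to_b, m2$c_to_b, tolerance = 1e-10)
})

test_that("a 30% lower cytochrome peak is recovered as a lower group median", {
  n_ok <- 0
  for (s in 1:50) {
    med <- function(fac, off) {
      vals <- vapply(1:6, function(i) {
        set.seed(derive_seed(s, off + i))
        amps <- c(1.5 * fac, 1, 4, 3) * exp(rnorm(4, 0, 0.1))
        sp <- gen_raman(data.frame(center = c(750, 1126, 1440, 1660),
                                   amplitude = amps, width = c(8, 8, 10, 9)),
                        baseline_coeffs = c(5, 1), noise_sd = 0.05,
                        seed = derive_seed(s, off + 100 + i))
        metrics_532(sp)$red_cyt_cb_per_protein
      }, numeric(1))
      median(vals)
    }
    if (med(0.7, 200) < med(1, 0)) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 50)
})

test_that("spectrum file I/O and batch manifest work", {
  dir <- withr::local_tempdir()
  sp <- gen_raman(data.frame(center = c(750, 1126, 1440, 1660),
                             amplitude = c(2, 1, 4, 2), width = c(8, 8, 10, 9)),
                  noise_sd = 0, seed = 1)
  f <- file.path(dir, "cell1.csv")
  write.csv(data.frame(shift = sp$shifts, intensity = sp$intensities), f,
            row.names = FALSE)
  rd <- read_spectrum(f)
  expect_equal(rd$intensities, sp$intensities)
  man <- data.frame(file = "cell1.csv", cell_id = "c1",
                    cell_class = "astrocyte", laser_nm = 532, group = "younger")
  out <- raman_batch(man, dir = dir)
  expect_equal(nrow(out), 1)
  expect_equal(out$c_to_b, 2, tolerance = 0.02)
})
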