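omega <- function(f = 4e7) 2 * pi * f

test_that("reference calibration recovers instrument offsets and round-trips", {
  # zero-lifetime (scatterer) reference: measured values are the offsets
  cal0 <- flim_calibrate(0.1, 0.9, reference_lifetime = 0)
  expect_equal(cal0$phase_offset, 0.1)
  expect_equal(cal0$modulation_scale, 0.9)

  # fluorescein at 4.0 ns, 40 MHz: omega*tau ~ 1.0053, atan ~ 0.7880 rad
  cal <- flim_calibrate(1.0, 0.5, reference_lifetime = 4e-9)
  wt <- omega() * 4e-9
  expect_equal(wt, 1.00531, tolerance = 1e-5)
  expect_equal(1.0 - cal$phase_offset, atan(wt))
  expect_equal(atan(wt), 0.7880, tolerance = 1e-4)

  # applying the calibration to the reference itself recovers tau_ref
  ref_frame <- lifetime_frame(matrix(1.0, 2, 2), matrix(0.5, 2, 2))
  lt <- lifetimes_from_phase_mod(ref_frame, cal)
  expect_equal(lt$tau_phase[1, 1], 4, tolerance = 1e-12)
  expect_equal(lt$tau_mod[1, 1], 4, tolerance = 1e-12)

  expect_error(flim_calibrate(1, 0), "positive")
  expect_error(flim_calibrate(1, 0.5, reference_lifetime = -1))
})

test_that("mono-exponential frames invert exactly and flag impossible pixels", {
  ident <- flim_calibrate(0, 1, reference_lifetime = 0)

  # zero lifetime: phase 0, modulation 1, both lifetimes 0 (valid pixel)
  fr0 <- simulate_flim_frame(matrix(0, 2, 2))
  lt0 <- lifetimes_from_phase_mod(fr0, ident)
  expect_equal(lt0$tau_phase[1, 1], 0)
  expect_equal(lt0$tau_mod[1, 1], 0)
  expect_equal(lt0$n_invalid, 0L)

  # noiseless round trip across the working lifetime range
  for (tau in c(0.5, 1, 2.5, 4, 6)) {
    fr <- simulate_flim_frame(matrix(tau, 3, 3))
    lt <- lifetimes_from_phase_mod(fr, ident)
    expect_equal(lt$tau_phase[2, 2], tau, tolerance = 1e-12)
    expect_equal(lt$tau_mod[2, 2], tau, tolerance = 1e-12)
  }

  # physically impossible pixels (m > 1, negative phase) are excluded
  fr <- simulate_flim_frame(matrix(2.5, 2, 2))
  fr$modulation[1, 1] <- 1.2
  fr$phase[2, 1] <- -0.05
  lt <- lifetimes_from_phase_mod(fr, ident)
  expect_equal(lt$n_invalid, 2L)
  expect_true(is.na(lt$tau_phase[1, 1]))
  expect_equal(cell_mean_lifetime(fr, ident), 2.5, tolerance = 1e-12)
})

test_that("lifetime heterogeneity orders the two estimators", {
  # phasor of an equal-amplitude 1 ns + 4 ns mixture (closed form)
  w <- omega()
  taus <- c(1e-9, 4e-9)
  g <- mean(1 / (1 + (w * taus)^2))
  s <- mean(w * taus / (1 + (w * taus)^2))
  fr <- lifetime_frame(matrix(atan2(s, g), 1, 1),
                       matrix(sqrt(g^2 + s^2), 1, 1))
  lt <- lifetimes_from_phase_mod(fr, flim_calibrate(0, 1, reference_lifetime = 0))
  expect_lt(lt$tau_phase[1, 1], lt$tau_mod[1, 1])
  expect_gt(lt$tau_phase[1, 1], 1)
  expect_lt(lt$tau_mod[1, 1], 4)

  # estimator switch matters on the mixture, not on a mono-exponential field
  ident <- flim_calibrate(0, 1, reference_lifetime = 0)
  mono <- simulate_flim_frame(matrix(2.4, 2, 2))
  expect_equal(cell_mean_lifetime(mono, ident, "phase"),
               cell_mean_lifetime(mono, ident, "modulation"),
               tolerance = 1e-12)
  mix <- fr
  expect_false(isTRUE(all.equal(cell_mean_lifetime(mix, ident, "phase"),
                                cell_mean_lifetime(mix, ident, "modulation"))))
})

test_that("FRET efficiency follows the donor-lifetime formula", {
  expect_equal(fret_efficiency(2.4, 2.4)$e_app, 0)
  expect_equal(fret_efficiency(1.2, 2.4)$e_app, 50)
  expect_equal(fret_efficiency(1.92, 2.4)$e_app, 20)

  fm <- fret_efficiency(c(1.92, 2.04, 1.80), 2.4)
  expect_equal(fm$mean_e_app, mean(c(20, 15, 25)))
  expect_equal(fm$n_cells, 3L)

  # monotone decreasing in tau_DA
  taus <- seq(0.5, 2.4, by = 0.1)
  expect_true(all(diff(fret_efficiency(taus, 2.4)$e_app) < 0))
  expect_error(fret_efficiency(1.9, 0), "positive")
})

test_that("FLIM frames survive CSV and TIFF round trips", {
  fr <- simulate_flim_frame(matrix(seq(0.5, 4, length.out = 12), 3, 4))
  pf <- tempfile(fileext = ".csv")
  mf <- tempfile(fileext = ".csv")
  write.table(fr$phase, pf, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(fr$modulation, mf, sep = ",", row.names = FALSE, col.names = FALSE)
  back <- read_lifetime_frame(pf, mf)
  expect_equal(back$phase, fr$phase, tolerance = 1e-12)
  expect_equal(back$modulation, fr$modulation, tolerance = 1e-12)

  skip_if_not_installed("tiff")
  pt <- tempfile(fileext = ".tif")
  mt <- tempfile(fileext = ".tif")
  tiff::writeTIFF(fr$phase / pi, pt, bits.per.sample = 32L)
  tiff::writeTIFF(fr$modulation, mt, bits.per.sample = 32L)
  back2 <- read_lifetime_frame(pt, mt)
  expect_equal(back2$phase * pi, fr$phase, tolerance = 1e-6)
})
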