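# Electron-density-profile reconstruction, d_pp, truncation correction,
# water layer.

test_that("Lorentz-corrected amplitudes from areas; gaps rejected, zeros kept", {
  amps <- fourier_amplitudes(c(100, 25, 100 / 9), d = 4.99)
  expect_equal(amps$table$F, rep(10, 3), tolerance = 1e-12)

  # zero intensity is a legitimate zero amplitude
  amps0 <- fourier_amplitudes(c(100, 0, 11), d = 4.99)
  expect_equal(amps0$table$F[2], 0)

  # missing intermediate order is rejected
  ser <- group_series(data.frame(q0 = d_to_q(4.99) * c(1, 3)))
  multi <- Filter(function(s) s$n_orders >= 2, ser)
  # peaks at h = 1 and 3 of one fundamental index as orders 1 and 3
  expect_length(multi, 1L)
  expect_error(amplitudes_from_peaks(multi[[1]]), "consecutive")
})

test_that("amplitudes recovered from a synthetic profile match the form factor", {
  gel <- gel_bilayer_model(4.99)
  prof <- make_gel_profile(seed = 42)
  a <- assess_point(prof)
  amps <- amplitudes_from_peaks(a$series[[1]])
  Ftrue <- abs(analytic_form_factor(gel, d_to_q(4.99) * (1:3)))
  sc <- sum(amps$table$F * Ftrue) / sum(amps$table$F^2)
  expect_equal(sc * amps$table$F, Ftrue, tolerance = 0.03)
})

test_that("reconstruction: one-term series, sign flips, linearity, symmetry", {
  amps <- fourier_amplitudes(c(100, 25, 11), d = 5)
  one <- fourier_amplitudes(c(50, 0), d = 5)

  # single surviving order with sign +1 behaves as cos(2 pi z / d)
  edp1 <- reconstruct_edp(one, signs = c(1, 1))
  expect_equal(edp1$rho, cos(2 * pi * edp1$z / 5), tolerance = 1e-12)

  # flipping every sign negates rho exactly
  s <- c(-1, -1, 1)
  e1 <- reconstruct_edp(amps, signs = s)
  e2 <- reconstruct_edp(amps, signs = -s)
  expect_identical(e1$rho, -e2$rho)

  # linearity before normalization
  amps4 <- fourier_amplitudes(4 * c(100, 25, 11), d = 5)
  r1 <- reconstruct_edp(amps, signs = s, normalize = FALSE)
  r2 <- reconstruct_edp(amps4, signs = s, normalize = FALSE)
  expect_equal(r2$rho, 2 * r1$rho, tolerance = 1e-12)

  # mirror symmetry to machine precision for every sign choice
  for (i in 1:8) {
    sg <- default_signs(3) * sample(c(-1, 1), 3, replace = TRUE)
    e <- reconstruct_edp(amps, signs = sg)
    expect_identical(e$rho, rev(e$rho))
  }

  expect_error(reconstruct_edp(amps, n_z = 8), "undersampled")
  expect_error(reconstruct_edp(amps, signs = c(1, 1)), "one sign per order")
})

test_that("default sign conventions for 2-5 orders", {
  expect_equal(default_signs(2), c(-1, -1))
  expect_equal(default_signs(3), c(-1, -1, 1))
  expect_equal(default_signs(4), c(-1, -1, 1, -1))
  expect_equal(default_signs(5), c(-1, -1, 1, -1, 1))
})

test_that("d_pp measurement: boundary flag and headgroup recovery at 5 orders", {
  # sign convention that pushes the maxima to the unit-cell edge is flagged
  one <- fourier_amplitudes(c(50, 0), d = 5)
  edge <- reconstruct_edp(one, signs = c(-1, -1))  # -cos: maxima at +-d/2
  expect_warning(measure_dpp(edge), "boundary")

  # >= 5 exact orders: headgroup maxima within 2% of +-z_head
  withr::with_seed(51, {
    for (i in 1:10) {
      ph <- random_gel_phantom()
      ex <- exact_amplitudes(ph$model, 5)
      edp <- reconstruct_edp(ex$amps, signs = ex$signs)
      raw <- measure_dpp(edp)
      expect_equal(as.numeric(raw), true_dpp(ph$model),
                   tolerance = 0.02)
    }
  })
})

test_that("3-order reconstruction underestimates d_pp relative to 5 orders", {
  withr::with_seed(52, {
    for (i in 1:15) {
      ph <- random_gel_phantom()
      e3 <- exact_amplitudes(ph$model, 3)
      e5 <- exact_amplitudes(ph$model, 5)
      raw3 <- measure_dpp(reconstruct_edp(e3$amps, signs = e3$signs))
      raw5 <- measure_dpp(reconstruct_edp(e5$amps, signs = e5$signs))
      expect_lt(raw3, raw5)
      expect_lt(raw3, true_dpp(ph$model))
    }
  })
})

test_that("truncation correction table and arithmetic", {
  expect_equal(round(as.numeric(truncation_correct(3.03, 3)), 2), 3.33)
  expect_equal(as.numeric(truncation_correct(2.00, 3)), 2.20)
  x <- truncation_correct(3.5, 4)
  expect_equal(as.numeric(x), 3.5)
  expect_equal(attr(x, "factor"), 1.00)
  # fluid two-order estimates receive no correction
  expect_equal(as.numeric(truncation_correct(3.96, 2)), 3.96)
  expect_error(truncation_correct(3.0, 1), "no truncation factor")
})

test_that("water layer arithmetic and guards", {
  expect_equal(water_layer(4.99, 3.33), 1.66)
  expect_equal(water_layer(5, 2.5), 2.5)
  expect_equal(water_layer(6.40, 4.57), 1.83)
  expect_error(water_layer(4.99, 5.1), "0 < d_pp < d")
  expect_error(water_layer(4.99, -1), "0 < d_pp < d")
})

test_that("sign scan enumerates 2^n reconstructions and ranks the convention well", {
  ph <- withr::with_seed(53, random_gel_phantom())
  ex <- exact_amplitudes(ph$model, 3)
  scan <- sign_scan(ex$amps)
  expect_equal(nrow(scan), 8L)
  expect_equal(anyDuplicated(scan$signs), 0L)
  # the physically sensible convention sits at the top of the ranking
  expect_equal(scan$signs[1], paste(ifelse(ex$signs > 0, "+", "-"),
                                    collapse = ""))
})

test_that("full series-to-EDP chain reports a consistent record", {
  prof <- make_gel_profile(seed = 46)
  a <- assess_point(prof)
  edp <- edp_from_series(a$series[[1]])
  expect_equal(edp$correction_factor, 1.10)
  expect_equal(edp$d_pp, 1.10 * edp$d_pp_raw)
  expect_equal(edp$d_w, edp$d - edp$d_pp)
  expect_gt(edp$d_pp, 0)
  expect_lt(edp$d_pp, edp$d)
})
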