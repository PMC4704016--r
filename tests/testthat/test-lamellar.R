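# Indexing, d-spacing, phase classification, point assessment,
# phase-diagram assembly.

peak_df <- function(q0, ...) {
  df <- data.frame(q0 = q0, ...)
  df[order(df$q0), , drop = FALSE]
}

test_that("three equally spaced orders index as one series with d = 4.99 nm", {
  ser <- group_series(peak_df(c(0.126, 0.252, 0.378)))
  expect_length(ser, 1L)
  expect_equal(ser[[1]]$orders$h, 1:3)
  expect_equal(round(dspacing(ser[[1]]), 2), 4.99)
})

test_that("two interleaved series are separated with correct memberships", {
  qg <- d_to_q(4.99) * (1:3)
  qf <- d_to_q(7.00) * (1:2)
  ser <- group_series(peak_df(c(qg, qf)))
  multi <- Filter(function(s) s$n_orders >= 2, ser)
  expect_length(multi, 2L)
  ds <- sort(vapply(multi, function(s) s$d, numeric(1)))
  expect_equal(ds, c(4.99, 7.00), tolerance = 1e-9)
})

test_that("a single peak becomes a one-order series with unknown phase", {
  ser <- group_series(peak_df(0.126))
  expect_length(ser, 1L)
  expect_equal(ser[[1]]$n_orders, 1L)
  expect_equal(classify_phase(ser[[1]])$phase, "unknown")
})

test_that("d-spacing values and exactness", {
  s126 <- group_series(peak_df(0.126))[[1]]
  expect_equal(round(dspacing(s126), 2), 4.99)
  # q1 = 2 pi nm^-1 = 0.6283 A^-1 -> 1 nm
  s1 <- group_series(peak_df(2 * pi / 10))[[1]]
  expect_equal(dspacing(s1), 1.0, tolerance = 1e-12)
  s897 <- group_series(peak_df(0.0897))[[1]]
  expect_equal(round(dspacing(s897), 2), 7.00)
  # exact multiples of 2 pi / d return d to 1e-9 relative
  withr::with_seed(41, {
    for (i in 1:20) {
      d <- runif(1, 3, 9)
      ser <- group_series(peak_df(d_to_q(d) * (1:3)))[[1]]
      expect_equal(dspacing(ser), d, tolerance = 1e-9)
    }
  })
})

test_that("indexing matches the exhaustive best-partition oracle on 200 random cases", {
  withr::with_seed(42, {
    for (case in 1:200) {
      cs <- random_index_case()
      got <- group_series(peak_df(cs$q0))
      got_blocks <- canonical_blocks(lapply(
        Filter(function(s) s$n_orders >= 2, got),
        function(s) match(s$orders$q0, cs$q0)))
      oracle_blocks <- oracle_group(cs$q0)
      expect_identical(got_blocks, oracle_blocks,
                       info = paste("case", case))
      expect_identical(got_blocks, cs$truth, info = paste("case", case))
    }
  })
})

test_that("phase classification follows the diffraction signatures", {
  gel3 <- group_series(peak_df(d_to_q(4.99) * (1:3),
                               fwhm = rep(0.0019, 3)))[[1]]
  waxs <- structure(data.frame(q0 = 1.57, height = 100, sigma = 0.01,
                               q0_se = 1e-4, area = 2, area_se = 0.1,
                               fwhm = 0.03, shape = "gaussian",
                               miller_label = NA),
                    class = c("peak_table", "data.frame"))
  expect_equal(classify_phase(gel3, waxs)$phase, "gel")
  expect_equal(classify_phase(gel3)$phase, "gel")   # 3 orders suffice

  fluid2 <- group_series(peak_df(d_to_q(7) * (1:2),
                                 fwhm = rep(0.009, 2)))[[1]]
  expect_equal(classify_phase(fluid2)$phase, "fluid")
  # broad 2-order series is fluid even when a chain peak exists elsewhere
  expect_equal(classify_phase(fluid2, waxs)$phase, "fluid")
  # 2 sharp orders + chain peak -> gel
  gel2 <- group_series(peak_df(d_to_q(4.99) * (1:2),
                               fwhm = rep(0.0019, 2)))[[1]]
  expect_equal(classify_phase(gel2, waxs)$phase, "gel")
  expect_equal(classify_phase(gel2)$phase, "unknown")
})

test_that("classification is invariant to overall intensity scaling", {
  for (scale in c(0.25, 1, 40)) {
    inst <- instrument_config("SAXS", seed = 91,
                              exposure_scale = 250 * scale,
                              background = c(50, -40) * scale)
    p <- synthesize_profile(
      list(list(edp = gel_bilayer_model(4.99), stack = gel_stack(4.99))),
      instrument = inst, meta = sample_meta(0.1, 20))
    a <- assess_point(p)
    expect_equal(a$state, "gel", info = paste("scale", scale))
  }
})

test_that("assess_point recovers coexistence, fluid-only and gel-only states", {
  inst <- instrument_config("SAXS", seed = 61)
  co <- synthesize_profile(list(
    list(edp = gel_bilayer_model(4.99), stack = gel_stack(4.99, phi = 0.5)),
    list(edp = fluid_bilayer_model(7.0), stack = fluid_stack(7.0, phi = 0.5))),
    instrument = inst, meta = sample_meta(0.1, 25))
  a <- assess_point(co)
  expect_equal(a$state, "coexistence")
  ds <- sort(vapply(Filter(function(s) s$n_orders >= 2, a$series),
                    function(s) s$d, numeric(1)))
  expect_equal(ds[1], 4.99, tolerance = 0.02 * 4.99)
  expect_equal(ds[2], 7.00, tolerance = 0.02 * 7.00)

  expect_equal(assess_point(make_fluid_profile(seed = 62))$state, "fluid")
  expect_equal(assess_point(make_gel_profile(d = 6.28, seed = 63))$state,
               "gel")
  # featureless profile: no label is forced
  flat <- synthesize_profile(
    list(), instrument = instrument_config("SAXS", seed = 64))
  expect_equal(assess_point(flat)$state, "unknown")
})

test_that("phase diagram assembly: T_m rule, boundary flags, contiguity", {
  mk_point <- function(comp, temp, state)
    structure(list(meta = sample_meta(comp, temp), state = state,
                   series = list(), waxs_gel_peak = NULL),
              class = "phase_point")
  pts <- list(mk_point(0.1, 20, "gel"), mk_point(0.1, 25, "coexistence"),
              mk_point(0.1, 29, "coexistence"), mk_point(0.1, 33, "fluid"),
              mk_point(0.1, 40, "fluid"))
  pd <- build_phase_diagram(pts)
  expect_equal(pd$tm$T_m, (29 + 33) / 2)   # midpoint rule
  expect_equal(pd$tm$note, "midpoint")
  expect_length(pd$flags, 0)

  # all-fluid column: T_m unbounded below
  pd2 <- build_phase_diagram(list(mk_point(1, 35, "fluid"),
                                  mk_point(1, 40, "fluid")))
  expect_equal(pd2$tm$T_m, 35)
  expect_equal(pd2$tm$note, "unbounded below")

  # all-gel column: T_m above the sampled range
  pd3 <- build_phase_diagram(list(mk_point(0, 16, "gel"),
                                  mk_point(0, 20, "gel")))
  expect_true(is.na(pd3$tm$T_m))
  expect_equal(pd3$tm$note, "above-range")

  # non-contiguous states are flagged, not hidden
  pd4 <- build_phase_diagram(list(mk_point(0.5, 20, "fluid"),
                                  mk_point(0.5, 25, "gel"),
                                  mk_point(0.5, 30, "fluid")))
  expect_match(pd4$flags, "not contiguous")
})
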