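# Forward simulator: form factors, structure factors, profile synthesis,
# powder rendering, phase grid.

test_that("analytic form factor matches quadrature, q = 0 limit, mirror symmetry", {
  # q = 0: cosine terms collapse to the summed Gaussian areas
  m <- gel_bilayer_model(4.99)
  cmp <- m$components
  expect_equal(analytic_form_factor(m, 0),
               sum(cmp$sign * cmp$A * sqrt(2 * pi) * cmp$sigma))

  # single +-2 nm pair, sigma 0.3, at q = pi/2 nm^-1; frozen quadrature value
  pair <- bilayer_edp_model(
    data.frame(z = c(2, -2), sigma = 0.3, A = 1, sign = 1), d = 6)
  expect_equal(analytic_form_factor(pair, pi / 2, q_unit = "invnm"),
               -1.34592278, tolerance = 1e-8)

  # 100 random symmetric models against numerical quadrature
  withr::with_seed(11, {
    for (i in 1:100) {
      m <- random_symmetric_model()
      q_nm <- runif(3, 0.3, 6)
      expect_equal(analytic_form_factor(m, q_nm, q_unit = "invnm"),
                   quadrature_form_factor(m$components, q_nm),
                   tolerance = 1e-6)
    }
  })

  # negating every z leaves F unchanged
  m <- random_symmetric_model()
  neg <- m
  neg$components$z <- -neg$components$z
  q <- seq(0.02, 0.45, length.out = 50)
  expect_identical(analytic_form_factor(m, q),
                   analytic_form_factor(neg, q))
})

test_that("asymmetric bilayer models are rejected with an explicit message", {
  expect_error(
    bilayer_edp_model(data.frame(z = c(1.5, 0), sigma = 0.3, A = 1,
                                 sign = 1), d = 5),
    "mirror-symmetric")
  expect_error(gel_bilayer_model(4.99, sigma_head = -0.1), "> 0")
})

test_that("structure factor: order positions, damping limit, per-peak oracle", {
  q <- seq(0.01, 0.45, length.out = 2000)
  s <- gel_stack(4.99)
  S <- structure_factor(s, q)
  # local maxima sit at 2 pi h / d: 0.1259, 0.2518, 0.3777 A^-1
  pk <- q[which(diff(sign(diff(S))) == -2) + 1]
  expect_equal(pk[1:3], c(0.1259, 0.2518, 0.3777), tolerance = 2e-3)

  # infinite damping kills every order
  dead <- lamellar_stack_model("gel", d = 4.99, eta = 60)
  expect_true(all(structure_factor(dead, q) < 1e-10))

  # beta = 0, eta = 0: equal-width unit peaks, direct construction
  flat <- lamellar_stack_model("fluid", d = 6, w1 = 0.002, beta = 0,
                               eta = 0)
  manual <- Reduce(`+`, lapply(1:6, function(h)
    exp(-(q - h * d_to_q(6))^2 / (2 * 0.002^2))))
  expect_equal(structure_factor(flat, q), manual, tolerance = 1e-12)
})

test_that("profile synthesis: background-only mean, determinism, gel order count", {
  inst <- instrument_config("SAXS", seed = 101, background = c(80))
  p <- synthesize_profile(list(), instrument = inst)
  expect_equal(mean(p$intensity), 80,
               tolerance = 3 * sqrt(80 / length(p$q)) / 80)

  # same seed twice: byte-identical
  p2 <- synthesize_profile(list(), instrument = inst)
  expect_identical(p$intensity, p2$intensity)
  g1 <- make_gel_profile(seed = 7)
  g2 <- make_gel_profile(seed = 7)
  expect_identical(g1$intensity, g2$intensity)

  # one gel population: exactly 3 peaks above noise below 0.45 A^-1
  bl <- estimate_baseline(g1)
  expect_equal(nrow(detect_peaks(g1, bl)), 3L)

  # empty simulation is rejected
  inst0 <- instrument_config("SAXS", background = c(0))
  expect_error(synthesize_profile(list(), instrument = inst0), "nothing")

  # volume fractions above 1 are rejected
  expect_error(synthesize_profile(
    list(list(edp = gel_bilayer_model(4.99), stack = gel_stack(4.99, phi = 0.7)),
         list(edp = fluid_bilayer_model(7), stack = fluid_stack(7, phi = 0.7))),
    instrument = instrument_config("SAXS")), "sum")
})

test_that("powder rendering: ring geometry, azimuthal isotropy, beam-centre check", {
  inst <- instrument_config("SAXS", seed = 3, image_size = 64L,
                            pixel_mm = 4.4)
  # narrow ring: bright pixels concentrate at the predicted radius
  qstar <- 0.2
  img <- render_powder_image(function(q)
    2e3 * exp(-(q - qstar)^2 / (2 * 0.008^2)), inst)
  bright <- which(img$counts > 300, arr.ind = TRUE)
  r_obs <- sqrt((bright[, 1] - inst$beam_center[1])^2 +
                  (bright[, 2] - inst$beam_center[2])^2)
  expect_equal(mean(r_obs), ring_radius_px(qstar, inst), tolerance = 0.05)

  # flat expected counts: azimuthal bins statistically uniform
  flat <- render_powder_image(function(q) rep(200, length(q)),
                              instrument_config("SAXS", seed = 9,
                                                image_size = 64L,
                                                pixel_mm = 4.4))
  ang <- atan2(row(flat$counts) - 32.5, col(flat$counts) - 32.5)
  sector <- cut(as.vector(ang), breaks = seq(-pi, pi, length.out = 9))
  tot <- tapply(as.vector(flat$counts), sector, sum)
  npix <- tabulate(as.integer(sector), 8)   # wedge pixel counts differ
  chi <- sum((tot - npix * 200)^2 / (npix * 200))
  expect_lt(chi, qchisq(0.99, df = 8))

  bad <- instrument_config("SAXS", beam_center = c(-5, 10))
  expect_error(render_powder_image(function(q) q * 0 + 1, bad),
               "beam centre")
})

test_that("phase grid rules assign the canonical states and reject contradictions", {
  r <- phase_rules()
  expect_equal(phase_state_at(r, 0.1, 25)$state, "coexistence")
  expect_equal(phase_state_at(r, 0.1, 35)$state, "fluid")
  expect_equal(phase_state_at(r, 2.5, 35)$state, "fluid")
  expect_equal(phase_state_at(r, 0, 20)$state, "gel")
  # fully gel membrane only below the band and only under 0.2 mol%
  expect_equal(phase_state_at(r, 0.1, 20)$state, "gel")
  expect_equal(phase_state_at(r, 0.5, 20)$state, "coexistence")
  # pure-host ripple regime is gel-with-flag, not a forced new state
  st <- phase_state_at(r, 0, 38)
  expect_equal(st$state, "gel")
  expect_true(st$ripple_flag)
  expect_error(phase_rules(ripple_onset = 45), "contradictory")
  expect_error(phase_rules(fluid_onset = 43), "contradictory")
})

test_that("generated coexistence points carry two populations with the stated d values", {
  grid <- generate_phase_grid(compositions = 0.1, temperatures = c(25, 35),
                              seed = 5)
  expect_equal(grid$truth$state, c("coexistence", "fluid"))
  expect_equal(grid$truth$d_gel[1], 4.99)
  expect_equal(grid$truth$d_fluid[1], 7.00)
  # gel-bearing point gets a WAXS companion, fluid-only does not
  expect_false(is.null(grid$points[[1]]$waxs))
  expect_null(grid$points[[2]]$waxs)
})
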