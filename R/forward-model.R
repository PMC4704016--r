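# Forward diffraction simulator: ground-truth bilayer electron-density
# models, lamellar structure factors, and Poisson-sampled 1D profiles.

#' Gaussian bilayer electron-density model
#'
#' A relative electron-density profile across one bilayer, expressed as a
#' sum of Gaussian components on the bilayer-normal coordinate z (nm),
#' symmetric about the bilayer centre z = 0.  Every off-centre component
#' must have a mirror partner with identical width, amplitude and sign.
#'
#' @param components data frame with columns `z` (centre, nm), `sigma`
#'   (Gaussian width, nm, > 0), `A` (amplitude, relative electron density,
#'   > 0) and `sign` (+1 or -1; electron density above/below the solvent
#'   level).
#' @param d lamellar repeat distance of the stack this bilayer sits in, nm.
#' @return object of class `bilayer_edp_model`.
#' @export
bilayer_edp_model <- function(components, d) {
  components <- as.data.frame(components)
  stopifnot(all(c("z", "sigma", "A", "sign") %in% names(components)),
            is.numeric(d), length(d) == 1L, d > 0)
  if (any(components$sigma <= 0)) stop("all component widths must be > 0")
  if (any(components$A <= 0)) stop("component amplitudes must be > 0 (use `sign`)")
  if (!all(components$sign %in% c(-1, 1))) stop("`sign` must be +1 or -1")
  if (!edp_model_is_symmetric(components))
    stop("bilayer model must be mirror-symmetric: every off-centre ",
         "component needs a partner at -z with identical sigma, A and sign")
  zh <- headgroup_z(components)
  if (!is.na(zh) && !(2 * zh > 0 && 2 * zh < d))
    stop("head-to-head distance 2*|z_head| must lie inside (0, d)")
  structure(list(components = components, d = d),
            class = "bilayer_edp_model")
}

edp_model_is_symmetric <- function(components, tol = 1e-9) {
  off <- components[abs(components$z) > tol, , drop = FALSE]
  if (nrow(off) == 0L) return(TRUE)
  for (i in seq_len(nrow(off))) {
    match <- abs(off$z + off$z[i]) < tol &
      abs(off$sigma - off$sigma[i]) < tol &
      abs(off$A - off$A[i]) < tol &
      off$sign == off$sign[i]
    if (!any(match)) return(FALSE)
  }
  TRUE
}

# Centre of the positive off-centre component with the largest amplitude
# (the headgroup peak); NA if the model has no positive off-centre term.
headgroup_z <- function(components) {
  pos <- components[components$sign > 0 & abs(components$z) > 1e-9, , drop = FALSE]
  if (nrow(pos) == 0L) return(NA_real_)
  abs(pos$z[which.max(pos$A)])
}

#' True head-to-head distance of a bilayer model
#'
#' Twice the centre of the positive headgroup component, nm.
#' @param model a [bilayer_edp_model()].
#' @export
true_dpp <- function(model) {
  stopifnot(inherits(model, "bilayer_edp_model"))
  2 * headgroup_z(model$components)
}

#' Default gel-phase (L-beta-prime) bilayer phantom
#'
#' Headgroup Gaussians at +-z_head with a deep, narrow terminal-methyl
#' trough at the centre -- the canonical shape of a rigid, ordered
#' saturated-PC bilayer.  The headgroup position defaults to a fixed
#' fraction of the repeat distance so phantoms at different d stay
#' geometrically similar.
#'
#' @param d repeat distance, nm.
#' @param dpp_frac head-to-head distance as a fraction of d.
#' @param sigma_head,sigma_methyl Gaussian widths, nm.
#' @param methyl_amp methyl-trough amplitude (positive; applied with sign -1).
#' @export
gel_bilayer_model <- function(d = 4.99, dpp_frac = 0.67,
                              sigma_head = 0.25, sigma_methyl = 0.25,
                              methyl_amp = 1.0) {
  zh <- dpp_frac * d / 2
  bilayer_edp_model(data.frame(
    z = c(zh, -zh, 0), sigma = c(sigma_head, sigma_head, sigma_methyl),
    A = c(1, 1, methyl_amp), sign = c(1, 1, -1)), d = d)
}

#' Default fluid-phase (L-alpha) bilayer phantom
#'
#' Broader, softer features than the gel phantom: thermal disorder smears
#' the headgroup maxima and shallows the methyl trough.
#'
#' @inheritParams gel_bilayer_model
#' @export
fluid_bilayer_model <- function(d = 7.00, dpp_frac = 0.566,
                                sigma_head = 0.45, sigma_methyl = 0.40,
                                methyl_amp = 0.8) {
  zh <- dpp_frac * d / 2
  bilayer_edp_model(data.frame(
    z = c(zh, -zh, 0), sigma = c(sigma_head, sigma_head, sigma_methyl),
    A = c(1, 1, methyl_amp), sign = c(1, 1, -1)), d = d)
}

#' Analytic bilayer form factor
#'
#' Continuous cosine transform of the symmetric Gaussian electron-density
#' model: \deqn{F(q) = \sum_i s_i A_i \sqrt{2\pi}\,\sigma_i
#'   e^{-q^2\sigma_i^2/2} \cos(q z_i).}
#' For a centrosymmetric bilayer F is real.
#'
#' @param model a [bilayer_edp_model()].
#' @param q scattering-vector grid.
#' @param q_unit `"invA"` (default; converted internally to the nm-based
#'   model coordinates) or `"invnm"`.
#' @return numeric vector F(q), arbitrary units.
#' @export
analytic_form_factor <- function(model, q, q_unit = c("invA", "invnm")) {
  stopifnot(inherits(model, "bilayer_edp_model"), is.numeric(q))
  q_unit <- match.arg(q_unit)
  if (!edp_model_is_symmetric(model$components))
    stop("form factor requires a mirror-symmetric model")
  qn <- if (q_unit == "invA") 10 * q else q
  cmp <- model$components
  vapply(qn, function(qq) {
    sum(cmp$sign * cmp$A * sqrt(2 * pi) * cmp$sigma *
          exp(-qq^2 * cmp$sigma^2 / 2) * cos(qq * cmp$z))
  }, numeric(1))
}

#' Lamellar stacking model
#'
#' Describes one population of stacked bilayers: orders appear at
#' q_h = 2\eqn{\pi}h/d with Gaussian width `w1 * h^beta` and relative peak
#' height exp(-eta h^2).  The gel defaults give resolution-limited sharp
#' orders (at least three visible below the detector cutoff); the fluid
#' defaults (strong order broadening and damping) give exactly two -- the
#' short-range-order signature of the fluid lamellar phase.
#'
#' @param phase `"gel"` or `"fluid"` (ground-truth label carried along).
#' @param d repeat distance, nm.
#' @param w1 fundamental Gaussian peak width (sigma), inverse Angstrom.
#' @param beta order-broadening exponent (width of order h = w1 * h^beta).
#' @param eta amplitude damping: order h is scaled by exp(-eta h^2).
#' @param phi volume fraction of this population in [0, 1].
#' @export
lamellar_stack_model <- function(phase = c("gel", "fluid"), d,
                                 w1 = NULL, beta = NULL, eta = NULL,
                                 phi = 1) {
  phase <- match.arg(phase)
  def <- if (phase == "gel") list(w1 = 8e-4, beta = 0, eta = 0)
         else list(w1 = 1.5e-3, beta = 2, eta = 0.55)
  w1 <- w1 %||% def$w1; beta <- beta %||% def$beta; eta <- eta %||% def$eta
  stopifnot(d > 0, w1 > 0, eta >= 0, phi >= 0, phi <= 1)
  structure(list(phase = phase, d = d, w1 = w1, beta = beta, eta = eta,
                 phi = phi),
            class = "lamellar_stack_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname lamellar_stack_model
#' @export
gel_stack <- function(d = 4.99, phi = 1, ...)
  lamellar_stack_model("gel", d = d, phi = phi, ...)

#' @rdname lamellar_stack_model
#' @export
fluid_stack <- function(d = 7.00, phi = 1, ...)
  lamellar_stack_model("fluid", d = d, phi = phi, ...)

#' Lamellar structure factor
#'
#' Sum over orders h >= 1 of unit-height Gaussians centred at 2\eqn{\pi}h/d
#' scaled by exp(-eta h^2), with width w1 * h^beta.
#'
#' @param stack a [lamellar_stack_model()].
#' @param q grid, inverse Angstrom.
#' @export
structure_factor <- function(stack, q) {
  stopifnot(inherits(stack, "lamellar_stack_model"), is.numeric(q))
  q1 <- d_to_q(stack$d)
  h_max <- max(1L, ceiling((max(q) + 6 * stack$w1) / q1))
  S <- numeric(length(q))
  for (h in seq_len(h_max)) {
    amp <- exp(-stack$eta * h^2)
    if (amp < 1e-12) next
    w <- stack$w1 * h^stack$beta
    S <- S + amp * exp(-(q - h * q1)^2 / (2 * w^2))
  }
  S
}

#' WAXS chain-packing peak model
#'
#' The wide-angle reflection from in-plane acyl-chain packing; present only
#' for gel-phase (ordered-chain) populations.
#'
#' @param q_chain peak position, inverse Angstrom (typically 1.4--1.7).
#' @param width Gaussian sigma, inverse Angstrom.
#' @param amplitude peak height, counts.
#' @param present logical flag.
#' @export
waxs_chain_model <- function(q_chain = 1.57, width = 0.015,
                             amplitude = 2000, present = TRUE) {
  stopifnot(q_chain > 0, width > 0, amplitude >= 0)
  if (present && (q_chain < 1.4 || q_chain > 1.7))
    warning("chain peak outside the usual 1.4-1.7 A^-1 window")
  structure(list(q_chain = q_chain, width = width, amplitude = amplitude,
                 present = isTRUE(present)),
            class = "waxs_chain_model")
}

#' Instrument and acquisition configuration
#'
#' Wavelength, q-range, binning, detector geometry, counting scale,
#' background model and RNG seed for the simulator.  Defaults follow a
#' synchrotron SAXS setup: wavelength 1.127 Angstrom (11 keV), 1.7 m
#' sample-detector distance, data collected up to q_max = 0.45 inverse
#' Angstrom.  `mode = "WAXS"` switches to a wide-angle window covering the
#' chain-packing peak.
#'
#' @param mode `"SAXS"` or `"WAXS"`.
#' @param wavelength Angstrom.
#' @param q_min,q_max profile range, inverse Angstrom.
#' @param n_bins number of q bins.
#' @param distance_m sample-detector distance, metres.
#' @param pixel_mm detector pixel size, mm.
#' @param image_size detector size in pixels (square).
#' @param beam_center beam centre (x, y) in pixel coordinates.
#' @param exposure_scale overall counting scale (counts).
#' @param background polynomial coefficients (intercept, slope, ...) of the
#'   expected background counts as a function of q.
#' @param seed RNG seed; a fixed seed makes every simulator output
#'   byte-identical across runs.
#' @export
instrument_config <- function(mode = c("SAXS", "WAXS"),
                              wavelength = 1.127,
                              q_min = NULL, q_max = NULL, n_bins = NULL,
                              distance_m = 1.7, pixel_mm = 1.1,
                              image_size = 256L,
                              beam_center = NULL,
                              exposure_scale = 250,
                              background = NULL,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "SAXS") {
    q_min <- q_min %||% 0.01; q_max <- q_max %||% 0.45
    n_bins <- n_bins %||% 600L
    background <- background %||% c(50, -40)
  } else {
    q_min <- q_min %||% 1.20; q_max <- q_max %||% 1.90
    n_bins <- n_bins %||% 350L
    background <- background %||% c(35, -5)
  }
  beam_center <- beam_center %||% rep((image_size + 1) / 2, 2)
  stopifnot(wavelength > 0, q_min > 0, q_min < q_max, n_bins >= 10,
            distance_m > 0, pixel_mm > 0, exposure_scale > 0)
  structure(list(mode = mode, wavelength = wavelength,
                 q_min = q_min, q_max = q_max, n_bins = as.integer(n_bins),
                 distance_m = distance_m, pixel_mm = pixel_mm,
                 image_size = as.integer(image_size),
                 beam_center = beam_center,
                 exposure_scale = exposure_scale,
                 background = background, seed = as.integer(seed)),
            class = "instrument_config")
}

q_grid <- function(instrument) {
  seq(instrument$q_min, instrument$q_max, length.out = instrument$n_bins)
}

background_at <- function(instrument, q) {
  b <- outer(q, seq_along(instrument$background) - 1, `^`) %*%
    instrument$background
  pmax(drop(b), 0)
}

#' 1D scattering profile container
#'
#' @param q strictly increasing, positive scattering-vector grid
#'   (inverse Angstrom).
#' @param intensity counts, same length as `q`, >= 0 (NA marks missing bins).
#' @param uncertainty optional per-bin uncertainty, counts.
#' @param meta a [sample_meta()].
#' @param mode `"SAXS"` or `"WAXS"`.
#' @export
scattering_profile <- function(q, intensity, uncertainty = NULL,
                               meta = sample_meta(),
                               mode = c("SAXS", "WAXS")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(q), is.numeric(intensity),
            length(q) == length(intensity),
            all(q > 0), all(diff(q) > 0),
            all(intensity >= 0, na.rm = TRUE))
  if (!is.null(uncertainty)) stopifnot(length(uncertainty) == length(q))
  structure(list(q = q, intensity = as.numeric(intensity),
                 uncertainty = uncertainty, meta = meta, mode = mode),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %s, %d bins, q in [%.4g, %.4g] A^-1\n",
              x$mode, length(x$q), min(x$q), max(x$q)))
  print(x$meta)
  invisible(x)
}

#' @export
plot.scattering_profile <- function(x, log = "y", ...) {
  graphics::plot(x$q, pmax(x$intensity, 0.5),
                 type = "l", log = log,
                 xlab = expression(q ~ (ring(A)^-1)),
                 ylab = "intensity (counts)", ...)
  invisible(x)
}

# Expected (noise-free) counts for a set of populations on a q grid.
expected_counts <- function(populations, waxs, instrument, q) {
  lam <- background_at(instrument, q)
  if (instrument$mode == "SAXS") {
    for (pop in populations) {
      Fq <- analytic_form_factor(pop$edp, q)
      S <- structure_factor(pop$stack, q)
      lam <- lam + instrument$exposure_scale * pop$stack$phi *
        S * Fq^2 / q^2          # 1/q^2 Lorentz factor, powder lamellae
    }
  }
  if (!is.null(waxs) && waxs$present && instrument$mode == "WAXS") {
    lam <- lam + waxs$amplitude *
      exp(-(q - waxs$q_chain)^2 / (2 * waxs$width^2))
  }
  lam
}

check_populations <- function(populations) {
  for (pop in populations) {
    stopifnot(inherits(pop$edp, "bilayer_edp_model"),
              inherits(pop$stack, "lamellar_stack_model"))
    if (abs(pop$edp$d - pop$stack$d) > 1e-9)
      stop("population bilayer model and stack model disagree on d")
  }
  phi <- sum(vapply(populations, function(p) p$stack$phi, numeric(1)))
  if (phi > 1 + 1e-9) stop("population volume fractions sum to > 1")
  invisible(phi)
}

#' Synthesize a 1D scattering profile
#'
#' Expected counts are background(q) plus, per population,
#' `phi * S(q) * F(q)^2 / q^2` (incoherent sum over populations; 1/q^2
#' Lorentz factor for unoriented lamellar powders), scaled by the exposure
#' level; in WAXS mode the chain-packing Gaussian is added instead.
#' Intensities are drawn from Poisson(lambda) using the instrument seed,
#' so a fixed seed gives byte-identical profiles.
#'
#' @param populations list of `list(edp = bilayer_edp_model, stack =
#'   lamellar_stack_model)`; volume fractions must sum to <= 1.
#' @param waxs optional [waxs_chain_model()] (used in WAXS mode).
#' @param instrument an [instrument_config()].
#' @param meta a [sample_meta()].
#' @export
synthesize_profile <- function(populations = list(), waxs = NULL,
                               instrument = instrument_config(),
                               meta = sample_meta()) {
  stopifnot(inherits(instrument, "instrument_config"))
  check_populations(populations)
  if (length(populations) == 0L && is.null(waxs) &&
      all(abs(instrument$background) < 1e-12))
    stop("nothing to simulate: no populations, no WAXS peak, no background")
  q <- q_grid(instrument)
  lam <- expected_counts(populations, waxs, instrument, q)
  counts <- with_seed(instrument$seed, stats::rpois(length(q), lam))
  scattering_profile(q, counts, uncertainty = sqrt(pmax(lam, 1)),
                     meta = meta, mode = instrument$mode)
}

#' Render a 2D powder image
#'
#' Maps every detector pixel to its scattering vector via
#' \eqn{q = (4\pi/\lambda)\sin(\theta/2)} with
#' \eqn{\theta = \arctan(r_{pix} \cdot pixel / distance)}, evaluates the
#' expected counts there, and Poisson-samples with the instrument seed.
#'
#' @param x source of expected counts: a function of q, a
#'   [scattering_profile()] (interpolated; counts outside its range fall
#'   back to the instrument background), or a list of populations as in
#'   [synthesize_profile()].
#' @param instrument an [instrument_config()] with detector geometry.
#' @param waxs optional [waxs_chain_model()] (population source only).
#' @return object of class `powder_image`: integer count matrix plus
#'   geometry.
#' @export
render_powder_image <- function(x, instrument = instrument_config(),
                                waxs = NULL) {
  stopifnot(inherits(instrument, "instrument_config"))
  n <- instrument$image_size
  bc <- instrument$beam_center
  if (bc[1] < 1 || bc[1] > n || bc[2] < 1 || bc[2] > n)
    stop("beam centre lies outside the detector image")
  lam_fun <-
    if (is.function(x)) x
    else if (inherits(x, "scattering_profile")) {
      prof <- x
      function(q) {
        y <- stats::approx(prof$q, prof$intensity, xout = q, rule = 1)$y
        ifelse(is.na(y), background_at(instrument, q), y)
      }
    } else if (is.list(x)) {
      check_populations(x)
      function(q) expected_counts(x, waxs, instrument, q)
    } else stop("unsupported expected-counts source")
  q <- pixel_q(instrument)
  lam <- matrix(pmax(lam_fun(as.vector(q)), 0), n, n)
  counts <- with_seed(instrument$seed,
                      matrix(stats::rpois(n * n, lam), n, n))
  structure(list(counts = counts, geometry = instrument),
            class = "powder_image")
}

# Per-pixel scattering vector (matrix, inverse Angstrom).
pixel_q <- function(instrument) {
  n <- instrument$image_size
  bc <- instrument$beam_center
  dx <- matrix(seq_len(n) - bc[1], n, n)
  dy <- matrix(seq_len(n) - bc[2], n, n, byrow = TRUE)
  r_m <- sqrt(dx^2 + dy^2) * instrument$pixel_mm / 1000
  theta <- atan(r_m / instrument$distance_m)
  (4 * pi / instrument$wavelength) * sin(theta / 2)
}

#' Radius (pixels) of the powder ring at scattering vector q
#'
#' Inverse of the pixel -> q mapping used by [render_powder_image()].
#' @param q inverse Angstrom.
#' @param instrument an [instrument_config()].
#' @export
ring_radius_px <- function(q, instrument) {
  s <- q * instrument$wavelength / (4 * pi)
  stopifnot(all(s < 1))
  instrument$distance_m * tan(2 * asin(s)) * 1000 / instrument$pixel_mm
}

#' @export
print.powder_image <- function(x, ...) {
  cat(sprintf("<powder_image> %dx%d px, %s mode, total %.3g counts\n",
              nrow(x$counts), ncol(x$counts), x$geometry$mode,
              sum(x$counts)))
  invisible(x)
}
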