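# Rule-driven synthetic phase grids: each (composition, temperature) point
# is assigned a thermodynamic state, profiles are simulated from it, and
# the ground-truth label travels alongside for validation.

#' Phase-behaviour rules for the synthetic grid
#'
#' The rules are data, not code: they parameterize the binary phase map the
#' generator emulates.  Defaults encode the studied DPPC host / PUFA-PE
#' guest system: a pure-host melting point near 41.5 degC with a ripple
#' regime just below it, a fluid onset at 30 degC once any guest lipid is
#' present (rising slowly above 1 mol\%), a coexistence band about 7 degC
#' wide below the fluid onset, and a fully gel membrane only below that
#' band and only under 0.2 mol\% guest.
#'
#' Repeat distances: the pure-host gel stack at 6.28 nm, the mixed gel
#' stack at 4.99 nm, and a fluid stack starting at 7.00 nm at 25 degC that
#' shrinks slowly on heating.  The gel WAXS chain-packing position moves
#' from 1.486 (pure) to 1.576 (trace guest) to 1.537 (>= 1 mol\%) inverse
#' Angstrom.
#'
#' @param pure_tm pure-host main transition, degC.
#' @param ripple_onset lower edge of the pure-host ripple regime, degC
#'   (labelled gel with a flag; no distinct pattern is synthesized).
#' @param fluid_onset fluid-only onset for any guest content, degC.
#' @param tm_slope_above1 increase of the fluid onset per mol\% above
#'   1 mol\%, degC.
#' @param coex_band_width width of the coexistence band, degC.
#' @param gel_only_max_c maximum guest content (mol\%) that still shows a
#'   fully gel membrane below the coexistence band.
#' @param d_gel_pure,d_gel_mix gel repeat distances, nm.
#' @param d_fluid_25 fluid repeat distance at 25 degC, nm.
#' @param d_fluid_slope change of fluid d per degC, nm.
#' @param phi_gel_range gel volume fraction at the bottom and top of the
#'   coexistence band (linear lever rule in between).
#' @param waxs_q_pure,waxs_q_trace,waxs_q_high gel chain-peak positions,
#'   inverse Angstrom.
#' @param t_range instrument-accessible temperature range, degC.
#' @export
phase_rules <- function(pure_tm = 41.5, ripple_onset = 34,
                        fluid_onset = 30, tm_slope_above1 = 2,
                        coex_band_width = 7, gel_only_max_c = 0.2,
                        d_gel_pure = 6.28, d_gel_mix = 4.99,
                        d_fluid_25 = 7.00, d_fluid_slope = -7/300,
                        phi_gel_range = c(0.75, 0.25),
                        waxs_q_pure = 1.486, waxs_q_trace = 1.576,
                        waxs_q_high = 1.537,
                        t_range = c(16, 45)) {
  rules <- structure(as.list(environment()), class = "phase_rules")
  validate_phase_rules(rules)
  rules
}

validate_phase_rules <- function(r) {
  stopifnot(r$coex_band_width > 0, r$gel_only_max_c >= 0,
            r$d_gel_pure > 0, r$d_gel_mix > 0, r$d_fluid_25 > 0,
            length(r$phi_gel_range) == 2,
            all(r$phi_gel_range > 0), all(r$phi_gel_range < 1),
            r$t_range[1] < r$t_range[2])
  if (r$fluid_onset - r$coex_band_width >= r$fluid_onset)
    stop("contradictory rules: empty coexistence band")
  if (r$ripple_onset >= r$pure_tm)
    stop("contradictory rules: ripple regime above the pure-host melting point")
  if (r$fluid_onset > r$pure_tm)
    stop("contradictory rules: mixed fluid onset above the pure-host melting point")
  invisible(r)
}

# Fluid-only onset temperature for a given guest content.
fluid_onset_at <- function(rules, comp) {
  if (comp <= 0) return(rules$pure_tm)
  rules$fluid_onset + rules$tm_slope_above1 * max(0, comp - 1)
}

#' Ground-truth state at one grid point
#'
#' @param rules a [phase_rules()].
#' @param comp guest content, mol\%.
#' @param temp temperature, degC.
#' @return list with `state` (gel/coexistence/fluid), `ripple_flag`,
#'   `phi_gel`, `d_gel`, `d_fluid`, `waxs_q`.
#' @export
phase_state_at <- function(rules, comp, temp) {
  stopifnot(inherits(rules, "phase_rules"), comp >= 0)
  tm <- fluid_onset_at(rules, comp)
  coex_lo <- tm - rules$coex_band_width
  d_gel <- if (comp <= 0) rules$d_gel_pure else rules$d_gel_mix
  d_fluid <- rules$d_fluid_25 + rules$d_fluid_slope * (temp - 25)
  waxs_q <- if (comp <= 0) rules$waxs_q_pure
            else if (comp < 1) rules$waxs_q_trace else rules$waxs_q_high
  if (temp >= tm)
    return(list(state = "fluid", ripple_flag = FALSE, phi_gel = 0,
                d_gel = NA_real_, d_fluid = d_fluid, waxs_q = NA_real_))
  if (comp <= 0) {
    # single component: no two-phase band, ripple regime flagged as gel
    return(list(state = "gel", ripple_flag = temp >= rules$ripple_onset,
                phi_gel = 1, d_gel = d_gel, d_fluid = NA_real_,
                waxs_q = waxs_q))
  }
  if (temp >= coex_lo || comp > rules$gel_only_max_c) {
    frac <- if (temp >= coex_lo)
      (temp - coex_lo) / rules$coex_band_width else 0
    phi_gel <- rules$phi_gel_range[1] +
      frac * diff(rules$phi_gel_range)
    return(list(state = "coexistence", ripple_flag = FALSE,
                phi_gel = phi_gel, d_gel = d_gel, d_fluid = d_fluid,
                waxs_q = waxs_q))
  }
  list(state = "gel", ripple_flag = FALSE, phi_gel = 1,
       d_gel = d_gel, d_fluid = NA_real_, waxs_q = waxs_q)
}

#' Generate a labelled synthetic phase grid
#'
#' For every (composition, temperature) combination the rules assign a
#' state; a SAXS profile (and, when a gel fraction exists, a WAXS profile)
#' is simulated from the corresponding populations; the true label is
#' returned alongside.
#'
#' @param compositions guest contents, mol\%.
#' @param temperatures degC; must lie within `rules$t_range`.
#' @param rules a [phase_rules()].
#' @param instrument SAXS [instrument_config()] used as the template; the
#'   WAXS companion is derived from it.
#' @param seed master seed; each grid point receives its own child seed.
#' @return object of class `phase_grid`: list with `points` (each holding
#'   `saxs`, optional `waxs`, `truth` row) and a `truth` data frame
#'   (composition, temperature, state, ripple_flag, d_gel, d_fluid).
#' @export
generate_phase_grid <- function(compositions = c(0, 0.1, 0.25, 0.5, 1, 2.5),
                                temperatures = seq(16, 44, by = 4),
                                rules = phase_rules(),
                                instrument = instrument_config("SAXS"),
                                seed = 1L) {
  stopifnot(inherits(rules, "phase_rules"),
            all(temperatures >= rules$t_range[1]),
            all(temperatures <= rules$t_range[2]))
  grid <- expand.grid(composition = compositions,
                      temperature = temperatures,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- child_seeds(seed, 2L * nrow(grid))
  points <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    comp <- grid$composition[i]; temp <- grid$temperature[i]
    st <- phase_state_at(rules, comp, temp)
    meta <- sample_meta(comp, temp,
                        label = sprintf("c%.2f_T%04.1f", comp, temp))
    pops <- list()
    if (st$phi_gel > 0)
      pops <- c(pops, list(list(edp = gel_bilayer_model(st$d_gel),
                                stack = gel_stack(st$d_gel,
                                                  phi = st$phi_gel))))
    if (st$phi_gel < 1)
      pops <- c(pops, list(list(edp = fluid_bilayer_model(st$d_fluid),
                                stack = fluid_stack(st$d_fluid,
                                                    phi = 1 - st$phi_gel))))
    inst_s <- instrument
    inst_s$seed <- seeds[2L * i - 1L]
    saxs <- synthesize_profile(pops, instrument = inst_s, meta = meta)
    waxs_prof <- NULL
    if (st$phi_gel > 0) {
      inst_w <- instrument_config("WAXS", wavelength = instrument$wavelength,
                                  seed = seeds[2L * i])
      chain <- waxs_chain_model(q_chain = st$waxs_q,
                                amplitude = 2000 * st$phi_gel)
      waxs_prof <- synthesize_profile(list(), waxs = chain,
                                      instrument = inst_w, meta = meta)
    }
    points[[i]] <- list(saxs = saxs, waxs = waxs_prof, truth = st)
    truth[[i]] <- data.frame(composition = comp, temperature = temp,
                             state = st$state,
                             ripple_flag = st$ripple_flag,
                             d_gel = st$d_gel, d_fluid = st$d_fluid)
  }
  structure(list(points = points, truth = do.call(rbind, truth),
                 rules = rules, seed = seed),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("<phase_grid> %d points (%s)\n", length(x$points),
              paste(sprintf("%s: %d", names(table(x$truth$state)),
                            table(x$truth$state)), collapse = ", ")))
  invisible(x)
}
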