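# Indexing fitted peaks into lamellar series, phase classification,
# point assessment, and phase-diagram assembly.

#' Group fitted peaks into lamellar series
#'
#' Candidate fundamentals are generated as `q0 / h` for every peak and
#' h = 1..3; each candidate is scored by how many peaks it matches at
#' integer multiples within `rel_tolerance` (each order used at most once;
#' when two peaks compete for one order the closer wins).  Series are
#' accepted greedily -- most orders first, ties broken by smallest RMS
#' residual -- matched peaks are removed, and the scan repeats.  The
#' fundamental of each accepted series is refined by weighted least
#' squares of q_h against h through the origin.  Peaks matching no
#' multi-order series are returned as singleton series (orphans).
#'
#' @param peaks a `peak_table` (or data frame with `q0`, `area`, `fwhm`),
#'   sorted by q0.
#' @param rel_tolerance relative tolerance on |q0 - h q1| / (h q1).
#' @param max_order largest order considered.
#' @return list of `lamellar_series` objects, multi-order series first.
#' @export
group_series <- function(peaks, rel_tolerance = 0.015, max_order = 6L) {
  stopifnot(nrow(peaks) >= 1, !is.unsorted(peaks$q0))
  remaining <- seq_len(nrow(peaks))
  series <- list()
  repeat {
    if (length(remaining) == 0L) break
    best <- NULL
    for (i in remaining) for (h in 1:3) {
      q1c <- peaks$q0[i] / h
      m <- match_orders(peaks$q0[remaining], q1c, rel_tolerance, max_order)
      if (is.null(m) || length(m$idx) < 2L) next
      cand <- list(members = remaining[m$idx], h = m$h, rms = m$rms)
      if (is.null(best) ||
          length(cand$members) > length(best$members) ||
          (length(cand$members) == length(best$members) &&
           cand$rms < best$rms))
        best <- cand
    }
    if (is.null(best)) break
    series <- c(series, list(make_series(peaks, best$members, best$h)))
    remaining <- setdiff(remaining, best$members)
  }
  orphans <- lapply(remaining, function(i) make_series(peaks, i, 1L))
  c(series, orphans)
}

# Assign peaks to integer orders of a trial fundamental.  Returns indices
# into `qs`, their orders, and the RMS relative residual.  A series must
# contain its first order: the instrument window starts well below any
# lamellar fundamental, so a repeat whose h = 1 reflection is absent is a
# sub-harmonic artifact, not a physical stack.
match_orders <- function(qs, q1c, rel_tol, max_order) {
  if (q1c <= 0) return(NULL)
  h <- round(qs / q1c)
  ok <- h >= 1 & h <= max_order &
    abs(qs - h * q1c) <= rel_tol * pmax(h * q1c, 1e-12)
  if (!any(h[ok] == 1)) return(NULL)
  if (!any(ok)) return(NULL)
  idx <- which(ok); hh <- h[ok]
  # one peak per order: keep the closest
  rel <- abs(qs[idx] - hh * q1c) / (hh * q1c)
  keep <- !duplicated(hh[order(rel)])
  ord <- order(rel)[keep]
  idx <- idx[ord]; hh <- hh[ord]
  o <- order(hh)
  list(idx = idx[o], h = hh[o], rms = sqrt(mean(rel[ord]^2)))
}

make_series <- function(peaks, members, h) {
  pk <- peaks[members, , drop = FALSE]
  w <- rep(1, nrow(pk))
  if (!is.null(pk$q0_se)) {
    ok <- is.finite(pk$q0_se) & pk$q0_se > 0
    w[ok] <- 1 / pk$q0_se[ok]^2
    w[!ok] <- if (any(ok)) stats::median(w[ok]) else 1
  }
  q1 <- sum(w * h * pk$q0) / sum(w * h^2)       # WLS through origin
  q1_se <- if (!is.null(pk$q0_se) && all(is.finite(pk$q0_se)))
    sqrt(1 / sum(w * h^2)) else NA_real_
  orders <- data.frame(h = h, q0 = pk$q0,
                       residual = pk$q0 - h * q1,
                       area = if (!is.null(pk$area)) pk$area else NA_real_,
                       fwhm = if (!is.null(pk$fwhm)) pk$fwhm else NA_real_,
                       area_se = if (!is.null(pk$area_se)) pk$area_se
                                 else NA_real_)
  structure(list(q1 = q1, q1_se = q1_se, d = q_to_d(q1), orders = orders,
                 n_orders = nrow(orders), phase = "unknown"),
            class = "lamellar_series")
}

#' Lamellar repeat distance of an indexed series
#'
#' `d = 2 pi / q1` with q1 the weighted least-squares fundamental;
#' uncertainty propagated from the fit errors.
#'
#' @param series a `lamellar_series`.
#' @return d in nm, with attribute `se` (nm) when fit errors are available.
#' @export
dspacing <- function(series) {
  stopifnot(inherits(series, "lamellar_series"), series$n_orders >= 1)
  d <- q_to_d(series$q1)
  if (is.finite(series$q1_se))
    attr(d, "se") <- d * series$q1_se / series$q1
  d
}

#' Classify a lamellar series as gel or fluid
#'
#' Gel (L-beta-prime) when the series shows >= 3 diffraction orders, or
#' >= 2 orders together with a sharp wide-angle chain-packing peak in
#' 1.45--1.65 inverse Angstrom.  Fluid (L-alpha) when it shows <= 2 orders
#' that are broad.  Anything else -- in particular a single order -- is
#' `unknown` (insufficient evidence; no label is forced).
#'
#' @param series a `lamellar_series`.
#' @param waxs_peaks optional `peak_table` from a WAXS profile.
#' @param sharp_fwhm width threshold (inverse Angstrom) separating sharp
#'   from broad first orders; default 3 instrument bins of the default
#'   SAXS grid.
#' @param waxs_window chain-peak search window, inverse Angstrom.
#' @return the series with `phase` set and a `decision` attribute tracing
#'   the rule that fired.
#' @export
classify_phase <- function(series, waxs_peaks = NULL,
                           sharp_fwhm = 0.0022,
                           waxs_window = c(1.45, 1.65)) {
  stopifnot(inherits(series, "lamellar_series"))
  fw <- series$orders$fwhm[series$orders$h == min(series$orders$h)][1]
  broad <- is.finite(fw) && fw >= sharp_fwhm
  chain <- !is.null(waxs_peaks) && nrow(waxs_peaks) > 0 &&
    any(waxs_peaks$q0 >= waxs_window[1] & waxs_peaks$q0 <= waxs_window[2])
  if (series$n_orders >= 3) {
    series$phase <- "gel"
    attr(series, "decision") <- ">=3 orders"
  } else if (series$n_orders >= 2 && chain && !broad) {
    series$phase <- "gel"
    attr(series, "decision") <- "2 sharp orders + WAXS chain peak"
  } else if (series$n_orders <= 2 && series$n_orders >= 2 && broad) {
    series$phase <- "fluid"
    attr(series, "decision") <- "<=2 broad orders"
  } else {
    series$phase <- "unknown"
    attr(series, "decision") <- "insufficient evidence"
  }
  series
}

#' @export
print.lamellar_series <- function(x, ...) {
  cat(sprintf("<lamellar_series> d = %.3f nm (q1 = %.5g A^-1), %d order%s, %s\n",
              x$d, x$q1, x$n_orders, if (x$n_orders > 1) "s" else "",
              x$phase))
  invisible(x)
}

#' Assess one sample point: full profile-to-phase chain
#'
#' Runs baseline estimation, peak detection, peak fitting, series
#' indexing and phase classification on a SAXS profile (plus an optional
#' WAXS companion), then sets the point state: `coexistence` when two or
#' more accepted (>= 2 order) series have repeat distances differing by
#' more than `coex_min_rel_dd`, otherwise the phase of the dominant
#' accepted series, `unknown` when no series is accepted.
#'
#' @param saxs SAXS [scattering_profile()].
#' @param waxs optional WAXS [scattering_profile()].
#' @param config a [run_config()] carrying the stage parameters.
#' @return object of class `phase_point`.
#' @export
assess_point <- function(saxs, waxs = NULL, config = run_config()) {
  stopifnot(inherits(saxs, "scattering_profile"))
  pf <- config$peakfit; lm <- config$lamellar
  stage <- function(what, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  bl <- stage("baseline", estimate_baseline(
    saxs, smoothness = pf$smoothness, asymmetry = pf$asymmetry))
  cand <- stage("detect", detect_peaks(
    saxs, bl, min_prominence_sigmas = pf$min_prominence_sigmas,
    smooth_window = pf$smooth_window,
    min_separation = pf$min_separation))
  waxs_fit <- NULL
  if (!is.null(waxs)) {
    waxs_fit <- tryCatch({
      blw <- estimate_baseline(waxs, smoothness = pf$smoothness,
                               asymmetry = pf$asymmetry)
      cw <- detect_peaks(waxs, blw,
                         min_prominence_sigmas = pf$min_prominence_sigmas,
                         smooth_window = pf$smooth_window,
                         min_separation = pf$min_separation)
      if (nrow(cw) > 0)
        label_waxs_peaks(fit_peaks(waxs, blw, cw, shape = pf$waxs_shape))
      else NULL
    }, error = function(e) NULL)
  }
  if (nrow(cand) == 0L) {
    return(structure(list(meta = saxs$meta, state = "unknown",
                          series = list(), waxs_gel_peak = NULL,
                          peaks = NULL, waxs_peaks = waxs_fit),
                     class = "phase_point"))
  }
  pk <- stage("fit", fit_peaks(saxs, bl, cand))
  series <- stage("index", group_series(
    pk, rel_tolerance = lm$rel_tolerance, max_order = lm$max_order))
  series <- lapply(series, classify_phase, waxs_peaks = waxs_fit,
                   sharp_fwhm = lm$sharp_fwhm)
  accepted <- Filter(function(s) s$n_orders >= 2, series)
  state <- "unknown"
  if (length(accepted) >= 2) {
    ds <- vapply(accepted, function(s) s$d, numeric(1))
    distinct <- abs(max(ds) - min(ds)) / min(ds) > lm$coex_min_rel_dd
    state <- if (distinct) "coexistence" else accepted[[1]]$phase
  } else if (length(accepted) == 1) {
    state <- accepted[[1]]$phase
  }
  chain_pk <- NULL
  if (!is.null(waxs_fit)) {
    inw <- which(waxs_fit$q0 >= 1.45 & waxs_fit$q0 <= 1.65)
    if (length(inw) > 0) chain_pk <- waxs_fit[inw[1], , drop = FALSE]
  }
  structure(list(meta = saxs$meta, state = state, series = series,
                 waxs_gel_peak = chain_pk, peaks = pk,
                 waxs_peaks = waxs_fit),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("<phase_point> state: %s\n", x$state))
  print(x$meta)
  for (s in x$series) print(s)
  if (!is.null(x$waxs_gel_peak))
    cat(sprintf("  WAXS chain peak at q = %.4f A^-1\n",
                x$waxs_gel_peak$q0))
  invisible(x)
}

#' Assemble a binary phase diagram from assessed points
#'
#' Tabulates states on the (composition, temperature) grid and derives a
#' per-composition transition temperature T_m: the midpoint between the
#' warmest coexistence temperature and the coolest fluid-only temperature
#' when both exist, else the boundary sample itself.  Within each
#' composition the states are checked for contiguity in temperature
#' (gel, then coexistence, then fluid); violations are flagged, not
#' hidden.
#'
#' @param points list of `phase_point` objects.
#' @return object of class `phase_diagram` with `table` (composition,
#'   temperature, state), `tm` (per-composition data frame with `T_m` and
#'   `note`), and `flags` (character vector of contiguity violations).
#' @export
build_phase_diagram <- function(points) {
  stopifnot(length(points) >= 1,
            all(vapply(points, inherits, logical(1), "phase_point")))
  tab <- do.call(rbind, lapply(points, function(p)
    data.frame(composition = p$meta$dha_molpercent,
               temperature = p$meta$temperature,
               state = p$state)))
  comps <- sort(unique(tab$composition))
  if (length(unique(tab$temperature)) < 2)
    stop("phase diagram needs at least two temperatures")
  flags <- character(0)
  tm <- do.call(rbind, lapply(comps, function(cc) {
    sub <- tab[tab$composition == cc, , drop = FALSE]
    sub <- sub[order(sub$temperature), , drop = FALSE]
    rank <- c(gel = 1, coexistence = 2, fluid = 3, unknown = NA)[sub$state]
    known <- !is.na(rank)
    if (any(diff(rank[known]) < 0))
      flags <<- c(flags, sprintf(
        "composition %.3g: states not contiguous in temperature", cc))
    fluid_t <- sub$temperature[sub$state == "fluid"]
    below_t <- sub$temperature[sub$state %in% c("gel", "coexistence")]
    coex_t <- sub$temperature[sub$state == "coexistence"]
    if (length(fluid_t) == 0)
      return(data.frame(composition = cc, T_m = NA_real_,
                        note = "above-range"))
    if (length(below_t) == 0)
      return(data.frame(composition = cc, T_m = min(fluid_t),
                        note = "unbounded below"))
    anchor <- if (length(coex_t) > 0) max(coex_t) else max(below_t)
    data.frame(composition = cc,
               T_m = (anchor + min(fluid_t)) / 2,
               note = if (length(coex_t) > 0) "midpoint" else
                 "boundary-sample")
  }))
  structure(list(table = tab, tm = tm, flags = flags),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d points, %d composition(s)\n",
              nrow(x$table), nrow(x$tm)))
  print(x$tm, row.names = FALSE)
  if (length(x$flags)) cat("flags:\n", paste(" -", x$flags, "\n"))
  invisible(x)
}

#' @export
summary.phase_diagram <- function(object, ...) {
  with(object$table, table(state, composition))
}

#' @export
plot.phase_diagram <- function(x, ...) {
  cols <- c(gel = "#3B6FB6", coexistence = "#8E44AD",
            fluid = "#D35400", unknown = "grey70")
  with(x$table, {
    graphics::plot(composition, temperature, pch = 15, cex = 2,
                   col = cols[state],
                   xlab = "guest lipid (mol%)",
                   ylab = expression(T ~ (degree * C)), ...)
  })
  graphics::legend("topright", legend = names(cols), col = cols,
                   pch = 15, bty = "n")
  invisible(x)
}
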