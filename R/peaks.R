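# Peak detection and nonlinear least-squares peak fitting.

#' Detect candidate Bragg peaks
#'
#' Works on the baseline-subtracted residual.  The residual is lightly
#' smoothed (Savitzky-Golay, quadratic) for detection only; candidates are
#' strict local maxima of the smoothed residual whose height above the
#' baseline exceeds `min_prominence_sigmas` times the robust noise scale
#' (median absolute deviation of the smoothed residual).  Peak prominence
#' is measured relative to the fitted baseline -- the baseline is the base
#' level -- so flat noise produces no candidates even when its extrema
#' span several sigma.  Neighbouring maxima on the same hump (no
#' intervening valley dropping below 70\% of the lower one) are merged.
#'
#' @param profile a [scattering_profile()].
#' @param baseline a [estimate_baseline()] result for the same profile.
#' @param min_prominence_sigmas detection threshold k; a peak needs height
#'   >= k * sigma_noise above the baseline.
#' @param smooth_window odd Savitzky-Golay window length (bins).
#' @param min_separation minimum distance between candidates (bins);
#'   closer pairs keep only the higher one.
#' @return data frame with columns `q`, `height` (above baseline), `bin`,
#'   sorted by q; zero rows when nothing exceeds the threshold.
#' @export
detect_peaks <- function(profile, baseline,
                         min_prominence_sigmas = 5,
                         smooth_window = 11L, min_separation = 8L) {
  stopifnot(inherits(profile, "scattering_profile"),
            inherits(baseline, "baseline"),
            min_prominence_sigmas > 0)
  resid <- profile$intensity - baseline$y
  resid[is.na(resid)] <- 0
  n <- length(resid)
  win <- min(as.integer(smooth_window), if (n %% 2L == 0L) n - 1L else n)
  if (win %% 2L == 0L) win <- win - 1L
  rs <- if (win >= 5L) signal::sgolayfilt(resid, p = 2, n = win) else resid
  # robust noise scale from first differences of the raw residual:
  # insensitive to the positive offset left by the lower-envelope baseline
  sigma <- max(stats::mad(diff(resid)) / sqrt(2), .Machine$double.eps)
  # relative floor guards the noise-free limit against baseline ripples
  thr <- max(min_prominence_sigmas * sigma, 1e-3 * max(rs, 0))
  # strict interior local maxima (plateaus break to the left-most point)
  i <- which(rs > c(Inf, rs[-n]) & rs >= c(rs[-1], Inf))
  i <- i[rs[i] >= thr & rs[i] > 0]
  i <- merge_close_maxima(rs, i, min_separation)
  i <- merge_same_hump(rs, i)
  out <- data.frame(q = profile$q[i], height = resid[i], bin = i)
  out[order(out$q), , drop = FALSE]
}

# Keep only the higher of any two maxima closer than min_sep bins.
merge_close_maxima <- function(rs, idx, min_sep) {
  if (length(idx) < 2L) return(idx)
  idx <- idx[order(rs[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx)
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  sort(kept)
}

# Merge maxima that sit on one broad hump: if the valley between two
# adjacent candidates stays above 70% of the lower candidate, they are
# the same peak -- keep the higher.
merge_same_hump <- function(rs, idx, valley_frac = 0.7) {
  while (length(idx) >= 2L) {
    merged <- FALSE
    for (k in seq_len(length(idx) - 1L)) {
      a <- idx[k]; b <- idx[k + 1L]
      valley <- min(rs[a:b])
      if (valley > valley_frac * min(rs[a], rs[b])) {
        idx <- idx[-(if (rs[a] >= rs[b]) k + 1L else k)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  idx
}

# ---- peak shapes --------------------------------------------------------

gauss_shape <- function(q, height, q0, sigma)
  height * exp(-(q - q0)^2 / (2 * sigma^2))

# pseudo-Voigt with mixing parameter eta sharing one fwhm
pvoigt_shape <- function(q, height, q0, sigma, eta) {
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  g <- exp(-(q - q0)^2 / (2 * sigma^2))
  l <- 1 / (1 + ((q - q0) / (fwhm / 2))^2)
  height * ((1 - eta) * g + eta * l)
}

gauss_area <- function(height, sigma) height * sigma * sqrt(2 * pi)

pvoigt_area <- function(height, sigma, eta) {
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  (1 - eta) * gauss_area(height, sigma) + eta * height * pi * fwhm / 2
}

#' Fit detected peaks by nonlinear least squares
#'
#' Each candidate gets a local window sized from the half-maximum extent of
#' the baseline-subtracted signal; windows overlapping by more than 25\%
#' are fitted jointly as a sum of peaks (tie-break: overlap fraction is
#' measured against the narrower window).  The default shape is Gaussian;
#' `shape = "pseudo-voigt"` adds a Lorentzian admixture (intended for WAXS
#' chain peaks).  Integrated areas come analytically from the fitted
#' parameters.  Candidates whose fit fails or returns a non-finite or
#' non-positive height are dropped with a message, never silently kept.
#'
#' @param profile a [scattering_profile()].
#' @param baseline matching [estimate_baseline()] result.
#' @param candidates data frame from [detect_peaks()] (non-empty).
#' @param window_halfwidth_fwhm half-width of the fit window in units of
#'   the estimated peak fwhm.
#' @param shape `"gaussian"` or `"pseudo-voigt"`.
#' @return object of class `peak_table`: data frame with `q0`, `height`,
#'   `sigma`, `fwhm`, `area`, standard errors `q0_se`, `area_se`, `shape`
#'   and `miller_label` (NA until assigned).
#' @export
fit_peaks <- function(profile, baseline, candidates,
                      window_halfwidth_fwhm = 2.5,
                      shape = c("gaussian", "pseudo-voigt")) {
  shape <- match.arg(shape)
  stopifnot(inherits(profile, "scattering_profile"),
            inherits(baseline, "baseline"))
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("no candidate peaks to fit")
  y <- profile$intensity - baseline$y
  y[is.na(y)] <- 0
  q <- profile$q
  dq <- stats::median(diff(q))
  n <- length(q)

  # window per candidate from half-max crossings
  wins <- lapply(seq_len(nrow(candidates)), function(k) {
    i0 <- candidates$bin[k]; h <- y[i0]
    l <- i0; while (l > 1L && y[l] > h / 2) l <- l - 1L
    r <- i0; while (r < n && y[r] > h / 2) r <- r + 1L
    hw <- max(as.integer(ceiling(window_halfwidth_fwhm * (r - l))), 4L)
    c(max(1L, i0 - hw), min(n, i0 + hw))
  })

  # group windows whose overlap exceeds 25% of the narrower window
  groups <- list(); g <- 1L
  assign_g <- integer(nrow(candidates))
  assign_g[1] <- 1L
  if (nrow(candidates) > 1L) {
    for (k in 2L:nrow(candidates)) {
      prev <- wins[[k - 1L]]; cur <- wins[[k]]
      ov <- max(0L, min(prev[2], cur[2]) - max(prev[1], cur[1]) + 1L)
      narrower <- min(prev[2] - prev[1], cur[2] - cur[1]) + 1L
      assign_g[k] <- if (ov > 0.25 * narrower) assign_g[k - 1L] else
        (g <- g + 1L)
    }
  }

  rows <- list(); dropped <- integer(0)
  for (gi in unique(assign_g)) {
    members <- which(assign_g == gi)
    lo <- min(vapply(wins[members], `[`, integer(1), 1L))
    hi <- max(vapply(wins[members], `[`, integer(1), 2L))
    sel <- lo:hi
    fit <- try(fit_peak_group(q[sel], y[sel],
                              candidates[members, , drop = FALSE],
                              dq, shape),
               silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit)) {
      message(sprintf("peak fit failed near q = %s; candidate(s) dropped",
                      paste(signif(candidates$q[members], 4),
                            collapse = ", ")))
      dropped <- c(dropped, members)
      next
    }
    rows <- c(rows, list(fit))
  }
  if (length(rows) == 0L)
    stop("all peak fits failed")
  out <- do.call(rbind, rows)
  out <- out[is.finite(out$q0) & out$height > 0 & out$sigma > 0, ,
             drop = FALSE]
  out <- out[order(out$q0), , drop = FALSE]
  out$fwhm <- 2 * sqrt(2 * log(2)) * out$sigma
  out$shape <- shape
  out$miller_label <- NA_character_
  rownames(out) <- NULL
  structure(out, class = c("peak_table", "data.frame"),
            dropped = dropped)
}

# Joint NLS fit of one or more peaks on a window; returns a data frame.
fit_peak_group <- function(qw, yw, cand, dq, shape) {
  m <- nrow(cand)
  start <- list(); lower <- c(); upper <- c()
  for (j in seq_len(m)) {
    start[[paste0("h", j)]] <- max(cand$height[j], 1e-6)
    start[[paste0("c", j)]] <- cand$q[j]
    start[[paste0("s", j)]] <- max(2 * dq, diff(range(qw)) / (8 * m))
    lower <- c(lower, 0, min(qw), dq / 2)
    upper <- c(upper, Inf, max(qw), diff(range(qw)))
  }
  if (shape == "pseudo-voigt") {
    start$eta <- 0.3; lower <- c(lower, 0); upper <- c(upper, 1)
  }
  model_fun <- function(par) {
    tot <- numeric(length(qw))
    for (j in seq_len(m)) {
      tot <- tot + if (shape == "gaussian")
        gauss_shape(qw, par[[paste0("h", j)]], par[[paste0("c", j)]],
                    par[[paste0("s", j)]])
      else
        pvoigt_shape(qw, par[[paste0("h", j)]], par[[paste0("c", j)]],
                     par[[paste0("s", j)]], par[["eta"]])
    }
    tot
  }
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(par) yw - model_fun(par),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0) stop("nls.lm: improper input")
  est <- fit$par
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(unlist(start))))
  names(se) <- names(unlist(start))
  eta <- if (shape == "pseudo-voigt") est$eta else NA_real_
  do.call(rbind, lapply(seq_len(m), function(j) {
    h <- est[[paste0("h", j)]]; c0 <- est[[paste0("c", j)]]
    s <- est[[paste0("s", j)]]
    area <- if (shape == "gaussian") gauss_area(h, s)
            else pvoigt_area(h, s, eta)
    h_se <- se[paste0("h", j)]; s_se <- se[paste0("s", j)]
    area_se <- if (is.finite(h_se) && is.finite(s_se))
      area * sqrt((h_se / h)^2 + (s_se / s)^2) else NA_real_
    data.frame(q0 = c0, height = h, sigma = s,
               q0_se = unname(se[paste0("c", j)]),
               area = area, area_se = unname(area_se))
  }))
}

#' Label WAXS chain-packing reflections
#'
#' For a tilted-chain gel phase the two wide-angle reflections are, by
#' convention, (2,0) at lower q and (1,1) at higher q.
#'
#' @param peaks a `peak_table`.
#' @param window q window (inverse Angstrom) considered chain-packing.
#' @export
label_waxs_peaks <- function(peaks, window = c(1.4, 1.7)) {
  stopifnot(inherits(peaks, "peak_table"))
  inw <- which(peaks$q0 >= window[1] & peaks$q0 <= window[2])
  if (length(inw) >= 1) peaks$miller_label[inw[1]] <- "d_20"
  if (length(inw) >= 2) peaks$miller_label[inw[2]] <- "d_11"
  peaks
}

#' @export
print.peak_table <- function(x, digits = 4, ...) {
  cat(sprintf("<peak_table> %d peak(s), shape %s\n", nrow(x),
              x$shape[1] %||% "?"))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
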