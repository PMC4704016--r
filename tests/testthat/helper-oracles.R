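# Independent oracles and fixture builders used across the suite.

# Numerical quadrature of the cosine transform of a Gaussian-sum model:
# integral of rho(z) cos(q z) dz on a fine grid (q in nm^-1).
quadrature_form_factor <- function(components, q_nm) {
  zmax <- max(abs(components$z)) + 8 * max(components$sigma)
  vapply(q_nm, function(qq) {
    f <- function(z) {
      rho <- rep(0, length(z))
      for (i in seq_len(nrow(components)))
        rho <- rho + components$sign[i] * components$A[i] *
          exp(-(z - components$z[i])^2 / (2 * components$sigma[i]^2))
      rho * cos(qq * z)
    }
    stats::integrate(f, -zmax, zmax, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }, numeric(1))
}

# Random mirror-symmetric Gaussian bilayer model (pair + optional centre
# trough), for form-factor and EDP property tests.
random_symmetric_model <- function() {
  d <- runif(1, 4.5, 8)
  zh <- runif(1, 0.25, 0.42) * d
  comps <- data.frame(z = c(zh, -zh, 0),
                      sigma = c(rep(runif(1, 0.15, 0.5), 2),
                                runif(1, 0.15, 0.5)),
                      A = c(rep(runif(1, 0.5, 1.5), 2),
                            runif(1, 0.3, 1.2)),
                      sign = c(1, 1, -1))
  bilayer_edp_model(comps, d = d)
}

# Random gel phantom drawn from the generator's realistic family, used by
# the EDP parameter-recovery harness.
random_gel_phantom <- function() {
  d <- runif(1, 4.8, 5.2)
  list(d = d,
       model = gel_bilayer_model(
         d, dpp_frac = runif(1, 0.67, 0.70),
         sigma_head = runif(1, 0.23, 0.28),
         sigma_methyl = runif(1, 0.22, 0.28),
         methyl_amp = runif(1, 0.9, 1.1)))
}

# Exact Fourier amplitudes (and true signs) of a bilayer model at its
# first n lamellar orders.
exact_amplitudes <- function(model, n) {
  qh <- d_to_q(model$d) * seq_len(n)
  Fh <- analytic_form_factor(model, qh)
  list(amps = fourier_amplitudes(Fh^2 / seq_len(n)^2, model$d),
       signs = ifelse(Fh >= 0, 1, -1))
}

# ---- set-partition indexing oracle -------------------------------------

# All set partitions of 1..n (Bell(6) = 203, fine for n <= 6).
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p))
      out <- c(out, list({ q <- p; q[[b]] <- c(q[[b]], n); q }))
    out <- c(out, list(c(p, list(n))))
  }
  out
}

# Is a block of peak positions a self-consistent lamellar series?
# Returns the RMS relative residual, or NA.  Mirrors the contract of the
# implementation: a series must contain its observed first order.
block_series_rms <- function(qs, rel_tol, max_order) {
  if (length(qs) == 1L) return(0)
  for (h0 in 1:3) {
    q1c <- min(qs) / h0
    h <- round(qs / q1c)
    if (!any(h == 1)) next
    if (any(h < 1) || any(h > max_order) || anyDuplicated(h)) next
    q1 <- sum(h * qs) / sum(h^2)
    rel <- abs(qs - h * q1) / (h * q1)
    if (all(rel <= rel_tol)) return(sqrt(mean(rel^2)))
  }
  NA_real_
}

# Exhaustive best-partition indexing: maximize peaks covered by
# multi-order series, then fewest series, then smallest total RMS.
# Returns the multi-order blocks as a set of sorted index vectors.
oracle_group <- function(q0, rel_tol = 0.015, max_order = 6L) {
  best <- NULL
  for (p in set_partitions(length(q0))) {
    rms <- vapply(p, function(idx) block_series_rms(q0[idx], rel_tol,
                                                    max_order),
                  numeric(1))
    if (anyNA(rms)) next
    multi <- lengths(p) >= 2L
    score <- c(sum(lengths(p)[multi]), -sum(multi), -sum(rms[multi]))
    if (is.null(best) || isTRUE(compare_lex(score, best$score) > 0))
      best <- list(score = score, blocks = p[multi])
  }
  canonical_blocks(best$blocks)
}

compare_lex <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(1)
    if (a[i] < b[i]) return(-1)
  }
  0
}

canonical_blocks <- function(blocks) {
  blocks <- lapply(blocks, function(b) as.integer(unname(sort(b))))
  unname(blocks[order(vapply(blocks, `[`, integer(1), 1L))])
}

# Random indexing test case: 1-2 clean lamellar series (+ optional
# orphan), peaks sorted ascending, with the true multi-order memberships.
random_index_case <- function(rel_tol = 0.015, max_order = 6L) {
  repeat {
    n_series <- sample(1:2, 1)
    d1 <- runif(1, 4, 8)
    ds <- d1
    if (n_series == 2) ds <- c(d1, d1 * runif(1, 1.3, 1.6))
    qs <- list()
    for (d in ds) {
      k <- sample(2:3, 1)
      q1 <- d_to_q(d)
      qs <- c(qs, list(q1 * seq_len(k) * (1 + runif(k, -0.003, 0.003))))
    }
    if (runif(1) < 0.3) qs <- c(qs, list(runif(1, 0.05, 0.44)))
    flat <- unlist(qs)
    memb <- rep(seq_along(qs), lengths(qs))
    # reject ambiguous geometries: any cross-series pair near an integer
    # ratio could legitimately index either way
    ok <- TRUE
    for (i in seq_along(flat)) for (j in seq_along(flat)) {
      if (memb[i] == memb[j] || flat[i] <= flat[j]) next
      r <- flat[i] / flat[j]
      if (abs(r - round(r)) < 4 * rel_tol * round(r)) ok <- FALSE
    }
    if (!ok) next
    if (min(abs(diff(sort(flat)))) < 0.01) next
    o <- order(flat)
    truth <- split(seq_along(flat), memb[o])
    truth <- truth[vapply(truth, length, integer(1)) >= 2L]
    return(list(q0 = flat[o], truth = canonical_blocks(truth)))
  }
}

# Per-pixel brute-force azimuthal integration oracle (double loop).
pixel_loop_integrate <- function(image, n_bins, q_range = NULL) {
  geom <- image$geometry
  n <- geom$image_size
  qs <- numeric(0); cs <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r_m <- sqrt((i - geom$beam_center[1])^2 +
                (j - geom$beam_center[2])^2) * geom$pixel_mm / 1000
    th <- atan(r_m / geom$distance_m)
    qs <- c(qs, (4 * pi / geom$wavelength) * sin(th / 2))
    cs <- c(cs, image$counts[i, j])
  }
  if (is.null(q_range)) {
    q_range <- range(qs)
    q_range[2] <- q_range[2] * (1 + 1e-9) + 1e-12
  }
  edges <- seq(q_range[1], q_range[2], length.out = n_bins + 1)
  means <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    inb <- qs >= edges[k] & qs < edges[k + 1]
    if (any(inb)) means[k] <- mean(cs[inb])
  }
  list(centers = (edges[-1] + edges[-(n_bins + 1)]) / 2, means = means)
}

# Small synthetic gel / fluid profiles shared across tests.
make_gel_profile <- function(d = 4.99, seed = 42, phi = 1) {
  synthesize_profile(
    list(list(edp = gel_bilayer_model(d), stack = gel_stack(d, phi = phi))),
    instrument = instrument_config("SAXS", seed = seed),
    meta = sample_meta(0.1, 20))
}

make_fluid_profile <- function(d = 7.00, seed = 43, phi = 1) {
  synthesize_profile(
    list(list(edp = fluid_bilayer_model(d),
              stack = fluid_stack(d, phi = phi))),
    instrument = instrument_config("SAXS", seed = seed),
    meta = sample_meta(0.1, 40))
}
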