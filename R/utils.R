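# Unit conventions used throughout:
#   q  : scattering vector in inverse Angstrom (profile axis)
#   d  : lamellar repeat distance in nm
#   z  : bilayer-normal coordinate in nm
# 1 A^-1 == 10 nm^-1, so d[nm] = 2*pi / (10 * q[A^-1]).

#' Convert a scattering vector to a real-space spacing
#'
#' A Bragg reflection at scattering vector \eqn{q} corresponds to a
#' real-space periodicity \eqn{d = 2\pi/q}.
#'
#' @param q scattering vector(s), inverse Angstrom.
#' @return spacing in nm.
#' @export
q_to_d <- function(q) {
  stopifnot(is.numeric(q), all(q > 0))
  2 * pi / (10 * q)
}

#' @rdname q_to_d
#' @param d spacing in nm.
#' @return `d_to_q()`: scattering vector in inverse Angstrom.
#' @export
d_to_q <- function(d) {
  stopifnot(is.numeric(d), all(d > 0))
  2 * pi / (10 * d)
}

# Evaluate code with a fixed RNG seed without disturbing the caller's
# random-number stream.  NULL seed runs the code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from one master seed (keeps values well
# inside 32-bit integer range).
child_seeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2000000011L
}

#' Construct sample metadata
#'
#' @param dha_molpercent guest-lipid content, mol\% (>= 0).
#' @param temperature sample temperature, degrees Celsius.
#' @param label free-text sample label.
#' @export
sample_meta <- function(dha_molpercent = 0, temperature = 20, label = "") {
  stopifnot(is.numeric(dha_molpercent), dha_molpercent >= 0,
            is.numeric(temperature))
  structure(list(dha_molpercent = dha_molpercent,
                 temperature = temperature,
                 label = as.character(label)),
            class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("sample: %s  (%.3g mol%%, %.1f degC)\n",
              if (nzchar(x$label)) x$label else "<unlabelled>",
              x$dha_molpercent, x$temperature))
  invisible(x)
}

# Local quadratic (three-point) refinement of an extremum position on a
# uniform grid; returns the refined x.  Falls back to x[i] at the edges.
quad_refine <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(x[i])
  y3 <- y[(i - 1L):(i + 1L)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (denom == 0) return(x[i])
  off <- (y3[1] - y3[3]) / (2 * denom)
  x[i] + off * (x[2] - x[1])
}
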