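# Text and image I/O: two-column profile files with commented metadata
# headers, ground-truth and phase-diagram CSVs, EDP CSV + JSON sidecar,
# 16-bit TIFF powder images.

#' Write / read a 1D profile as two-column text
#'
#' Format: comment lines starting with `#` carrying metadata
#' (`# key: value`), then whitespace-delimited columns q (inverse
#' Angstrom) and intensity (counts), plus an optional third uncertainty
#' column.
#'
#' @param profile a [scattering_profile()].
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "scattering_profile"))
  hdr <- c(sprintf("# mode: %s", profile$mode),
           sprintf("# label: %s", profile$meta$label),
           sprintf("# dha_molpercent: %.6g", profile$meta$dha_molpercent),
           sprintf("# temperature_C: %.6g", profile$meta$temperature),
           "# columns: q_invA intensity_counts uncertainty_counts")
  mat <- cbind(profile$q, profile$intensity,
               if (!is.null(profile$uncertainty)) profile$uncertainty)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(mat, digits = 10, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = "") {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  meta <- sample_meta(
    dha_molpercent = as.numeric(get("dha_molpercent", "0")),
    temperature = as.numeric(get("temperature_C", "20")),
    label = get("label"))
  mode <- get("mode", "SAXS")
  scattering_profile(dat[[1]], dat[[2]],
                     uncertainty = if (ncol(dat) >= 3) dat[[3]],
                     meta = meta, mode = mode)
}

#' Write the ground-truth table of a synthetic phase grid
#'
#' CSV columns: composition, temperature, state, ripple_flag, d_gel,
#' d_fluid.
#'
#' @param grid a `phase_grid`.
#' @param path file path.
#' @export
write_truth_csv <- function(grid, path) {
  stopifnot(inherits(grid, "phase_grid"))
  utils::write.csv(grid$truth, path, row.names = FALSE)
  invisible(path)
}

#' Write a phase diagram as CSV
#'
#' @param diagram a `phase_diagram`.
#' @param path file path.
#' @export
write_phase_diagram_csv <- function(diagram, path) {
  stopifnot(inherits(diagram, "phase_diagram"))
  utils::write.csv(diagram$table, path, row.names = FALSE)
  invisible(path)
}

#' Export an EDP as CSV plus JSON sidecar
#'
#' The CSV holds the (z, rho) curve; the sidecar
#' (`<path without extension>.json`) records d, d_pp_raw,
#' correction_factor, d_pp, d_w, the sign vector and the order count.
#'
#' @param edp an `edp_profile`.
#' @param path CSV path.
#' @export
write_edp <- function(edp, path) {
  stopifnot(inherits(edp, "edp_profile"))
  utils::write.csv(data.frame(z_nm = edp$z, rho = edp$rho), path,
                   row.names = FALSE)
  side <- sub("\\.[^.]+$", "", path)
  jsonlite::write_json(
    list(d_nm = edp$d, d_pp_raw_nm = edp$d_pp_raw,
         correction_factor = edp$correction_factor,
         d_pp_nm = edp$d_pp, d_w_nm = edp$d_w,
         signs = edp$signs, n_orders = edp$n_orders),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a powder image as 16-bit grayscale TIFF
#'
#' Counts above 65535 are clipped on write (with a warning).
#'
#' @param image a `powder_image`.
#' @param path TIFF path.
#' @export
write_powder_tiff <- function(image, path) {
  stopifnot(inherits(image, "powder_image"))
  counts <- image$counts
  if (any(counts > 65535)) {
    warning("counts exceed 16-bit range; clipping")
    counts <- pmin(counts, 65535)
  }
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_powder_tiff
#' @param instrument the [instrument_config()] describing the geometry of
#'   the stored image.
#' @export
read_powder_tiff <- function(path, instrument) {
  arr <- tiff::readTIFF(path)
  counts <- round(arr * 65535)
  structure(list(counts = counts, geometry = instrument),
            class = "powder_image")
}
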