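#' Canonical 1-nm wavelength grid
#'
#' The common grid every transform assumes: 350 to 2500 nm in 1 nm steps
#' (2151 bands), the full range of a field spectroradiometer. Band positions
#' reported by the screening step (e.g. 683 nm, 1283 nm) refer to this grid.
#'
#' @return Integer-valued numeric vector of length 2151.
#' @export
#' @examples
#' length(canonical_grid())
canonical_grid <- function() seq(350, 2500, by = 1)

#' Instrument-style sampling grid
#'
#' Emulates the native sampling of an ASD FieldSpec-style instrument:
#' 1.3 nm intervals below 1000 nm and 2 nm intervals above. Useful for
#' exercising [resample_to_grid()].
#'
#' @return Numeric vector of wavelengths (nm), strictly increasing.
#' @export
#' @examples
#' head(diff(asd_grid()))
asd_grid <- function() {
  lo <- seq(350, 1000, by = 1.3)
  hi <- seq(1000 + 2, 2500, by = 2)
  c(lo, hi)
}

# TRUE if wavelengths are (numerically) evenly spaced
.is_uniform <- function(wl, tol = 1e-8) {
  d <- diff(wl)
  length(d) > 0 && all(abs(d - d[1]) < tol)
}

# first inversion position in a wavelength vector, NULL if strictly increasing
.first_inversion <- function(wl) {
  bad <- which(diff(wl) <= 0)
  if (length(bad) == 0) return(NULL)
  bad[1]
}

.check_increasing <- function(wl, what = "wavelength_nm") {
  i <- .first_inversion(wl)
  if (!is.null(i)) {
    abort(sprintf(
      "%s not strictly increasing: first inversion at %g nm -> %g nm (position %d)",
      what, wl[i], wl[i + 1], i
    ))
  }
  invisible(wl)
}

# validate a long spectra tibble: plot_id, stage, wavelength_nm, <value col>
.check_spectra <- function(spectra, value = NULL) {
  stopifnot(is.data.frame(spectra))
  need <- c("plot_id", "stage", "wavelength_nm")
  miss <- setdiff(need, names(spectra))
  if (length(miss)) {
    abort(paste0("spectra is missing column(s): ", paste(miss, collapse = ", ")))
  }
  value <- value %||% .value_col(spectra)
  bad_stage <- setdiff(unique(spectra$stage), .stages)
  if (length(bad_stage)) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  if (!all(is.finite(spectra[[value]]))) {
    abort(sprintf("non-finite values in column '%s'", value))
  }
  invisible(value)
}

# which column carries the spectral measure
.value_col <- function(spectra) {
  cand <- intersect(c("reflectance", "derivative", "removed", "coefficient"),
                    names(spectra))
  if (length(cand) == 0) {
    abort("no value column found (expected one of reflectance, derivative, removed, coefficient)")
  }
  cand[1]
}

# split long spectra into a bands x plots matrix per (stage, grid); assumes
# every plot within a stage shares one grid (checked)
.spectra_matrix <- function(spectra, value = NULL) {
  value <- value %||% .value_col(spectra)
  plots <- unique(spectra$plot_id)
  wl <- sort(unique(spectra$wavelength_nm))
  n_wl <- length(wl)
  m <- matrix(NA_real_, nrow = n_wl, ncol = length(plots),
              dimnames = list(NULL, plots))
  idx_w <- match(spectra$wavelength_nm, wl)
  idx_p <- match(spectra$plot_id, plots)
  m[cbind(idx_w, idx_p)] <- spectra[[value]]
  if (anyNA(m)) abort("plots do not share a common wavelength grid")
  list(wavelength_nm = wl, values = m)
}

# apply f(wavelengths, values) -> values per plot-stage curve, keeping shape
.map_curves <- function(spectra, value, f) {
  spectra %>%
    group_by(.data$plot_id, .data$stage) %>%
    group_split() %>%
    purrr::map(function(grp) {
      .check_increasing(grp$wavelength_nm)
      grp[[value]] <- f(grp$wavelength_nm, grp[[value]])
      grp
    }) %>%
    bind_rows()
}

# inverse of .spectra_matrix for one stage
.matrix_spectra <- function(wl, m, stage, value = "reflectance") {
  plots <- colnames(m)
  out <- tibble(
    plot_id = rep(plots, each = length(wl)),
    stage = stage,
    wavelength_nm = rep(wl, times = length(plots))
  )
  out[[value]] <- as.vector(m)
  out
}
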