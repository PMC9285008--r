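#' Read canopy reflectance spectra from CSV
#'
#' Two dialects are supported. `"wide"`: first column `wavelength_nm`, one
#' column per plot; all plots share the file's grid and belong to one growth
#' stage (given by `stage`). `"long"`: columns
#' `plot_id, stage, wavelength_nm, reflectance`, possibly covering several
#' stages.
#'
#' Readers never reorder or drop plots: plot order follows first appearance
#' in the file. Non-monotone wavelength grids, duplicated plot columns and
#' non-numeric cells are errors.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param stage Growth stage of the file (wide dialect only); one of
#'   [growth_stages()].
#' @return A tibble with columns `plot_id`, `stage`, `wavelength_nm`,
#'   `reflectance`.
#' @seealso [write_spectra()], [resample_to_grid()]
#' @export
read_spectra <- function(path, dialect = c("wide", "long"), stage = NULL) {
  dialect <- arg_match(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  if (dialect == "wide") {
    if (names(raw)[1] != "wavelength_nm") {
      abort("wide spectra CSV must have 'wavelength_nm' as its first column")
    }
    if (is.null(stage)) abort("`stage` is required for the wide dialect")
    stage <- arg_match(stage, .stages)
    plots <- names(raw)[-1]
    if (anyDuplicated(plots)) {
      abort(paste0("duplicate plot_id column(s): ",
                   paste(unique(plots[duplicated(plots)]), collapse = ", ")))
    }
    num <- purrr::imap(raw, function(col, nm) .parse_numeric(col, nm, path))
    wl <- num[["wavelength_nm"]]
    .check_increasing(wl)
    tidyr::pivot_longer(
      tibble::as_tibble(num),
      cols = -"wavelength_nm",
      names_to = "plot_id", values_to = "reflectance"
    ) %>%
      mutate(stage = stage, plot_id = factor(.data$plot_id, levels = plots)) %>%
      arrange(.data$plot_id, .data$wavelength_nm) %>%
      mutate(plot_id = as.character(.data$plot_id)) %>%
      select("plot_id", "stage", "wavelength_nm", "reflectance")
  } else {
    need <- c("plot_id", "stage", "wavelength_nm", "reflectance")
    miss <- setdiff(need, names(raw))
    if (length(miss)) abort(paste0("long spectra CSV missing column(s): ",
                                   paste(miss, collapse = ", ")))
    out <- tibble(
      plot_id = raw$plot_id,
      stage = raw$stage,
      wavelength_nm = .parse_numeric(raw$wavelength_nm, "wavelength_nm", path),
      reflectance = .parse_numeric(raw$reflectance, "reflectance", path)
    )
    dup <- out %>%
      dplyr::count(.data$plot_id, .data$stage, .data$wavelength_nm) %>%
      filter(n > 1)
    if (nrow(dup)) {
      abort(sprintf("duplicate plot_id '%s' at stage '%s' (wavelength %g nm)",
                    dup$plot_id[1], dup$stage[1], dup$wavelength_nm[1]))
    }
    for (grp in split(out, paste(out$plot_id, out$stage))) {
      .check_increasing(grp$wavelength_nm,
                        sprintf("wavelength_nm for plot '%s'", grp$plot_id[1]))
    }
    .check_spectra(out)
    out
  }
}

# parse a character column to numeric, pointing at the first offending row
.parse_numeric <- function(col, nm, path) {
  x <- suppressWarnings(as.numeric(col))
  bad <- which(is.na(x) & !is.na(col))
  if (length(bad)) {
    abort(sprintf("non-numeric value '%s' in column '%s' of %s (data row %d)",
                  col[bad[1]], nm, path, bad[1]))
  }
  if (anyNA(x)) {
    abort(sprintf("missing value in column '%s' of %s (data row %d)",
                  nm, path, which(is.na(x))[1]))
  }
  x
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]; round trips are lossless (readr writes the
#' shortest decimal representation that restores the double exactly).
#'
#' @param spectra Long spectra tibble (`plot_id`, `stage`, `wavelength_nm`,
#'   `reflectance`).
#' @param path Output CSV path.
#' @param dialect `"wide"` (single stage only) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, dialect = c("wide", "long")) {
  dialect <- arg_match(dialect)
  .check_spectra(spectra)
  if (dialect == "wide") {
    if (length(unique(spectra$stage)) != 1) {
      abort("wide dialect can only hold one stage; use dialect = 'long'")
    }
    plots <- unique(spectra$plot_id)
    wide <- tidyr::pivot_wider(
      spectra %>% select("plot_id", "wavelength_nm", "reflectance"),
      names_from = "plot_id", values_from = "reflectance"
    ) %>%
      arrange(.data$wavelength_nm) %>%
      select("wavelength_nm", all_of(plots))
    readr::write_csv(wide, path, progress = FALSE)
  } else {
    readr::write_csv(spectra, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a plot yield table from CSV
#'
#' Expects columns `plot_id,yield_g_per_m2`. Duplicated plot ids and
#' non-positive yields are rejected; plots missing from a later join are an
#' error at join time, not here.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `plot_id` (character) and `yield_g_per_m2`.
#' @export
read_yields <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("plot_id", "yield_g_per_m2")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste0("yield CSV missing column(s): ",
                                 paste(miss, collapse = ", ")))
  out <- tibble(
    plot_id = raw$plot_id,
    yield_g_per_m2 = .parse_numeric(raw$yield_g_per_m2, "yield_g_per_m2", path)
  )
  .check_yields(out)
  out
}

.check_yields <- function(yields) {
  stopifnot(is.data.frame(yields))
  miss <- setdiff(c("plot_id", "yield_g_per_m2"), names(yields))
  if (length(miss)) abort(paste0("yield table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(yields$plot_id)) {
    abort(sprintf("duplicate plot_id '%s' in yield table",
                  yields$plot_id[duplicated(yields$plot_id)][1]))
  }
  if (any(!is.finite(yields$yield_g_per_m2)) || any(yields$yield_g_per_m2 <= 0)) {
    abort("yields must be finite and > 0")
  }
  invisible(yields)
}

#' Write a yield table to CSV
#'
#' @param yields Tibble with `plot_id`, `yield_g_per_m2`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_yields <- function(yields, path) {
  .check_yields(yields)
  readr::write_csv(yields, path, progress = FALSE)
  invisible(path)
}

#' Resample spectra onto a new wavelength grid
#'
#' Linear interpolation onto `grid`; values at wavelengths shared with the
#' source grid are returned unchanged. Extrapolation is never performed —
#' a grid point outside the source range is an error, because silently
#' extrapolated edges corrupt edge-parameter features.
#'
#' @param spectra Long spectra tibble.
#' @param grid Target wavelengths (nm), strictly increasing, within the
#'   source range of every spectrum. Defaults to [canonical_grid()].
#' @return Spectra tibble on `grid`.
#' @export
#' @examples
#' s <- tibble::tibble(plot_id = "p1", stage = "heading",
#'                     wavelength_nm = asd_grid(),
#'                     reflectance = 0.2 + 1e-4 * (asd_grid() - 350))
#' resample_to_grid(s, canonical_grid())
resample_to_grid <- function(spectra, grid = canonical_grid()) {
  value <- .check_spectra(spectra)
  .check_increasing(grid, "target grid")
  spectra %>%
    group_by(.data$plot_id, .data$stage) %>%
    group_split() %>%
    purrr::map(function(grp) {
      wl <- grp$wavelength_nm
      .check_increasing(wl, sprintf("wavelength_nm for plot '%s'", grp$plot_id[1]))
      if (min(grid) < min(wl) || max(grid) > max(wl)) {
        abort(sprintf(
          "target grid [%g, %g] nm outside source range [%g, %g] nm for plot '%s' (no extrapolation)",
          min(grid), max(grid), min(wl), max(wl), grp$plot_id[1]
        ))
      }
      out <- tibble(
        plot_id = grp$plot_id[1], stage = grp$stage[1], wavelength_nm = grid
      )
      out[[value]] <- approx(wl, grp[[value]], xout = grid, method = "linear",
                             ties = "ordered")$y
      shared <- match(wl, grid)
      keep <- !is.na(shared)
      out[[value]][shared[keep]] <- grp[[value]][keep]
      out
    }) %>%
    bind_rows()
}

#' Write a feature table to CSV
#'
#' Columns other than `plot_id` are sorted by name so two writes of the same
#' table are byte-identical.
#'
#' @param features Tibble with `plot_id` plus one numeric column per feature.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features), "plot_id" %in% names(features))
  cols <- sort(setdiff(names(features), "plot_id"))
  readr::write_csv(features %>% select("plot_id", all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_features()].
#' @return A tibble with `plot_id` plus numeric feature columns.
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plot_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' Write a model report to JSON
#'
#' Serialises a [stage_combination_grid()] report (or any tibble) to pretty
#' JSON with columns sorted by name, deterministically.
#'
#' @param report A data frame.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  first <- intersect(c("stage_combination", "transform", "algorithm"),
                     names(report))
  cols <- c(first, sort(setdiff(names(report), first)))
  jsonlite::write_json(as.data.frame(report[, cols, drop = FALSE]), path,
                       pretty = TRUE, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
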