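#' Vegetation indices from single red and NIR bands
#'
#' Computes NDVI, DVI, RVI and EVI from the reflectance at one red and one
#' near-infrared band per plot-stage:
#'
#' * `NDVI = (NIR - R) / (NIR + R)`
#' * `DVI  = NIR - R`
#' * `RVI  = R / NIR` (as defined in the source convention; set
#'   `rvi_inverted = TRUE` for the more common `NIR / R`)
#' * `EVI  = 2.5 (NIR - R) / (1 + NIR + 2.4 R)`
#'
#' A zero denominator yields `NA` with a message rather than an error.
#'
#' @param spectra Long spectra tibble containing both bands.
#' @param indices Subset of `c("NDVI", "DVI", "RVI", "EVI")`.
#' @param red_nm,nir_nm Band positions in nm (defaults 670 and 800).
#' @param rvi_inverted If `TRUE`, compute RVI as `NIR / R`.
#' @return Long tibble `plot_id`, `stage`, `index`, `value`.
#' @export
#' @examples
#' s <- tibble::tibble(plot_id = "p", stage = "heading",
#'                     wavelength_nm = c(670, 800), reflectance = c(0.1, 0.5))
#' vegetation_indices(s)
vegetation_indices <- function(spectra,
                               indices = c("NDVI", "DVI", "RVI", "EVI"),
                               red_nm = 670, nir_nm = 800,
                               rvi_inverted = FALSE) {
  value <- .check_spectra(spectra)
  indices <- match.arg(indices, c("NDVI", "DVI", "RVI", "EVI"),
                       several.ok = TRUE)
  bands <- spectra %>%
    filter(.data$wavelength_nm %in% c(red_nm, nir_nm)) %>%
    mutate(band = ifelse(.data$wavelength_nm == red_nm, "R", "NIR")) %>%
    select("plot_id", "stage", "band", value = all_of(value)) %>%
    tidyr::pivot_wider(names_from = "band", values_from = "value")
  if (!all(c("R", "NIR") %in% names(bands)) || anyNA(bands$R) || anyNA(bands$NIR)) {
    abort(sprintf("bands %g and %g nm must both be on the grid", red_nm, nir_nm))
  }
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) inform(sprintf("%s: zero denominator for %d plot(s); value set to NA",
                                 what, sum(bad)))
    ifelse(bad, NA_real_, num / den)
  }
  out <- purrr::map(indices, function(ix) {
    v <- switch(ix,
      NDVI = safe_div(bands$NIR - bands$R, bands$NIR + bands$R, "NDVI"),
      DVI  = bands$NIR - bands$R,
      RVI  = if (rvi_inverted) safe_div(bands$NIR, bands$R, "RVI")
             else safe_div(bands$R, bands$NIR, "RVI"),
      EVI  = 2.5 * (bands$NIR - bands$R) / (1 + bands$NIR + 2.4 * bands$R)
    )
    tibble(plot_id = bands$plot_id, stage = bands$stage, index = ix, value = v)
  })
  bind_rows(out)
}

#' Default red/blue/yellow edge windows
#'
#' Window bounds (nm) used by [tri_edge()]: red 680--760, blue 490--530,
#' yellow 560--640. These follow the tri-edge convention of the
#' agronomic-spectroscopy literature; the source analysis does not pin them,
#' so they are exposed here for override.
#'
#' @param red,blue,yellow Length-2 numeric `c(lo, hi)` in nm.
#' @return Named list of windows.
#' @export
edge_windows <- function(red = c(680, 760), blue = c(490, 530),
                         yellow = c(560, 640)) {
  w <- list(red = red, blue = blue, yellow = yellow)
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || diff(w[[nm]]) <= 0) {
      abort(sprintf("window '%s' must be c(lo, hi) with lo < hi", nm))
    }
  }
  w
}

#' Tri-edge parameters from a first-derivative spectrum
#'
#' For each of the red, blue and yellow edge windows, extracts:
#' `D` — the maximum of the first derivative in the window (the edge
#' "slope"; for the blue and yellow edges, where the derivative is usually
#' negative, this is still the maximum, by definition);
#' `lambda` — the wavelength of that maximum (smallest wavelength on ties);
#' `SD` — the trapezoidal integral of the first derivative over the window
#' (the edge "area", units of reflectance, telescoping to the reflectance
#' difference across the window for smooth spectra).
#'
#' @param fd Long first-derivative tibble from [first_derivative()]
#'   (value column `derivative`).
#' @param windows Edge windows, see [edge_windows()].
#' @return Tibble with one row per plot-stage and columns `lambda_r`, `D_r`,
#'   `SD_r`, `lambda_b`, `D_b`, `SD_b`, `lambda_y`, `D_y`, `SD_y`.
#' @export
tri_edge <- function(fd, windows = edge_windows()) {
  value <- .check_spectra(fd)
  fd %>%
    group_by(.data$plot_id, .data$stage) %>%
    group_split() %>%
    purrr::map(function(grp) {
      wl <- grp$wavelength_nm
      d <- grp[[value]]
      one <- function(win) {
        sel <- which(wl >= win[1] & wl <= win[2])
        if (length(sel) < 2 || wl[sel][1] > win[1] || tail(wl[sel], 1) < win[2]) {
          abort(sprintf("edge window [%g, %g] nm not covered by the grid",
                        win[1], win[2]))
        }
        ww <- wl[sel]; dd <- d[sel]
        i <- which.max(dd)                      # which.max takes first on ties
        sd_ <- sum(diff(ww) * (head(dd, -1) + tail(dd, -1)) / 2)
        c(lambda = ww[i], D = dd[i], SD = sd_)
      }
      r <- one(windows$red); b <- one(windows$blue); y <- one(windows$yellow)
      tibble(
        plot_id = grp$plot_id[1], stage = grp$stage[1],
        lambda_r = r[["lambda"]], D_r = r[["D"]], SD_r = r[["SD"]],
        lambda_b = b[["lambda"]], D_b = b[["D"]], SD_b = b[["SD"]],
        lambda_y = y[["lambda"]], D_y = y[["D"]], SD_y = y[["SD"]]
      )
    }) %>%
    bind_rows()
}

#' Derived edge-area combinations
#'
#' The eight differences, ratios and normalised differences of the edge
#' areas: `SD_r - SD_b`, `SD_r - SD_y`, `SD_b - SD_y`, `SD_r / SD_b`,
#' `SD_r / SD_y`, `SD_b / SD_y`, `(SD_r - SD_b) / (SD_r + SD_b)` and
#' `(SD_r - SD_y) / (SD_r + SD_y)`. Zero denominators give `NA`; the
#' difference forms stay defined.
#'
#' @param triedge Output of [tri_edge()].
#' @return `triedge` with eight additional columns (`SDr_minus_SDb`,
#'   `SDr_over_SDb`, `SDr_SDb_norm`, ...).
#' @export
edge_combinations <- function(triedge) {
  need <- c("SD_r", "SD_b", "SD_y")
  if (!all(need %in% names(triedge))) {
    abort("input must contain SD_r, SD_b, SD_y (see tri_edge())")
  }
  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  triedge %>%
    mutate(
      SDr_minus_SDb = .data$SD_r - .data$SD_b,
      SDr_minus_SDy = .data$SD_r - .data$SD_y,
      SDb_minus_SDy = .data$SD_b - .data$SD_y,
      SDr_over_SDb = ratio(.data$SD_r, .data$SD_b),
      SDr_over_SDy = ratio(.data$SD_r, .data$SD_y),
      SDb_over_SDy = ratio(.data$SD_b, .data$SD_y),
      SDr_SDb_norm = ratio(.data$SD_r - .data$SD_b, .data$SD_r + .data$SD_b),
      SDr_SDy_norm = ratio(.data$SD_r - .data$SD_y, .data$SD_r + .data$SD_y)
    )
}

#' Build a stage-tagged feature table
#'
#' Assembles one row per plot from raw multi-stage spectra: smooths
#' ([sg_smooth()]), derives ([first_derivative()]) and extracts the
#' requested feature groups per stage, tagging every column with its stage
#' (e.g. `heading_NDVI`, `heading_FD_1283`, `heading_CWT_s8_732`).
#'
#' Groups: `"VI"` — the four vegetation indices from the smoothed spectrum;
#' `"EDGE"` — the nine tri-edge parameters plus the eight
#' [edge_combinations()]; `"FD"` — first-derivative values at
#' `fd_bands`; `"CWT"` — wavelet coefficients at `cwt_cells` (columns
#' labelled by the base-2 log of the scale when the scale is dyadic).
#'
#' Plots missing any requested stage are dropped with a warning (they cannot
#' enter a fused model); duplicated band/cell requests are collapsed with a
#' warning.
#'
#' @param spectra Raw long spectra tibble covering the requested stages.
#' @param groups Subset of `c("VI", "EDGE", "FD", "CWT")`.
#' @param fd_bands Tibble `stage`, `wavelength_nm` of screened
#'   first-derivative bands (required for group `"FD"`).
#' @param cwt_cells Tibble `stage`, `scale`, `wavelength_nm` of screened
#'   wavelet cells (required for group `"CWT"`).
#' @param stages Stages to extract (default: those present in `spectra`).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param red_nm,nir_nm,rvi_inverted Vegetation-index settings.
#' @param windows Edge windows for `"EDGE"`.
#' @return Wide tibble `plot_id` + one numeric column per stage-tagged
#'   feature, columns sorted by name.
#' @export
build_feature_table <- function(spectra,
                                groups = c("VI", "FD", "CWT"),
                                fd_bands = NULL, cwt_cells = NULL,
                                stages = NULL,
                                sg_window = 11, sg_polyorder = 3,
                                red_nm = 670, nir_nm = 800,
                                rvi_inverted = FALSE,
                                windows = edge_windows()) {
  .check_spectra(spectra)
  groups <- match.arg(groups, c("VI", "EDGE", "FD", "CWT"), several.ok = TRUE)
  stages <- stages %||% intersect(.stages, unique(spectra$stage))
  spectra <- spectra %>% filter(.data$stage %in% stages)

  # plots must cover every requested stage
  cover <- spectra %>% distinct(.data$plot_id, .data$stage) %>%
    dplyr::count(.data$plot_id)
  incomplete <- cover$plot_id[cover$n < length(stages)]
  if (length(incomplete)) {
    warn(sprintf("dropping %d plot(s) missing one or more stages: %s",
                 length(incomplete), paste(incomplete, collapse = ", ")))
    spectra <- spectra %>% filter(!.data$plot_id %in% incomplete)
  }

  or <- sg_smooth(spectra, window = sg_window, polyorder = sg_polyorder)
  need_fd <- any(c("FD", "EDGE") %in% groups)
  fd <- if (need_fd) first_derivative(or) else NULL

  pieces <- list()
  if ("VI" %in% groups) {
    pieces$VI <- vegetation_indices(or, red_nm = red_nm, nir_nm = nir_nm,
                                    rvi_inverted = rvi_inverted) %>%
      mutate(feature = paste(.data$stage, .data$index, sep = "_")) %>%
      select("plot_id", "feature", "value")
  }
  if ("EDGE" %in% groups) {
    pieces$EDGE <- edge_combinations(tri_edge(fd, windows = windows)) %>%
      tidyr::pivot_longer(cols = -c("plot_id", "stage"),
                          names_to = "name", values_to = "value") %>%
      mutate(feature = paste(.data$stage, .data$name, sep = "_")) %>%
      select("plot_id", "feature", "value")
  }
  if ("FD" %in% groups) {
    if (is.null(fd_bands)) abort("group 'FD' requires `fd_bands`")
    fb <- fd_bands %>% distinct(.data$stage, .data$wavelength_nm)
    if (nrow(fb) < nrow(fd_bands)) warn("duplicate fd_bands collapsed")
    pieces$FD <- fd %>%
      inner_join(fb, by = c("stage", "wavelength_nm")) %>%
      mutate(feature = sprintf("%s_FD_%g", .data$stage, .data$wavelength_nm)) %>%
      select("plot_id", "feature", value = "derivative")
  }
  if ("CWT" %in% groups) {
    if (is.null(cwt_cells)) abort("group 'CWT' requires `cwt_cells`")
    cc <- cwt_cells %>% distinct(.data$stage, .data$scale, .data$wavelength_nm)
    if (nrow(cc) < nrow(cwt_cells)) warn("duplicate cwt_cells collapsed")
    pieces$CWT <- cwt_at_cells(or, cc) %>%
      mutate(feature = sprintf("%s_CWT_%s_%g", .data$stage,
                               .scale_label(.data$scale), .data$wavelength_nm)) %>%
      select("plot_id", "feature", "value" = "coefficient")
  }

  long <- bind_rows(pieces)
  if (nrow(long) == 0) {
    return(tibble(plot_id = unique(spectra$plot_id)))
  }
  wide <- tidyr::pivot_wider(long, names_from = "feature",
                             values_from = "value")
  wide %>% select("plot_id", all_of(sort(setdiff(names(wide), "plot_id"))))
}

# dyadic scales get the conventional exponent label (s8 = scale 2^8)
.scale_label <- function(scale) {
  e <- log2(scale)
  ifelse(abs(e - round(e)) < 1e-9, sprintf("s%d", as.integer(round(e))),
         sprintf("a%g", scale))
}
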