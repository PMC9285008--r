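#' Plot spectra curves
#'
#' Reflectance (or derivative, or continuum-removed) curves coloured by
#' stage, one thin line per plot.
#'
#' @param spectra Long spectra tibble.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, alpha = 0.3) {
  value <- .check_spectra(spectra)
  ggplot2::ggplot(spectra, ggplot2::aes(
    x = .data$wavelength_nm, y = .data[[value]],
    group = interaction(.data$plot_id, .data$stage), colour = .data$stage
  )) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = value, colour = "stage") +
    ggplot2::theme_minimal()
}

#' Plot a correlation map
#'
#' Band maps are drawn as |r| against wavelength per stage with the
#' significance threshold; wavelet maps as a scale x band heat map of |r|,
#' faceted by stage.
#'
#' @param object A `pw_corr` tibble.
#' @param alpha Significance level for the threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pw_corr <- function(object, alpha = 0.05, ...) {
  if (identical(attr(object, "axis"), "wavelet")) {
    ggplot2::ggplot(object, ggplot2::aes(
      x = .data$wavelength_nm, y = factor(log2(.data$scale)),
      fill = abs(.data$r)
    )) +
      ggplot2::geom_tile() +
      ggplot2::facet_wrap(~stage) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(x = "wavelength (nm)", y = "scale (log2)", fill = "|r|") +
      ggplot2::theme_minimal()
  } else {
    thr <- critical_r(max(object$n), alpha)
    ggplot2::ggplot(object, ggplot2::aes(
      x = .data$wavelength_nm, y = abs(.data$r), colour = .data$stage
    )) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
      ggplot2::labs(x = "wavelength (nm)", y = "|r| with yield") +
      ggplot2::theme_minimal()
  }
}

#' Plot continuum removal for one spectrum
#'
#' Overlays reflectance, its upper-hull continuum and hull vertices.
#'
#' @param object A `pw_continuum` tibble (one plot-stage is clearest).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pw_continuum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$reflectance,
                                    group = .data$plot_id), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$continuum,
                                    group = .data$plot_id),
                       colour = "steelblue") +
    ggplot2::geom_point(data = dplyr::filter(object, .data$is_hull),
                        ggplot2::aes(y = .data$reflectance),
                        colour = "steelblue", size = 0.8) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}

#' Plot a stage-combination report
#'
#' Validation-set R-squared per stage combination, coloured by transform
#' set and faceted by algorithm.
#'
#' @param object A `pw_report` tibble from [stage_combination_grid()].
#' @param metric Column prefix to display: `"val1"`, `"val2"` or `"train"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pw_report <- function(object, metric = "val1", ...) {
  col <- paste0(metric, "_r_squared")
  stopifnot(col %in% names(object))
  df <- tibble::as_tibble(object)
  df$stage_combination <- factor(df$stage_combination,
                                 levels = unique(df$stage_combination))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$stage_combination, y = .data[[col]], fill = .data$transform
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(x = NULL, y = bquote(R^2), fill = "features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Write the standard summary figures for a pipeline run
#'
#' Renders spectra, first-derivative band correlations, the wavelet
#' correlation heat map and the report bars as PNG files. Purely cosmetic;
#' safe on headless systems (the ragg/cairo device bundled with ggsave's
#' default png device is not required — `grDevices::png` is used).
#'
#' @param benchmark A `pw_benchmark`.
#' @param report A `pw_report`.
#' @param out_dir Directory for PNGs (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
plot_summaries <- function(benchmark, report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  or <- sg_smooth(benchmark$train$spectra)
  fd <- first_derivative(or)
  corr <- band_yield_correlation(fd, benchmark$train$yields)
  paths <- character(0)
  save_png <- function(name, plot) {
    p <- file.path(out_dir, name)
    grDevices::png(p, width = 1400, height = 900, res = 150)
    print(plot)
    grDevices::dev.off()
    paths <<- c(paths, p)
  }
  save_png("spectra_or.png", plot_spectra(or))
  save_png("fd_correlation.png", autoplot.pw_corr(corr))
  first_plot <- benchmark$train$spectra$plot_id[1]
  save_png("continuum.png", autoplot.pw_continuum(continuum_remove(
    or %>% filter(.data$plot_id == first_plot, .data$stage == "heading"))))
  save_png("report.png", autoplot.pw_report(report))
  invisible(paths)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
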