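#' Band-by-band correlation with yield
#'
#' Pearson correlation between the spectral value at each band and plot
#' yield, per stage, over the inner join of plots (no imputation). Bands
#' with zero variance get `NA` with a message.
#'
#' @param spectra Long spectra tibble (reflectance, derivative or removed
#'   value column).
#' @param yields Yield tibble (`plot_id`, `yield_g_per_m2`).
#' @return Tibble of class `pw_corr` with columns `stage`, `wavelength_nm`,
#'   `r`, `n`.
#' @export
band_yield_correlation <- function(spectra, yields) {
  value <- .check_spectra(spectra)
  .check_yields(yields)
  out <- spectra %>%
    inner_join(yields, by = "plot_id") %>%
    group_by(.data$stage, .data$wavelength_nm) %>%
    summarise(
      r = .safe_cor(.data[[value]], .data$yield_g_per_m2),
      n = dplyr::n(), .groups = "drop"
    )
  if (any(out$n < 3)) abort("need at least 3 joined plots per band")
  n_bad <- sum(is.na(out$r))
  if (n_bad > 0) inform(sprintf("%d band(s) with zero variance: r set to NA", n_bad))
  structure(out, class = c("pw_corr", class(out)), axis = "band")
}

.safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Scale x band wavelet-coefficient correlation with yield
#'
#' Pearson correlation between every wavelet cell (scale, band) and yield,
#' per stage — the correlation matrix used to locate yield-sensitive
#' regions of the wavelet plane.
#'
#' @param cwt Long tibble from [cwt_transform()].
#' @param yields Yield tibble.
#' @return Tibble of class `pw_corr` with columns `stage`, `scale`,
#'   `wavelength_nm`, `r`, `n`.
#' @export
wavelet_yield_correlation <- function(cwt, yields) {
  stopifnot(all(c("plot_id", "stage", "scale", "wavelength_nm", "coefficient")
                %in% names(cwt)))
  .check_yields(yields)
  out <- cwt %>%
    inner_join(yields, by = "plot_id") %>%
    group_by(.data$stage, .data$scale, .data$wavelength_nm) %>%
    summarise(
      r = .safe_cor(.data$coefficient, .data$yield_g_per_m2),
      n = dplyr::n(), .groups = "drop"
    )
  if (any(out$n < 3)) abort("need at least 3 joined plots per cell")
  n_bad <- sum(is.na(out$r))
  if (n_bad > 0) inform(sprintf("%d cell(s) with zero variance: r set to NA", n_bad))
  structure(out, class = c("pw_corr", class(out)), axis = "wavelet")
}

#' Two-tailed Pearson significance threshold
#'
#' The smallest |r| significant at level `alpha` for sample size `n`:
#' `r* = t* / sqrt(t*^2 + n - 2)` with `t*` the upper `alpha/2` quantile of
#' the t distribution on `n - 2` degrees of freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The critical |r|.
#' @export
#' @examples
#' critical_r(60)  # ~0.254
critical_r <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha <= 1)
  tstar <- qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Greedy selection of sensitive bands or cells
#'
#' Picks labels with `|r| >= r_min` in decreasing `|r|`, suppressing
#' neighbours within `min_separation_nm` at the same scale (adjacent bands
#' carry nearly identical information), up to `top_k` per stage. Ties are
#' broken by lower wavelength, then lower scale.
#'
#' @param map A `pw_corr` tibble from [band_yield_correlation()] or
#'   [wavelet_yield_correlation()].
#' @param r_min Minimum |r|; default `critical_r(n, alpha)` at the map's
#'   sample size.
#' @param top_k Maximum selections per stage (default 5).
#' @param min_separation_nm Suppression radius in nm (default 10).
#' @param alpha Significance level used for the default `r_min`.
#' @return Tibble of selected rows (`stage`, [`scale`,] `wavelength_nm`,
#'   `r`, `rank`), possibly empty.
#' @export
select_sensitive <- function(map, r_min = NULL, top_k = 5,
                             min_separation_nm = 10, alpha = 0.05) {
  stopifnot(top_k >= 1, min_separation_nm >= 0)
  has_scale <- "scale" %in% names(map)
  map %>%
    as_tibble() %>%
    filter(!is.na(.data$r)) %>%
    group_by(.data$stage) %>%
    group_split() %>%
    purrr::map(function(grp) {
      rmin <- r_min %||% critical_r(max(grp$n), alpha)
      cand <- grp %>%
        filter(abs(.data$r) >= rmin) %>%
        arrange(desc(abs(.data$r)), .data$wavelength_nm,
                if (has_scale) .data$scale else NULL)
      picked <- cand[0, ]
      while (nrow(cand) > 0 && nrow(picked) < top_k) {
        top <- cand[1, ]
        picked <- bind_rows(picked, top)
        same_scale <- if (has_scale) cand$scale == top$scale else TRUE
        cand <- cand[!(same_scale &
                       abs(cand$wavelength_nm - top$wavelength_nm) <= min_separation_nm), ]
      }
      if (nrow(picked)) picked$rank <- seq_len(nrow(picked))
      picked
    }) %>%
    bind_rows()
}
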