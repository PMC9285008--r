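#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of each spectrum, the standard
#' first step before derivative or wavelet analysis of field spectra. The
#' filter reproduces polynomials up to `polyorder` exactly (including at the
#' grid ends, where the fitted end frames are used).
#'
#' @param spectra Long spectra tibble on a uniform grid.
#' @param window Odd window length in samples (default 11).
#' @param polyorder Polynomial order, `< window` (default 3).
#' @return Smoothed spectra tibble (same shape and grid).
#' @export
sg_smooth <- function(spectra, window = 11, polyorder = 3) {
  value <- .check_spectra(spectra)
  if (window %% 2 != 1) abort("`window` must be odd")
  if (polyorder >= window) abort("`polyorder` must be < `window`")
  .map_curves(spectra, value, function(wl, x) {
    if (!.is_uniform(wl)) abort("sg_smooth requires a uniform wavelength grid")
    if (window >= length(x)) {
      abort(sprintf("window (%d) must be shorter than the spectrum (%d points)",
                    window, length(x)))
    }
    as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
  })
}

#' First-derivative transform
#'
#' Central differences in the interior, one-sided differences at the ends,
#' divided by the grid step, so units are reflectance per nm. Conventionally
#' applied after [sg_smooth()].
#'
#' @param spectra Long spectra tibble on a uniform grid (at least 3 points).
#' @return Tibble with the value column renamed `derivative`.
#' @export
first_derivative <- function(spectra) {
  value <- .check_spectra(spectra)
  out <- .map_curves(spectra, value, function(wl, x) {
    if (length(x) < 3) abort("first_derivative needs at least 3 points")
    if (!.is_uniform(wl)) abort("first_derivative requires a uniform wavelength grid")
    h <- wl[2] - wl[1]
    n <- length(x)
    d <- numeric(n)
    d[1] <- (x[2] - x[1]) / h
    d[n] <- (x[n] - x[n - 1]) / h
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
    d
  })
  names(out)[names(out) == value] <- "derivative"
  out
}

#' Continuum removal
#'
#' Fits the upper convex hull of each spectrum (the continuum), interpolates
#' it piecewise-linearly over the grid, and divides the spectrum by it:
#' `removed = reflectance / continuum`. Absorption features become wells
#' below 1; hull vertices sit exactly at 1. Grid endpoints are always hull
#' vertices.
#'
#' @param spectra Long spectra tibble with strictly positive reflectance.
#' @return A tibble of class `pw_continuum` with columns `plot_id`, `stage`,
#'   `wavelength_nm`, `reflectance`, `continuum`, `removed`, `is_hull`.
#' @export
continuum_remove <- function(spectra) {
  value <- .check_spectra(spectra)
  if (any(spectra[[value]] <= 0)) {
    abort("continuum removal requires strictly positive reflectance")
  }
  out <- spectra %>%
    group_by(.data$plot_id, .data$stage) %>%
    group_split() %>%
    purrr::map(function(grp) {
      wl <- grp$wavelength_nm
      .check_increasing(wl)
      r <- grp[[value]]
      hull <- .upper_hull(wl, r)
      cont <- approx(wl[hull], r[hull], xout = wl, method = "linear",
                     ties = "ordered")$y
      tibble(
        plot_id = grp$plot_id[1], stage = grp$stage[1], wavelength_nm = wl,
        reflectance = r, continuum = cont,
        removed = pmin(r / cont, 1),
        is_hull = seq_along(wl) %in% hull
      )
    }) %>%
    bind_rows()
  class(out) <- c("pw_continuum", class(out))
  out
}

# Andrew's monotone-chain upper hull; x strictly increasing.
# Returns indices of the hull vertices in increasing x order.
.upper_hull <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  h <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      # drop h[k] if it lies on or below segment h[k-1] -> i
      cr <- (x[h[k]] - x[h[k - 1L]]) * (y[i] - y[h[k - 1L]]) -
            (y[h[k]] - y[h[k - 1L]]) * (x[i] - x[h[k - 1L]])
      if (cr >= 0) k <- k - 1L else break
    }
    k <- k + 1L
    h[k] <- i
  }
  h[seq_len(k)]
}

#' Continuous wavelet transform of spectra
#'
#' Discretises the continuous wavelet transform
#' `W(a, b) = integral f(lambda) a^(-1/2) psi((lambda - b)/a) dlambda`
#' on the spectrum's uniform grid: for every scale `a` and band `b`, the sum
#' of `f * psi` over the grid times the grid step. The default mother
#' wavelet is the Mexican hat (negative second derivative of a Gaussian)
#' and the default scales are the ten dyadic scales 2^1 .. 2^10. Boundaries
#' are handled by symmetric (mirror, edge-repeated) extension of the
#' spectrum, which avoids edge ringing at the largest scales where the
#' wavelet support exceeds the 350--2500 nm range.
#'
#' Computation is exact FFT-based convolution of the extended signal with
#' the sampled wavelet (support truncated at |x| <= 8, where the Mexican
#' hat tail is below 1e-12 of its peak).
#'
#' @param spectra Long spectra tibble on a uniform grid.
#' @param scales Positive scale factors (default `2^(1:10)`).
#' @param wavelet Mother wavelet; only `"mexican_hat"` is available.
#' @return Long tibble `plot_id`, `stage`, `scale`, `wavelength_nm`,
#'   `coefficient`.
#' @export
#' @examples
#' s <- tibble::tibble(plot_id = "p", stage = "heading",
#'                     wavelength_nm = 400:600,
#'                     reflectance = exp(-((400:600) - 500)^2 / 800))
#' cw <- cwt_transform(s, scales = c(4, 8))
cwt_transform <- function(spectra, scales = 2^(1:10),
                          wavelet = "mexican_hat") {
  value <- .check_spectra(spectra)
  wavelet <- arg_match(wavelet, "mexican_hat")
  stopifnot(all(scales > 0))
  spectra %>%
    group_by(.data$stage) %>%
    group_split() %>%
    purrr::map(function(grp) {
      sm <- .spectra_matrix(grp, value)
      if (!.is_uniform(sm$wavelength_nm)) {
        abort("cwt_transform requires a uniform wavelength grid")
      }
      h <- sm$wavelength_nm[2] - sm$wavelength_nm[1]
      planes <- purrr::map(scales, function(a) {
        w <- .cwt_conv(sm$values, a, h)
        tibble(
          plot_id = rep(colnames(sm$values), each = length(sm$wavelength_nm)),
          stage = grp$stage[1],
          scale = a,
          wavelength_nm = rep(sm$wavelength_nm, times = ncol(sm$values)),
          coefficient = as.vector(w)
        )
      })
      bind_rows(planes)
    }) %>%
    bind_rows()
}

#' Mexican-hat mother wavelet
#'
#' `psi(x) = 2 / (sqrt(3) pi^(1/4)) (1 - x^2) exp(-x^2 / 2)`, the
#' L2-normalised negative second derivative of a Gaussian.
#'
#' @param x Numeric vector.
#' @return `psi(x)`.
#' @export
mexican_hat <- function(x) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - x^2) * exp(-x^2 / 2)
}

# map arbitrary integer positions to 1..n by symmetric (edge-repeated)
# reflection: ... 2 1 | 1 2 ... n | n n-1 ...
.reflect_index <- function(pos, n) {
  m <- ((pos - 1) %% (2 * n)) + 1
  ifelse(m <= n, m, 2 * n + 1 - m)
}

# FFT convolution of every column of x (bands x plots) with the sampled
# Mexican hat at scale a; grid step h; symmetric extension at boundaries
.cwt_conv <- function(x, a, h) {
  n <- nrow(x)
  p_half <- ceiling(8 * a / h)           # kernel half-width in samples
  k <- mexican_hat(((-p_half):p_half) * h / a) / sqrt(a) * h
  ext_idx <- .reflect_index((1 - p_half):(n + p_half), n)
  e <- x[ext_idx, , drop = FALSE]
  len <- nrow(e) + length(k) - 1
  nfft <- nextn(len, c(2, 3, 5))
  ke <- c(k, numeric(nfft - length(k)))
  ee <- rbind(e, matrix(0, nrow = nfft - nrow(e), ncol = ncol(e)))
  conv <- Re(mvfft(mvfft(ee) * as.vector(fft(ke)), inverse = TRUE)) / nfft
  conv[(2 * p_half + 1):(2 * p_half + n), , drop = FALSE]
}

#' Wavelet coefficients at selected scale/band cells
#'
#' Computes `W(a, b)` by direct summation only at the requested cells —
#' much cheaper than a full [cwt_transform()] plane when a handful of
#' screened cells is applied to new trials. Identical (to numerical
#' round-off) to the corresponding cells of the full transform.
#'
#' @param spectra Long spectra tibble on a uniform grid.
#' @param cells Tibble with columns `stage`, `scale`, `wavelength_nm`.
#' @return Long tibble `plot_id`, `stage`, `scale`, `wavelength_nm`,
#'   `coefficient` (one row per plot x requested cell).
#' @export
cwt_at_cells <- function(spectra, cells) {
  value <- .check_spectra(spectra)
  stopifnot(all(c("stage", "scale", "wavelength_nm") %in% names(cells)))
  spectra %>%
    group_by(.data$stage) %>%
    group_split() %>%
    purrr::map(function(grp) {
      cc <- cells %>% filter(.data$stage == grp$stage[1])
      if (nrow(cc) == 0) return(NULL)
      sm <- .spectra_matrix(grp, value)
      h <- sm$wavelength_nm[2] - sm$wavelength_nm[1]
      if (!.is_uniform(sm$wavelength_nm)) {
        abort("cwt_at_cells requires a uniform wavelength grid")
      }
      n <- length(sm$wavelength_nm)
      purrr::pmap(list(cc$scale, cc$wavelength_nm), function(a, b) {
        bi <- match(b, sm$wavelength_nm)
        if (is.na(bi)) abort(sprintf("band %g nm not on the grid", b))
        p_half <- ceiling(8 * a / h)
        pos <- (bi - p_half):(bi + p_half)
        k <- mexican_hat((pos - bi) * h / a) / sqrt(a) * h
        idx <- .reflect_index(pos, n)
        tibble(
          plot_id = colnames(sm$values),
          stage = grp$stage[1], scale = a, wavelength_nm = b,
          coefficient = as.vector(crossprod(sm$values[idx, , drop = FALSE], k))
        )
      }) %>% bind_rows()
    }) %>%
    bind_rows()
}
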