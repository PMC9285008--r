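# Independent oracles and small builders shared across the test files.
# Everything here is deliberately written from the mathematical definitions,
# not by calling the package's own computational paths.

# quick long-spectra tibble for one curve
make_spectrum <- function(wl, refl, plot_id = "p1", stage = "heading") {
  tibble::tibble(plot_id = plot_id, stage = stage,
                 wavelength_nm = wl, reflectance = refl)
}

# several plots on a shared grid; `curves` is a named list plot_id -> values
make_spectra <- function(wl, curves, stage = "heading") {
  purrr::imap_dfr(curves, function(v, id) make_spectrum(wl, v, id, stage))
}

# --- Mexican hat, defined independently of the package ------------------
oracle_psi <- function(x) (2 / (sqrt(3) * pi^0.25)) * (1 - x^2) * exp(-x^2 / 2)

# symmetric (edge-repeated) mirror index, the documented boundary rule
oracle_reflect <- function(pos, n) {
  m <- ((pos - 1) %% (2 * n)) + 1
  ifelse(m <= n, m, 2 * n + 1 - m)
}

# brute-force discretised CWT: direct double loop over bands
oracle_cwt_brute <- function(wl, f, scales) {
  n <- length(f)
  h <- wl[2] - wl[1]
  out <- matrix(NA_real_, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    p_half <- ceiling(8 * a / h)
    for (b in seq_len(n)) {
      pos <- (b - p_half):(b + p_half)
      x <- (pos - b) * h / a
      out[si, b] <- sum(f[oracle_reflect(pos, n)] * oracle_psi(x)) / sqrt(a) * h
    }
  }
  out
}

# adaptive-quadrature CWT of an analytic Gaussian bump, mirrored about the
# grid ends exactly as the symmetric boundary rule prescribes: the extended
# signal is a sum of reflected Gaussian bumps, integrated with integrate()
oracle_cwt_quadrature <- function(bump_center, bump_sd, bump_amp,
                                  grid_lo, grid_hi, a, b) {
  # centers of the bump's mirror images within the kernel's support.
  # half-sample symmetric reflection about lo - 0.5 and hi + 0.5
  lo <- grid_lo - 0.5
  hi <- grid_hi + 0.5
  period <- 2 * (hi - lo)
  centers <- c()
  for (k in -3:3) {
    centers <- c(centers, bump_center + k * period,
                 2 * lo - bump_center + k * period)
  }
  centers <- centers[abs(centers - b) < 8 * a + 6 * bump_sd]
  f_ext <- function(x) {
    v <- 0
    for (cc in centers) v <- v + bump_amp * exp(-(x - cc)^2 / (2 * bump_sd^2))
    v
  }
  integrand <- function(x) f_ext(x) * oracle_psi((x - b) / a) / sqrt(a)
  stats::integrate(integrand, b - 8 * a, b + 8 * a,
                   rel.tol = 1e-10, abs.tol = 1e-13, subdivisions = 2000L)$value
}

# --- brute-force upper convex hull (all-pairs definition) ----------------
# continuum at x = the maximum, over all point pairs (i, j) spanning x, of
# the chord value at x (endpoints included via degenerate pairs)
oracle_continuum_brute <- function(x, y) {
  n <- length(x)
  cont <- y  # the curve itself is always attainable (i = j)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      within <- x >= x[i] & x <= x[j]
      chord <- y[i] + (y[j] - y[i]) * (x[within] - x[i]) / (x[j] - x[i])
      cont[within] <- pmax(cont[within], chord)
    }
  }
  cont
}

# --- per-window Savitzky-Golay least squares (interior points) -----------
oracle_sg_interior <- function(y, window, polyorder) {
  half <- (window - 1) / 2
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    fit <- lm(y[idx] ~ poly(idx, polyorder, raw = TRUE))
    out[i] <- unname(predict(fit)[half + 1])
  }
  out
}

# --- stepwise regression re-implementation (normal equations) ------------
# independent path: entry/removal loop on partial-F p-values computed from
# explicit RSS via solve() on the normal equations
oracle_stepwise <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  rss_of <- function(vars) {
    m <- cbind(1, as.matrix(X[, vars, drop = FALSE]))
    beta <- solve(crossprod(m), crossprod(m, y))
    sum((y - m %*% beta)^2)
  }
  pF <- function(rss0, rss1, df2) {
    if (rss1 <= 0) return(0)
    f <- (rss0 - rss1) / (rss1 / df2)
    stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  n <- length(y)
  vars <- character(0)
  tss <- sum((y - mean(y))^2)
  repeat {
    changed <- FALSE
    if (rss_of(vars) / tss >= 1e-12 && n - length(vars) - 1 > 0) {
      cand <- setdiff(colnames(X), vars)
      ps <- vapply(cand, function(v) {
        m1 <- cbind(1, as.matrix(X[, c(vars, v), drop = FALSE]))
        if (qr(m1)$rank < ncol(m1)) return(NA_real_)
        pF(rss_of(vars), rss_of(c(vars, v)), n - ncol(m1))
      }, numeric(1))
      ps <- ps[!is.na(ps)]
      if (length(ps) && min(ps) < p_enter) {
        best <- names(ps)[ps <= min(ps)]
        pick <- colnames(X)[min(match(best, colnames(X)))]
        vars <- c(vars, pick)
        changed <- TRUE
      }
    }
    repeat {
      if (!length(vars)) break
      ps <- vapply(vars, function(v) {
        pF(rss_of(setdiff(vars, v)), rss_of(vars), n - length(vars) - 1)
      }, numeric(1))
      if (max(ps) > p_remove) {
        vars <- setdiff(vars, vars[which.max(ps)])
        changed <- TRUE
      } else break
    }
    if (!changed) return(vars)
  }
}

# verify a retained set is a fixed point of the entry/removal tests
oracle_is_fixed_point <- function(X, y, vars, p_enter = 0.05, p_remove = 0.10) {
  n <- length(y)
  rss_of <- function(v) {
    m <- cbind(1, as.matrix(X[, v, drop = FALSE]))
    sum(qr.resid(qr(m), y)^2)
  }
  pF <- function(rss0, rss1, df2) {
    if (rss1 <= 0) return(0)
    stats::pf((rss0 - rss1) / (rss1 / df2), 1, df2, lower.tail = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  # no retained variable is removable
  for (v in vars) {
    if (pF(rss_of(setdiff(vars, v)), rss_of(vars), n - length(vars) - 1) >
        p_remove) return(FALSE)
  }
  if (rss_of(vars) / tss < 1e-12) return(TRUE)  # perfect fit: entry closed
  # no excluded variable is enterable
  for (v in setdiff(colnames(X), vars)) {
    m1 <- cbind(1, as.matrix(X[, c(vars, v), drop = FALSE]))
    if (qr(m1)$rank < ncol(m1)) next
    if (pF(rss_of(vars), rss_of(c(vars, v)), n - ncol(m1)) < p_enter) {
      return(FALSE)
    }
  }
  TRUE
}
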