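test_that("band correlations are exact in engineered cases", {
  wl <- seq(600, 800, 10)
  set.seed(3)
  n_plot <- 12
  curves <- stats::setNames(
    lapply(1:n_plot, function(i) runif(length(wl), .1, .6)),
    sprintf("p%02d", 1:n_plot))
  sp <- make_spectra(wl, curves)
  band700 <- vapply(curves, function(v) v[wl == 700], numeric(1))

  y <- tibble::tibble(plot_id = names(curves), yield_g_per_m2 = band700 * 1000)
  co <- band_yield_correlation(sp, y)
  expect_equal(co$r[co$wavelength_nm == 700], 1, tolerance = 1e-12)

  # negation flips the sign; positive affine shift leaves |r| alone
  y2 <- dplyr::mutate(y, yield_g_per_m2 = 900 - yield_g_per_m2)
  co2 <- band_yield_correlation(sp, y2)
  expect_equal(co2$r[co2$wavelength_nm == 700], -1, tolerance = 1e-12)
  expect_equal(abs(co2$r), abs(co$r), tolerance = 1e-12)

  expect_error(band_yield_correlation(sp, y[1:2, ]), "at least 3")
})

test_that("independent yields rarely reach high spurious band correlations", {
  tr <- simulate_trial(synth_config(), seed = 99)
  or <- sg_smooth(dplyr::filter(tr$spectra, stage == "heading"))
  y <- tr$yields
  set.seed(123)
  max_abs <- vapply(1:100, function(i) {
    yp <- dplyr::mutate(y, yield_g_per_m2 = sample(yield_g_per_m2))
    max(abs(band_yield_correlation(or, yp)$r), na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(max_abs < 0.45), 0.95)
})

test_that("wavelet-cell correlations pinpoint engineered signal", {
  wl <- 400:550
  set.seed(8)
  n_plot <- 10
  curves <- stats::setNames(
    lapply(1:n_plot, function(i) runif(length(wl), .1, .6)),
    sprintf("p%02d", 1:n_plot))
  sp <- make_spectra(wl, curves)
  cw <- cwt_transform(sp, scales = c(4, 8, 16))
  cell <- dplyr::filter(cw, scale == 8, wavelength_nm == 470)
  y <- tibble::tibble(plot_id = cell$plot_id,
                      yield_g_per_m2 = 600 + 100 * scale(cell$coefficient)[, 1])
  co <- wavelet_yield_correlation(cw, y)
  expect_equal(co$r[co$scale == 8 & co$wavelength_nm == 470], 1,
               tolerance = 1e-12)

  # a degenerate all-zero scale row yields missing correlations
  cw0 <- dplyr::mutate(cw, coefficient = ifelse(scale == 4, 0, coefficient))
  expect_message(co0 <- wavelet_yield_correlation(cw0, y), "zero variance")
  expect_true(all(is.na(co0$r[co0$scale == 4])))
  expect_false(anyNA(co0$r[co0$scale == 8]))
})

test_that("the most yield-sensitive wavelet cells sit at mid scales", {
  hits <- vapply(1:20, function(s) {
    tr <- simulate_trial(seed = s)
    or <- sg_smooth(dplyr::filter(tr$spectra, stage == "heading"))
    co <- wavelet_yield_correlation(cwt_transform(or), tr$yields)
    best <- co[which.max(abs(co$r)), ]
    best$scale >= 2^4 && best$scale <= 2^9
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the Pearson significance threshold matches a numeric inversion", {
  # oracle: invert the t CDF numerically over r via uniroot
  oracle_crit <- function(n, alpha) {
    stats::uniroot(function(r) {
      t <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(t, n - 2, lower.tail = FALSE) - alpha
    }, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  expect_equal(critical_r(60), oracle_crit(60, 0.05), tolerance = 1e-9)
  expect_lt(abs(critical_r(60) - 0.2542), 5e-4)
  expect_gt(critical_r(3), 0.996)
  expect_lt(critical_r(60, alpha = 0.9999), 0.01)
  expect_equal(critical_r(25, 0.01), oracle_crit(25, 0.01), tolerance = 1e-9)
})

test_that("greedy selection obeys suppression, thresholds and tie rules", {
  mk <- function(wl, r, stage = "heading") {
    structure(tibble::tibble(stage = stage, wavelength_nm = wl, r = r,
                             n = 60),
              class = c("pw_corr", "tbl_df", "tbl", "data.frame"))
  }
  # single qualifying cell
  one <- mk(c(500, 600), c(0.9, 0.1))
  expect_equal(select_sensitive(one, r_min = 0.5)$wavelength_nm, 500)

  # two high bands 3 nm apart: only the stronger survives
  close2 <- mk(c(600, 603), c(0.8, 0.9))
  expect_equal(select_sensitive(close2, r_min = 0.5)$wavelength_nm, 603)

  # hand-built map: greedy result equals the exhaustive optimum
  map <- mk(c(500, 506, 600, 640, 700, 705), c(0.9, 0.85, -0.8, 0.7, 0.6, 0.65))
  got <- select_sensitive(map, r_min = 0.5, top_k = 4)
  # exhaustive: all feasible subsets (pairwise > 10 nm apart, size <= 4),
  # maximising total |r|
  labs <- map$wavelength_nm
  best <- NULL; best_sum <- -Inf
  for (k in 1:4) for (sub in utils::combn(seq_along(labs), k, simplify = FALSE)) {
    if (k > 1 && min(dist(labs[sub])) <= 10) next
    s <- sum(abs(map$r[sub]))
    if (s > best_sum) { best_sum <- s; best <- labs[sub] }
  }
  expect_setequal(got$wavelength_nm, best)

  # output size shrinks as r_min or the separation grows
  for (rm in c(0.5, 0.7, 0.86)) {
    expect_lte(nrow(select_sensitive(map, r_min = rm, top_k = 4)),
               nrow(select_sensitive(map, r_min = 0.5, top_k = 4)))
  }
  expect_lte(nrow(select_sensitive(map, r_min = 0.5, top_k = 4,
                                   min_separation_nm = 150)),
             nrow(select_sensitive(map, r_min = 0.5, top_k = 4)))

  # empty result is allowed
  expect_equal(nrow(select_sensitive(one, r_min = 0.99)), 0)
})

test_that("a planted signal band is always selected first", {
  wl <- seq(500, 700, 5)
  for (s in 1:20) {
    set.seed(s)
    n_plot <- 30
    yields <- runif(n_plot, 500, 900)
    curves <- lapply(seq_len(n_plot), function(i) {
      v <- runif(length(wl), .2, .4)
      v[wl == 600] <- 0.3 + yields[i] / 5000 + rnorm(1, 0, 0.002)
      v
    })
    names(curves) <- sprintf("p%02d", seq_len(n_plot))
    sp <- make_spectra(wl, curves)
    co <- band_yield_correlation(
      sp, tibble::tibble(plot_id = names(curves), yield_g_per_m2 = yields))
    sel <- select_sensitive(co, top_k = 3)
    expect_lte(abs(sel$wavelength_nm[1] - 600), 10)
  }
})
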