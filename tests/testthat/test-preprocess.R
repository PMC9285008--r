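test_that("Savitzky-Golay preserves polynomials and matches the local LS oracle", {
  wl <- 400:520
  # constant: unchanged
  flat <- make_spectrum(wl, rep(0.42, length(wl)))
  expect_equal(sg_smooth(flat)$reflectance, flat$reflectance)

  # cubic with polyorder 3: reproduced everywhere, including the ends
  cub <- 0.3 + 1e-4 * (wl - 450) + 2e-6 * (wl - 450)^2 - 1e-8 * (wl - 450)^3
  out <- sg_smooth(make_spectrum(wl, cub))
  expect_lt(max(abs(out$reflectance - cub)), 1e-10)

  # noisy sine: interior equals a direct per-window least-squares fit,
  # and the residual against the clean curve shrinks at least 2x
  set.seed(5)
  clean <- 0.4 + 0.1 * sin(wl / 15)
  noisy <- clean + rnorm(length(wl), 0, 0.01)
  sm <- sg_smooth(make_spectrum(wl, noisy))$reflectance
  oracle <- oracle_sg_interior(noisy, 11, 3)
  keep <- !is.na(oracle)
  expect_lt(max(abs(sm[keep] - oracle[keep])), 1e-8)
  expect_lt(sd(sm - clean), sd(noisy - clean) / 2)

  expect_error(sg_smooth(flat, window = 10), "odd")
  expect_error(sg_smooth(flat, window = 11, polyorder = 11), "polyorder")
  expect_error(sg_smooth(make_spectrum(400:405, rep(.1, 6)), window = 11),
               "shorter")
})

test_that("first derivative matches analytic slopes", {
  wl <- 400:900
  ramp <- make_spectrum(wl, 0.1 + 2e-4 * (wl - 400))
  expect_equal(first_derivative(ramp)$derivative, rep(2e-4, length(wl)),
               tolerance = 1e-12)
  expect_true(all(first_derivative(make_spectrum(wl, rep(0.5, length(wl))))$derivative == 0))

  s <- make_spectrum(wl, sin(2 * pi * wl / 200))
  d <- first_derivative(s)$derivative
  analytic <- (2 * pi / 200) * cos(2 * pi * wl / 200)
  expect_lt(max(abs(d - analytic)[2:(length(wl) - 1)]), 1e-3)

  expect_error(first_derivative(make_spectrum(400:401, c(.1, .2))), "3 points")

  # commutes with scalar multiplication
  s3 <- make_spectrum(wl, 3 * sin(2 * pi * wl / 200))
  expect_equal(first_derivative(s3)$derivative, 3 * d, tolerance = 1e-12)
})

test_that("continuum removal equals the brute-force hull and is idempotent", {
  # strictly concave curve: hull is the curve, removed == 1 everywhere
  wl <- seq(400, 600, 10)
  conc <- make_spectrum(wl, 0.5 - 1e-5 * (wl - 500)^2)
  cr <- continuum_remove(conc)
  expect_equal(cr$removed, rep(1, length(wl)))

  # V shape: flat continuum at 0.5, removed dips to 0.2
  v <- make_spectrum(c(400, 500, 600), c(0.5, 0.1, 0.5))
  crv <- continuum_remove(v)
  expect_equal(crv$continuum, c(0.5, 0.5, 0.5))
  expect_equal(crv$removed, c(1, 0.2, 1))

  # random small spectra: exact agreement with the all-pairs chord oracle
  set.seed(11)
  for (rep_i in 1:20) {
    n <- sample(4:20, 1)
    x <- sort(sample(400:900, n))
    y <- runif(n, 0.05, 0.8)
    got <- continuum_remove(make_spectrum(x, y))
    expect_equal(got$continuum, oracle_continuum_brute(x, y), tolerance = 1e-12)
    # invariants: hull above curve, removed in (0, 1], endpoints on hull
    expect_true(all(got$continuum >= got$reflectance - 1e-12))
    expect_true(all(got$removed > 0 & got$removed <= 1))
    expect_true(got$is_hull[1] && got$is_hull[n])
    expect_true(all(abs(got$removed[got$is_hull] - 1) < 1e-12))
  }

  # idempotence: the hull of a removed spectrum is the flat line at 1
  wl2 <- 400:700
  spec <- make_spectrum(wl2, 0.4 + 0.1 * sin(wl2 / 40) - 1e-6 * (wl2 - 550)^2)
  once <- continuum_remove(spec)
  twice <- continuum_remove(make_spectrum(wl2, once$removed))
  expect_equal(twice$removed, once$removed, tolerance = 1e-12)

  expect_error(continuum_remove(make_spectrum(c(1, 2, 3) + 400, c(.1, -.1, .2))),
               "positive")
})

test_that("the FFT wavelet transform equals the brute-force discretised integral", {
  wl <- 400:655  # 256 points
  set.seed(21)
  f <- 0.3 + 0.1 * sin(wl / 30) + cumsum(rnorm(length(wl), 0, 0.002))
  scales <- 2^(1:10)
  got <- cwt_transform(make_spectrum(wl, f), scales = scales)
  want <- oracle_cwt_brute(wl, f, scales)
  for (si in seq_along(scales)) {
    g <- got$coefficient[got$scale == scales[si]]
    expect_lt(max(abs(g - want[si, ])), 1e-8)
  }
  # ten labelled dyadic rows
  expect_identical(sort(unique(got$scale)), 2^(1:10))
})

test_that("wavelet transform is linear and zero on the zero spectrum", {
  wl <- 400:527
  z <- cwt_transform(make_spectrum(wl, rep(0, length(wl))), scales = c(4, 16))
  expect_true(all(z$coefficient == 0))

  set.seed(31)
  f <- runif(length(wl)); g <- runif(length(wl))
  a <- 2.5; b <- -1.25
  wf <- cwt_transform(make_spectrum(wl, f), scales = c(4, 16))$coefficient
  wg <- cwt_transform(make_spectrum(wl, g), scales = c(4, 16))$coefficient
  wfg <- cwt_transform(make_spectrum(wl, a * f + b * g),
                       scales = c(4, 16))$coefficient
  expect_lt(max(abs(wfg - (a * wf + b * wg))), 1e-10)

  expect_error(cwt_transform(make_spectrum(wl, f), wavelet = "haar"))
})

test_that("cwt_at_cells reproduces the full transform at the requested cells", {
  wl <- 400:700
  set.seed(41)
  sp <- make_spectra(wl, list(p1 = runif(length(wl), .1, .5),
                              p2 = runif(length(wl), .1, .5)))
  full <- cwt_transform(sp, scales = c(8, 64))
  cells <- tibble::tibble(stage = "heading", scale = c(8, 64, 64),
                          wavelength_nm = c(450, 500, 699))
  got <- cwt_at_cells(sp, cells)
  want <- dplyr::inner_join(
    cells, full, by = c("stage", "scale", "wavelength_nm"))
  got <- dplyr::arrange(got, scale, wavelength_nm, plot_id)
  want <- dplyr::arrange(want, scale, wavelength_nm, plot_id)
  expect_equal(got$coefficient, want$coefficient, tolerance = 1e-10)
})
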