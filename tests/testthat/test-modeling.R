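test_that("stage fusion concatenates columns over the shared plots", {
  t_head <- tibble::tibble(plot_id = c("a", "b", "c"), heading_NDVI = 1:3 / 10)
  t_milk <- tibble::tibble(plot_id = c("a", "b", "c"), milky_NDVI = 4:6 / 10,
                           milky_DVI = 7:9 / 10)
  expect_identical(fuse_stages(list(heading = t_head), "heading"), t_head)
  fused <- fuse_stages(list(heading = t_head, milky = t_milk),
                       c("heading", "milky"))
  expect_equal(ncol(fused) - 1, 3)
  expect_error(fuse_stages(list(heading = t_head), character(0)), "at least one")
  expect_error(fuse_stages(list(heading = t_head), "milky"), "no feature table")

  combos <- stage_combinations()
  expect_length(combos, 15)
  expect_equal(lengths(combos), c(rep(1, 4), rep(2, 6), rep(3, 4), 4))
  expect_identical(combos[[1]], "elongation")
  expect_identical(combos[[15]], growth_stages())
})

test_that("stepwise regression recovers a noiseless truth exactly", {
  set.seed(2)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  df <- tibble::tibble(yield_g_per_m2 = 2 + 3 * x1, x1 = x1, x2 = x2)
  m <- fit_msr(df)
  expect_identical(m$retained, "x1")
  expect_equal(unname(m$coefficients["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(m$coefficients["x1"]), 3, tolerance = 1e-8)

  # exact duplicate column: first by column order wins, the copy is skipped
  df2 <- tibble::tibble(yield_g_per_m2 = 2 + 3 * x1 + rnorm(n, 0, 0.1),
                        x1 = x1, x1_copy = x1)
  expect_message(m2 <- fit_msr(df2), "rank-deficient")
  expect_identical(m2$retained, "x1")

  # three-signal noiseless truth recovered to 1e-6
  x3 <- rnorm(n)
  df3 <- tibble::tibble(yield_g_per_m2 = 600 + 5 * x1 - 2 * x2 + 0.5 * x3,
                        x1 = x1, x2 = x2, x3 = x3)
  m3 <- fit_msr(df3)
  expect_setequal(m3$retained, c("x1", "x2", "x3"))
  expect_equal(unname(m3$coefficients[c("x1", "x2", "x3")]), c(5, -2, 0.5),
               tolerance = 1e-6)

  # pure noise candidates: intercept-only model with a warning
  dfn <- tibble::tibble(yield_g_per_m2 = rnorm(n),
                        x1 = seq_len(n) %% 2, x2 = rep(1:4, 10))
  expect_warning(mn <- fit_msr(dfn), "intercept-only")
  expect_length(mn$retained, 0)
})

test_that("stepwise retained sets match the independent oracle over random draws", {
  set.seed(77)
  mismatch <- 0
  not_fixed <- 0
  for (i in 1:100) {
    n <- 30
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    # half the draws carry a true 2-variable signal, half are null-ish
    beta <- if (i %% 2) c(1.2, -0.8, 0) else c(0.3, 0, 0)
    y <- 500 + as.matrix(X) %*% beta + rnorm(n, 0, 1)
    df <- dplyr::bind_cols(tibble::tibble(yield_g_per_m2 = as.numeric(y)), X)
    m <- suppressWarnings(fit_msr(df))
    want <- oracle_stepwise(X, as.numeric(y))
    if (!setequal(m$retained, want)) mismatch <- mismatch + 1
    if (!oracle_is_fixed_point(X, as.numeric(y), m$retained)) {
      not_fixed <- not_fixed + 1
    }
  }
  expect_equal(mismatch, 0)
  expect_equal(not_fixed, 0)
})

test_that("tidy and glance summarise stepwise models", {
  set.seed(4)
  x <- rnorm(30)
  df <- tibble::tibble(yield_g_per_m2 = 1 + 2 * x + rnorm(30, 0, .1), x = x)
  m <- fit_msr(df)
  td <- tidy(m)
  expect_identical(td$term, c("(Intercept)", "x"))
  expect_true(td$p_value[2] < 0.05)
  gl <- glance(m)
  expect_gt(gl$r_squared, 0.9)
  expect_equal(gl$n_terms, 1)
})

test_that("random forests are seeded, bounded and interpolate constants", {
  set.seed(10)
  n <- 30
  df <- tibble::tibble(yield_g_per_m2 = runif(n, 500, 900),
                       a = rnorm(n), b = rnorm(n), c = rnorm(n))
  m1 <- fit_rf(df, seed = 42)
  m2 <- fit_rf(df, seed = 42)
  p1 <- predict(m1, df); p2 <- predict(m2, df)
  expect_identical(p1, p2)
  expect_true(all(p1 >= min(df$yield_g_per_m2) & p1 <= max(df$yield_g_per_m2)))

  dfc <- dplyr::mutate(df, yield_g_per_m2 = 700)
  mc <- suppressWarnings(fit_rf(dfc, seed = 1))  # constant-response note
  expect_true(all(predict(mc, dfc) == 700))

  expect_error(fit_rf(df[1, ]), "at least 5")
  expect_equal(glance(m1)$n_trees, 500)
  expect_equal(nrow(tidy(m1)), 3)
})

test_that("evaluation metrics follow their definitions", {
  ev <- evaluate(c(650, 650), c(600, 700))
  expect_equal(ev$rmse, 50)
  expect_equal(ev$mape, (50 / 650 + 50 / 650) / 2 * 100, tolerance = 1e-10)
  expect_equal(ev$r_squared, 1 - 5000 / 5000)

  obs <- c(600, 650, 700, 750)
  perfect <- evaluate(obs, obs)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mape, 0)

  mean_pred <- evaluate(rep(mean(obs), 4), obs)
  expect_equal(mean_pred$r_squared, 0)

  # scale equivariance: RMSE scales, R^2 and MAPE do not
  pred <- c(610, 640, 720, 740)
  e1 <- evaluate(pred, obs)
  e2 <- evaluate(3 * pred, 3 * obs)
  expect_equal(e2$rmse, 3 * e1$rmse)
  expect_equal(e2$r_squared, e1$r_squared)
  expect_equal(e2$mape, e1$mape)

  # observed-denominator variant
  e3 <- evaluate(c(650, 650), c(600, 700), mape_denom = "observed")
  expect_equal(e3$mape, (50 / 600 + 50 / 700) / 2 * 100, tolerance = 1e-10)

  expect_message(ez <- evaluate(c(0, 650), c(600, 700)), "zero denominator")
  expect_true(is.na(ez$mape))
  expect_error(evaluate(1:3, 1:2), "equal length")
  expect_error(evaluate(c(1, 2), c(5, 5)), "constant")
})

test_that("stepwise refit of its own retained set changes nothing", {
  set.seed(15)
  n <- 40
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  y <- 600 + 2 * X$x1 + 1.5 * X$x3 + rnorm(n, 0, 1)
  df <- dplyr::bind_cols(tibble::tibble(yield_g_per_m2 = y), X)
  m <- suppressWarnings(fit_msr(df))
  m_again <- suppressWarnings(fit_msr(df))
  expect_identical(m$retained, m_again$retained)
  expect_true(oracle_is_fixed_point(X, y, m$retained))
})

test_that("random forests explain the synthetic training yields", {
  r2 <- vapply(1:5, function(s) {
    tr <- simulate_trial(seed = s)
    fd <- first_derivative(sg_smooth(tr$spectra))
    co <- band_yield_correlation(fd, tr$yields)
    bands <- dplyr::select(select_sensitive(co), stage, wavelength_nm)
    ft <- build_feature_table(tr$spectra, groups = c("VI", "FD"),
                              fd_bands = bands)
    df <- dplyr::inner_join(ft, tr$yields, by = "plot_id")
    m <- fit_rf(df, seed = s)
    evaluate(predict(m, df), df$yield_g_per_m2)$r_squared
  }, numeric(1))
  expect_true(all(r2 >= 0.7))
})
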