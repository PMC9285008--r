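#' Enumerate growth-stage combinations
#'
#' All non-empty subsets of the four stages in canonical order: the 4
#' singles, 6 pairs, 4 triples, then the full four-stage combination.
#'
#' @param stages Stage names (default [growth_stages()]).
#' @return List of character vectors (15 for four stages).
#' @export
#' @examples
#' length(stage_combinations())
stage_combinations <- function(stages = growth_stages()) {
  purrr::map(seq_along(stages), function(k) {
    combn(stages, k, simplify = FALSE)
  }) %>% purrr::flatten()
}

#' Fuse per-stage feature tables
#'
#' Column-wise concatenation (inner join on `plot_id`) of the per-stage
#' tables named in `combo`. Columns are assumed stage-tagged already (as
#' produced by [build_feature_table()]).
#'
#' @param tables Named list of per-stage feature tibbles (`plot_id` +
#'   features).
#' @param combo Non-empty character vector of stage names to fuse.
#' @return Fused feature tibble.
#' @export
fuse_stages <- function(tables, combo) {
  if (length(combo) == 0) abort("`combo` must name at least one stage")
  miss <- setdiff(combo, names(tables))
  if (length(miss)) abort(paste0("no feature table for stage(s): ",
                                 paste(miss, collapse = ", ")))
  purrr::reduce(tables[combo], function(a, b) inner_join(a, b, by = "plot_id"))
}

#' Stepwise multiple linear regression (forward entry, backward removal)
#'
#' Classic bidirectional stepwise selection on partial-F p-values: at each
#' round the candidate with the smallest entry p-value joins if
#' `p < p_enter`, then any retained variable whose removal p-value exceeds
#' `p_remove` is dropped, until a fixed point is reached. The final model is
#' an ordinary least-squares fit of the retained variables. Candidates
#' whose addition would make the design rank-deficient (e.g. exact
#' duplicates of a retained column) are skipped with a message; entry stops
#' early once the fit is numerically perfect (residual sum of squares below
#' `1e-12` of the total), where partial F tests are meaningless.
#'
#' @param data Tibble holding the response and all candidate predictors
#'   (a `plot_id` column, if present, is ignored).
#' @param response Name of the response column (default `yield_g_per_m2`).
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must be `>= p_enter`.
#' @return An object of class `msr` with elements `coefficients`
#'   (named, including `(Intercept)`), `retained`, `p_values` (removal
#'   p-values of retained terms), `fit` (the `lm`), `p_enter`, `p_remove`,
#'   `steps` (entry/removal log).
#' @seealso [predict.msr()], [generics::tidy()], [generics::glance()]
#' @export
fit_msr <- function(data, response = "yield_g_per_m2",
                    p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (p_enter > p_remove) abort("`p_enter` must be <= `p_remove`")
  y <- data[[response]]
  xcols <- setdiff(names(data), c(response, "plot_id"))
  X <- as.data.frame(data[xcols])
  if (!all(vapply(X, is.numeric, logical(1)))) {
    abort("all candidate predictors must be numeric")
  }
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("response has zero variance")

  retained <- character(0)
  steps <- list()
  repeat {
    changed <- FALSE
    # current residual sum of squares
    rss_now <- .ols_rss(y, X, retained)
    if (n - length(retained) - 1 <= 0) break
    if (rss_now / tss >= 1e-12) {
      # forward: best entry candidate
      cand <- setdiff(xcols, retained)
      entry <- purrr::map_dfr(cand, function(v) {
        res <- .partial_f(y, X, retained, v)
        tibble(term = v, p = res$p, ok = res$ok)
      })
      if (nrow(entry) == 0) entry <- tibble(term = character(), p = numeric(),
                                            ok = logical())
      if (any(!entry$ok)) {
        inform(paste0("skipping rank-deficient candidate(s): ",
                      paste(entry$term[!entry$ok], collapse = ", ")))
      }
      entry <- entry %>% filter(.data$ok) %>% arrange(.data$p)
      if (nrow(entry) > 0 && is.finite(entry$p[1]) && entry$p[1] < p_enter) {
        # tie-break by column order
        best_p <- entry$p[1]
        tied <- entry$term[entry$p <= best_p + 0]
        pick <- xcols[min(match(tied, xcols))]
        retained <- c(retained, pick)
        steps <- c(steps, list(list(action = "enter", term = pick, p = best_p)))
        changed <- TRUE
      }
    }
    # backward: drop worst retained variable(s)
    repeat {
      if (length(retained) == 0) break
      rem <- purrr::map_dbl(retained, function(v) {
        .partial_f(y, X, setdiff(retained, v), v)$p
      })
      worst <- which.max(rem)
      if (is.finite(rem[worst]) && rem[worst] > p_remove) {
        steps <- c(steps, list(list(action = "remove",
                                    term = retained[worst], p = rem[worst])))
        retained <- retained[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  if (length(retained) == 0) {
    warn("no candidate passed the entry test; returning intercept-only model")
  }
  fml <- stats::reformulate(if (length(retained)) sprintf("`%s`", retained) else "1",
                            response = sprintf("`%s`", response))
  fit <- lm(fml, data = cbind(stats::setNames(data.frame(y), response), X))
  pvals <- if (length(retained)) {
    stats::setNames(purrr::map_dbl(retained, function(v) {
      .partial_f(y, X, setdiff(retained, v), v)$p
    }), retained)
  } else numeric(0)
  cf <- coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  structure(list(
    coefficients = cf, retained = retained, p_values = pvals, fit = fit,
    response = response, p_enter = p_enter, p_remove = p_remove, steps = steps
  ), class = "msr")
}

# RSS of OLS of y on X[, vars] (with intercept)
.ols_rss <- function(y, X, vars) {
  m <- cbind(1, as.matrix(X[vars]))
  q <- qr(m)
  sum(qr.resid(q, y)^2)
}

# partial F test for adding `v` to `base`; ok = FALSE if rank-deficient
.partial_f <- function(y, X, base, v) {
  m0 <- cbind(1, as.matrix(X[base]))
  m1 <- cbind(m0, X[[v]])
  q1 <- qr(m1)
  if (q1$rank < ncol(m1)) return(list(p = NA_real_, ok = FALSE))
  rss0 <- sum(qr.resid(qr(m0), y)^2)
  rss1 <- sum(qr.resid(q1, y)^2)
  df2 <- length(y) - ncol(m1)
  if (df2 <= 0) return(list(p = NA_real_, ok = FALSE))
  f <- (rss0 - rss1) / (rss1 / df2)
  p <- pf(f, 1, df2, lower.tail = FALSE)
  if (rss1 == 0) p <- 0  # perfect fit: infinitely significant
  list(p = p, ok = TRUE)
}

#' @export
print.msr <- function(x, ...) {
  cat("Stepwise multiple regression (p_enter = ", x$p_enter,
      ", p_remove = ", x$p_remove, ")\n", sep = "")
  cat("Retained terms:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  print(x$coefficients)
  invisible(x)
}

#' Predict from a stepwise regression model
#'
#' @param object An `msr` model.
#' @param newdata Tibble containing the retained feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted yields.
#' @export
predict.msr <- function(object, newdata, ...) {
  miss <- setdiff(object$retained, names(newdata))
  if (length(miss)) abort(paste0("newdata missing feature(s): ",
                                 paste(miss, collapse = ", ")))
  cf <- object$coefficients
  out <- rep(cf[["(Intercept)"]], nrow(newdata))
  for (v in object$retained) out <- out + cf[[v]] * newdata[[v]]
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stepwise regression model
#'
#' @param x An `msr` model.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `p_value` (partial-F removal p-value;
#'   `NA` for the intercept).
#' @export
tidy.msr <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    p_value = c(NA_real_, unname(x$p_values))[
      match(names(x$coefficients), c("(Intercept)", names(x$p_values)))]
  )
}

#' One-row model summary of a stepwise regression
#'
#' @param x An `msr` model.
#' @param ... Unused.
#' @return Tibble `r_squared`, `n_terms`, `n`, `p_enter`, `p_remove`.
#' @export
glance.msr <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, n_terms = length(x$retained),
         n = length(x$fit$residuals), p_enter = x$p_enter,
         p_remove = x$p_remove)
}

#' Random-forest yield regression
#'
#' Bootstrap ensemble of regression trees; the prediction is the mean of
#' the per-tree predictions, so predictions always lie within the range of
#' the training response. Deterministic under a fixed `seed`.
#'
#' @param data Tibble with the response and feature columns (`plot_id`
#'   ignored).
#' @param response Response column name (default `yield_g_per_m2`).
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `ceiling(p / 3)`, the
#'   regression convention.
#' @param seed Integer seed (default 1).
#' @return Object of class `pw_rf` wrapping the fitted ensemble.
#' @export
fit_rf <- function(data, response = "yield_g_per_m2", n_trees = 500,
                   mtry = NULL, seed = 1) {
  stopifnot(is.data.frame(data), response %in% names(data))
  xcols <- setdiff(names(data), c(response, "plot_id"))
  if (nrow(data) < 5) abort("fit_rf needs at least 5 rows")
  X <- as.data.frame(data[xcols])
  y <- data[[response]]
  mtry <- mtry %||% max(1, ceiling(length(xcols) / 3))
  set.seed(seed)
  ens <- randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry)
  structure(list(ensemble = ens, features = xcols, response = response,
                 n_trees = n_trees, mtry = mtry, seed = seed),
            class = "pw_rf")
}

#' Predict from a random-forest yield model
#'
#' @param object A `pw_rf` model.
#' @param newdata Tibble containing the feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted yields.
#' @export
predict.pw_rf <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) abort(paste0("newdata missing feature(s): ",
                                 paste(miss, collapse = ", ")))
  as.numeric(predict(object$ensemble,
                     newdata = as.data.frame(newdata[object$features])))
}

#' Tidy a random-forest model: variable importance
#'
#' @param x A `pw_rf` model.
#' @param ... Unused.
#' @return Tibble `term`, `importance` (increase in node purity), sorted
#'   decreasing.
#' @export
tidy.pw_rf <- function(x, ...) {
  imp <- randomForest::importance(x$ensemble)
  tibble(term = rownames(imp), importance = as.numeric(imp[, 1])) %>%
    arrange(desc(.data$importance))
}

#' One-row summary of a random-forest model
#'
#' @param x A `pw_rf` model.
#' @param ... Unused.
#' @return Tibble `n_trees`, `mtry`, `n`, `oob_mse`.
#' @export
glance.pw_rf <- function(x, ...) {
  tibble(n_trees = x$n_trees, mtry = x$mtry,
         n = length(x$ensemble$y),
         oob_mse = tail(x$ensemble$mse, 1))
}

#' Yield-model accuracy metrics
#'
#' Computes the three standard evaluation metrics:
#' `R^2 = 1 - sum((x - xhat)^2) / sum((x - mean(x))^2)` (proportion of
#' yield variance explained; the conventional form — a published variant
#' printing the ratio without the `1 -` contradicts its own "higher is
#' better" reading and is not used),
#' `RMSE = sqrt(mean((x - xhat)^2))` in g m^-2, and
#' `MAPE = 100 * mean(|x - xhat| / xhat)` in percent, with the
#' **predicted** value in the denominator by default (set
#' `mape_denom = "observed"` for the conventional form). A zero
#' denominator entry makes MAPE `NA` with a message.
#'
#' @param pred Predicted yields.
#' @param obs Observed yields (same length, >= 2, non-constant).
#' @param mape_denom `"predicted"` (default) or `"observed"`.
#' @return One-row tibble `r_squared`, `rmse`, `mape`, `n`.
#' @export
#' @examples
#' evaluate(c(650, 650), c(600, 700))  # RMSE 50, MAPE 7.69
evaluate <- function(pred, obs, mape_denom = c("predicted", "observed")) {
  mape_denom <- arg_match(mape_denom)
  if (length(pred) != length(obs)) abort("pred and obs must have equal length")
  if (length(obs) < 2) abort("need at least 2 observations")
  if (var(obs) == 0) abort("observed yields are constant; R^2 undefined")
  err <- obs - pred
  den <- if (mape_denom == "predicted") pred else obs
  mape <- if (any(den == 0)) {
    inform("zero denominator in MAPE; value set to NA")
    NA_real_
  } else 100 * mean(abs(err) / abs(den))
  tibble(
    r_squared = 1 - sum(err^2) / sum((obs - mean(obs))^2),
    rmse = sqrt(mean(err^2)),
    mape = mape,
    n = length(obs)
  )
}
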