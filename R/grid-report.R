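#' Fit and evaluate yield models over the stage-combination grid
#'
#' The full model sweep: for each transform set (`"FD-VI"` — vegetation
#' indices plus screened first-derivative bands; `"CWT-FD-VI"` — those plus
#' screened wavelet cells), each growth-stage combination (15 when all four
#' stages are present) and each algorithm (stepwise regression, random
#' forest), fit on the training trial and evaluate on the training set and
#' both validation trials.
#'
#' Band and cell screening uses **training data only**: first-derivative
#' bands and wavelet cells are selected per stage by [select_sensitive()]
#' on training correlations, then the same selections index features in
#' every trial, so no information leaks from the validation years into
#' model selection.
#'
#' @param benchmark A `pw_benchmark` from [make_three_year_benchmark()], or
#'   any list with elements `train`, `validation1`, `validation2`, each a
#'   list with `spectra` and `yields`.
#' @param transforms Subset of `c("FD-VI", "CWT-FD-VI")`.
#' @param algorithms Subset of `c("MSR", "RF")`.
#' @param combos List of stage combinations (default [stage_combinations()]
#'   over the stages present in the training spectra).
#' @param groups_extra Additional feature groups (e.g. `"EDGE"`) appended
#'   to every transform set; default none.
#' @param top_k,min_separation_nm,alpha Screening parameters, see
#'   [select_sensitive()].
#' @param scales CWT scales screened (default `2^(1:10)`).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param p_enter,p_remove Stepwise thresholds.
#' @param n_trees,rf_seed Random-forest parameters.
#' @param mape_denom Passed to [evaluate()].
#' @return Tibble of class `pw_report`: one row per
#'   (stage_combination, transform, algorithm) with columns
#'   `train_r_squared`, `train_rmse`, `train_mape`, `val1_*`, `val2_*`,
#'   `n_features`.
#' @export
stage_combination_grid <- function(benchmark,
                                   transforms = c("FD-VI", "CWT-FD-VI"),
                                   algorithms = c("MSR", "RF"),
                                   combos = NULL,
                                   groups_extra = character(0),
                                   top_k = 5, min_separation_nm = 10,
                                   alpha = 0.05,
                                   scales = 2^(1:10),
                                   sg_window = 11, sg_polyorder = 3,
                                   p_enter = 0.05, p_remove = 0.10,
                                   n_trees = 500, rf_seed = 1,
                                   mape_denom = "predicted") {
  transforms <- match.arg(transforms, c("FD-VI", "CWT-FD-VI"), several.ok = TRUE)
  algorithms <- match.arg(algorithms, c("MSR", "RF"), several.ok = TRUE)
  trials <- list(train = benchmark$train, val1 = benchmark$validation1,
                 val2 = benchmark$validation2)
  stopifnot(!purrr::some(trials, is.null))
  # leakage guard: validation plots must be unseen
  tr_ids <- unique(trials$train$yields$plot_id)
  for (v in c("val1", "val2")) {
    if (length(intersect(tr_ids, unique(trials[[v]]$yields$plot_id)))) {
      abort("validation plot_ids overlap the training set")
    }
  }
  stages_avail <- intersect(.stages, unique(trials$train$spectra$stage))
  combos <- combos %||% stage_combinations(stages_avail)

  # ---- screening on the training year only ----
  tr_or <- sg_smooth(trials$train$spectra, sg_window, sg_polyorder)
  tr_fd <- first_derivative(tr_or)
  fd_corr <- band_yield_correlation(tr_fd, trials$train$yields)
  fd_bands <- select_sensitive(fd_corr, top_k = top_k,
                               min_separation_nm = min_separation_nm,
                               alpha = alpha) %>%
    select("stage", "wavelength_nm")
  cwt_cells <- NULL
  if ("CWT-FD-VI" %in% transforms) {
    tr_cwt <- cwt_transform(tr_or, scales = scales)
    cwt_corr <- wavelet_yield_correlation(tr_cwt, trials$train$yields)
    cwt_cells <- select_sensitive(cwt_corr, top_k = top_k,
                                  min_separation_nm = min_separation_nm,
                                  alpha = alpha) %>%
      select("stage", "scale", "wavelength_nm")
  }

  # ---- per-trial, per-transform feature tables (per stage) ----
  feature_tables <- purrr::map(trials, function(trial) {
    purrr::map(stats::setNames(transforms, transforms), function(tf) {
      groups <- if (tf == "FD-VI") c("VI", "FD") else c("VI", "FD", "CWT")
      groups <- unique(c(groups, groups_extra))
      purrr::map(stats::setNames(stages_avail, stages_avail), function(s) {
        build_feature_table(
          trial$spectra %>% filter(.data$stage == s),
          groups = groups, fd_bands = fd_bands, cwt_cells = cwt_cells,
          sg_window = sg_window, sg_polyorder = sg_polyorder
        )
      })
    })
  })

  rows <- list()
  for (tf in transforms) {
    for (combo in combos) {
      fused <- purrr::map(feature_tables, function(per_tf) {
        fuse_stages(per_tf[[tf]], combo)
      })
      train_df <- inner_join(fused$train, trials$train$yields, by = "plot_id")
      for (alg in algorithms) {
        model <- if (alg == "MSR") {
          fit_msr(train_df, p_enter = p_enter, p_remove = p_remove)
        } else {
          fit_rf(train_df, n_trees = n_trees, seed = rf_seed)
        }
        ev <- purrr::imap(fused, function(ft, nm) {
          df <- inner_join(ft, trials[[nm]]$yields, by = "plot_id")
          evaluate(predict(model, df), df$yield_g_per_m2,
                   mape_denom = mape_denom)
        })
        rows <- c(rows, list(tibble(
          stage_combination = paste(combo, collapse = "-"),
          transform = tf, algorithm = alg,
          n_features = ncol(fused$train) - 1,
          train_r_squared = ev$train$r_squared, train_rmse = ev$train$rmse,
          train_mape = ev$train$mape,
          val1_r_squared = ev$val1$r_squared, val1_rmse = ev$val1$rmse,
          val1_mape = ev$val1$mape,
          val2_r_squared = ev$val2$r_squared, val2_rmse = ev$val2$rmse,
          val2_mape = ev$val2$mape
        )))
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "fd_bands") <- fd_bands
  attr(out, "cwt_cells") <- cwt_cells
  class(out) <- c("pw_report", class(out))
  out
}
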