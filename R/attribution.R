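attribution_features <- c("species", "sex", "age", "ego_size", "group_size",
                          "habitat", "species_age", "species_sex")

#' Build the covariate feature table for attribution
#'
#' Joins per-ego \eqn{\eta} estimates to demographics and encodes the
#' predictors used throughout the attribution stage: indicator columns
#' `species` (chimpanzee = 1), `sex` (male = 1), `habitat` (zoo = 1),
#' numeric `age` (years), `ego_size` (number of groomed partners, L),
#' `group_size`, and the interaction products `species_age`
#' (species x raw age) and `species_sex`.
#'
#' @param fits Per-ego fit tibble from [fit_egos()] (needs `ego_id`, `eta`,
#'   `L`; `group_size` taken from here when present).
#' @param meta Metadata tibble ([read_metadata()] schema). Ignored for
#'   columns already present in `fits`.
#' @return A tibble with `ego_id`, response `eta` and the eight predictor
#'   columns; no missing values.
#' @export
build_feature_table <- function(fits, meta = NULL) {
  tbl <- fits
  need <- c("species", "sex", "age", "habitat", "group_size")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    if (is.null(meta)) {
      abort(paste0("fits lack columns ", paste(missing_cols, collapse = ", "),
                   " and no `meta` was supplied"))
    }
    unmatched <- setdiff(tbl$ego_id, meta$individual_id)
    if (length(unmatched) > 0) {
      abort(paste0("ego(s) missing from metadata: ",
                   paste(unmatched, collapse = ", ")))
    }
    meta_cols <- meta %>%
      group_by(group_id) %>%
      mutate(group_size = dplyr::n()) %>%
      ungroup() %>%
      rename(ego_id = individual_id)
    tbl <- tbl %>%
      left_join(meta_cols %>% select(ego_id, dplyr::all_of(missing_cols)),
                by = "ego_id")
  }
  ind <- function(x, one) if (is.numeric(x)) as.numeric(x) else as.numeric(x == one)
  out <- tibble(
    ego_id = tbl$ego_id,
    eta = tbl$eta,
    species = ind(tbl$species, "chimpanzee"),
    sex = ind(tbl$sex, "male"),
    age = as.numeric(tbl$age),
    ego_size = as.numeric(tbl$L),
    group_size = as.numeric(tbl$group_size),
    habitat = ind(tbl$habitat, "zoo")
  ) %>%
    mutate(species_age = species * age, species_sex = species * sex)
  if (anyNA(out)) abort("feature table contains missing values")
  out
}

feature_matrix <- function(table) {
  missing_cols <- setdiff(attribution_features, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "groomcircles_schema_error")
  }
  as.matrix(table[attribution_features])
}

#' Fit the gradient-boosted attribution model
#'
#' Trains a gradient-boosted regression-tree ensemble (xgboost, squared
#' error loss) predicting \eqn{\eta} from the covariates, on the full table:
#' the model is explanatory (which covariates shape \eqn{\eta}), not
#' predictive, so no train/test split is used. Global feature importance is
#' total split gain per feature, normalized to sum 1; features never used
#' by any tree get importance 0.
#'
#' @param table Feature table from [build_feature_table()] with at least 30
#'   rows.
#' @param max_depth,nrounds,learning_rate Boosting hyperparameters
#'   (defaults: shallow depth-3 trees, 300 rounds, learning rate 0.1).
#' @param seed Integer seed (training is single-threaded and deterministic).
#' @return An object of class `eta_booster`: list with the fitted `booster`,
#'   `feature_names`, `importance` tibble (`feature`, `importance`, sorted
#'   decreasing), `params` and `table`.
#' @export
fit_attribution_model <- function(table, max_depth = 3, nrounds = 300,
                                  learning_rate = 0.1, seed = 1L) {
  if (nrow(table) < 30) {
    abort(paste0("need at least 30 rows to fit the attribution model, got ",
                 nrow(table)))
  }
  X <- feature_matrix(table)
  dtrain <- xgboost::xgb.DMatrix(data = X, label = table$eta, nthread = 1)
  params <- list(objective = "reg:squarederror", max_depth = max_depth,
                 eta = learning_rate, nthread = 1, seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  imp_raw <- xgboost::xgb.importance(model = booster)
  gain <- setNames(rep(0, length(attribution_features)), attribution_features)
  gain[imp_raw$Feature] <- imp_raw$Gain
  if (sum(gain) > 0) gain <- gain / sum(gain)
  structure(
    list(
      booster = booster,
      feature_names = attribution_features,
      importance = tibble(feature = names(gain), importance = unname(gain)) %>%
        arrange(dplyr::desc(importance)),
      params = c(params, nrounds = nrounds),
      table = table
    ),
    class = "eta_booster"
  )
}

#' Predict eta from a fitted attribution model
#'
#' @param object An `eta_booster`.
#' @param newdata Feature table (defaults to the training table).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.eta_booster <- function(object, newdata = NULL, ...) {
  tbl <- newdata %||% object$table
  X <- feature_matrix(tbl)
  stats::predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' @export
print.eta_booster <- function(x, ...) {
  cat(sprintf("Gradient-boosted eta attribution model (%d rounds, depth %d)\n",
              x$params$nrounds, x$params$max_depth))
  print(x$importance, n = length(x$feature_names))
  invisible(x)
}

#' @rdname fit_attribution_model
#' @param x An `eta_booster` object.
#' @param ... Unused.
#' @export
tidy.eta_booster <- function(x, ...) x$importance

#' @rdname fit_attribution_model
#' @export
glance.eta_booster <- function(x, ...) {
  pred <- predict.eta_booster(x)
  tibble(
    n = nrow(x$table),
    nrounds = x$params$nrounds,
    max_depth = x$params$max_depth,
    learning_rate = x$params$eta,
    rmse = sqrt(mean((pred - x$table$eta)^2)),
    r_squared = 1 - sum((pred - x$table$eta)^2) /
      sum((x$table$eta - mean(x$table$eta))^2)
  )
}

#' Per-ego Shapley attributions
#'
#' Exact TreeSHAP decomposition of every prediction into signed per-feature
#' contributions plus a base value (the mean prediction), satisfying local
#' accuracy: base value + row sum of attributions = model prediction.
#'
#' @param model An `eta_booster`.
#' @param table Feature table with the same schema (defaults to the
#'   training table).
#' @return An object of class `eta_shap`: list with `values` (tibble, one
#'   row per ego, one column per feature), `base_value`, `prediction` and
#'   the `table` explained.
#' @export
shap_attributions <- function(model, table = NULL) {
  stopifnot(inherits(model, "eta_booster"))
  tbl <- table %||% model$table
  X <- feature_matrix(tbl)
  contrib <- stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1),
                            predcontrib = TRUE)
  bias_col <- ncol(contrib)
  structure(
    list(
      values = as_tibble(contrib[, -bias_col, drop = FALSE]),
      base_value = unname(contrib[1, bias_col]),
      prediction = unname(rowSums(contrib)),
      table = tbl
    ),
    class = "eta_shap"
  )
}

#' @export
print.eta_shap <- function(x, ...) {
  m <- sort(colMeans(abs(as.matrix(x$values))), decreasing = TRUE)
  cat(sprintf("Shapley attributions for %d egos (base value %.4f)\n",
              nrow(x$values), x$base_value))
  cat("mean |attribution| by feature:\n")
  print(round(m, 4))
  invisible(x)
}

#' @rdname shap_attributions
#' @param x An `eta_shap` object.
#' @param ... Unused.
#' @export
tidy.eta_shap <- function(x, ...) {
  vals <- x$values %>%
    mutate(ego_id = x$table$ego_id %||% as.character(row_number())) %>%
    tidyr::pivot_longer(-ego_id, names_to = "feature", values_to = "shap")
  feats <- x$table %>%
    mutate(ego_id = x$table$ego_id %||% as.character(row_number())) %>%
    select(ego_id, dplyr::all_of(attribution_features)) %>%
    tidyr::pivot_longer(-ego_id, names_to = "feature", values_to = "value")
  left_join(vals, feats, by = c("ego_id", "feature"))
}

#' Partial-dependence curve at median/mode conditioning
#'
#' Model output as a function of one focal feature, with every other
#' numeric feature held at its median and every other indicator feature at
#' its mode (single-point conditioning, not the averaged classical PDP;
#' set `average = TRUE` for the averaged variant). The grid is the focal
#' feature's quantile grid for numeric features and its observed levels for
#' indicator features; interaction columns are recomputed from their
#' parents at each grid point.
#'
#' @param model An `eta_booster`.
#' @param table Feature table (defaults to the training table).
#' @param feature Focal feature name (one of the eight predictors).
#' @param grid_size Number of quantile grid points for numeric features
#'   (default 20).
#' @param average If `TRUE`, average predictions over the observed rows
#'   (classical PDP) instead of conditioning at median/mode.
#' @return A tibble of class `eta_pdp` with columns `feature`,
#'   `grid_value`, `prediction`.
#' @export
partial_dependence <- function(model, table = NULL, feature,
                               grid_size = 20, average = FALSE) {
  stopifnot(inherits(model, "eta_booster"))
  tbl <- table %||% model$table
  base_features <- c("species", "sex", "age", "ego_size", "group_size", "habitat")
  if (!feature %in% attribution_features) {
    abort(paste0("unknown feature '", feature, "'; choose one of: ",
                 paste(attribution_features, collapse = ", ")))
  }
  is_indicator <- feature %in% c("species", "sex", "habitat")
  grid <- if (is_indicator || feature %in% c("species_age", "species_sex")) {
    sort(unique(tbl[[feature]]))
  } else {
    unique(unname(quantile(tbl[[feature]],
                           probs = seq(0, 1, length.out = grid_size))))
  }

  mode_of <- function(x) {
    ux <- sort(unique(x))
    ux[which.max(tabulate(match(x, ux)))]
  }
  make_row <- function(g) {
    row <- tbl[1, c("eta", base_features)]
    for (f in base_features) {
      row[[f]] <- if (f %in% c("species", "sex", "habitat")) {
        mode_of(tbl[[f]])
      } else {
        median(tbl[[f]])
      }
    }
    if (feature %in% base_features) row[[feature]] <- g
    row <- row %>% mutate(species_age = species * age,
                          species_sex = species * sex)
    # focal interaction column set directly (parents kept at median/mode)
    if (feature %in% c("species_age", "species_sex")) row[[feature]] <- g
    row
  }

  preds <- purrr::map_dbl(grid, function(g) {
    if (average) {
      newt <- tbl
      newt[[feature]] <- g
      if (feature %in% c("species", "age")) {
        newt$species_age <- newt$species * newt$age
      }
      if (feature %in% c("species", "sex")) {
        newt$species_sex <- newt$species * newt$sex
      }
      mean(predict.eta_booster(model, newt))
    } else {
      predict.eta_booster(model, make_row(g))
    }
  })
  structure(
    tibble(feature = feature, grid_value = grid, prediction = preds),
    class = c("eta_pdp", "tbl_df", "tbl", "data.frame")
  )
}
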