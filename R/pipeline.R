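#' Fit the circle model to every retained ego
#'
#' Maps [fit_ego()] over the rows of a (filtered) ego table, returning one
#' tidy row per ego. Demographic columns present in the input are carried
#' through.
#'
#' @param egos Ego tibble from [ego_table()] / [apply_filters()] (columns
#'   `ego_id` and `weights` required).
#' @param delta Per-side tail mass of the confidence interval
#'   (default 0.025 for 95% CIs).
#' @param s_max,s_min Optional dataset-wide weight bounds (default: per-ego
#'   bounds from each ego's own weights).
#' @param tol Solver tolerance for the implicit equation.
#' @return A tibble of class `eta_fits`: per ego `ego_id`, carried
#'   demographics, `L`, `sigma`, `t_bar`, `eta`, `ci_low`, `ci_high`,
#'   `regime`.
#' @export
fit_egos <- function(egos, delta = 0.025, s_max = NULL, s_min = NULL,
                     tol = 1e-9) {
  stopifnot(all(c("ego_id", "weights") %in% names(egos)))
  fits <- purrr::map2_dfr(egos$weights, egos$ego_id, function(w, id) {
    tidy(fit_ego(w, delta = delta, s_max = s_max, s_min = s_min,
                 ego_id = id, tol = tol))
  })
  carried <- intersect(
    c("group_id", "species", "sex", "age", "habitat", "group_size"),
    names(egos)
  )
  out <- dplyr::bind_cols(egos[carried], fits) %>%
    select(ego_id, dplyr::all_of(carried), L, sigma, t_bar, eta,
           ci_low, ci_high, regime)
  class(out) <- c("eta_fits", class(out))
  out
}

#' Histogram of eta by species, as proportions of individuals
#'
#' Bins the estimated \eqn{\eta} values per species with frequency expressed
#' as the proportion of that species' individuals, the form used to compare
#' regime distributions across species.
#'
#' @param fits An `eta_fits` tibble (needs `eta`; `species` optional).
#' @param binwidth Bin width (default 1).
#' @param range Histogram range, widened automatically if estimates fall
#'   outside (default `c(-10, 15)`).
#' @return A tibble: `species`, `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `proportion` (summing to 1 within species).
#' @export
eta_histogram <- function(fits, binwidth = 1, range = c(-10, 15)) {
  stopifnot("eta" %in% names(fits))
  lo <- min(range[1], floor(min(fits$eta)))
  hi <- max(range[2], ceiling(max(fits$eta)))
  breaks <- seq(lo, hi, by = binwidth)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  sp <- if ("species" %in% names(fits)) fits$species else "all"
  tibble(species = sp, eta = fits$eta) %>%
    mutate(bin = cut(eta, breaks = breaks, include.lowest = TRUE,
                     right = FALSE)) %>%
    count(species, bin, .drop = FALSE) %>%
    group_by(species) %>%
    mutate(proportion = n / sum(n)) %>%
    ungroup() %>%
    mutate(
      bin_lo = breaks[as.integer(bin)],
      bin_hi = breaks[as.integer(bin) + 1],
      bin_mid = (bin_lo + bin_hi) / 2
    ) %>%
    select(species, bin_lo, bin_hi, bin_mid, n, proportion)
}

#' Run the full analysis pipeline and write the report bundle
#'
#' Orchestrates read, filter, per-ego estimation, group structure and
#' covariate attribution, writing every stage's table to `out_dir`:
#' `eta_estimates.csv`, `filter_audit.csv`, `group_summary.csv`,
#' `community_assignments.csv`, `eta_histogram.csv`, `importance.csv`,
#' `shap_values.csv`, `pdp_<feature>.csv` and `manifest.json` (settings,
#' seed, package version — enough for an exact re-run). Partial outputs are
#' removed if a stage fails.
#'
#' @param interactions Interaction records: a path or a data frame in the
#'   [read_interactions()] schema.
#' @param metadata Metadata: a path or data frame in the [read_metadata()]
#'   schema.
#' @param out_dir Output directory (created if needed).
#' @param min_group_size,min_partners Inclusion filters (defaults 6 and 5).
#' @param delta CI tail mass (default 0.025).
#' @param seed Seed for community detection and model fitting.
#' @param attribution `TRUE`, `FALSE`, or `NULL` (default: run the
#'   attribution stage only when at least 30 egos are retained).
#' @param max_depth,nrounds,learning_rate Attribution hyperparameters.
#' @return Invisibly, a list with every stage's tibble (`egos`, `audit`,
#'   `fits`, `group_summary`, `histogram`, and when run `importance`,
#'   `shap`, `pdp`).
#' @export
run_pipeline <- function(interactions, metadata, out_dir,
                         min_group_size = 6, min_partners = 5,
                         delta = 0.025, seed = 1L, attribution = NULL,
                         max_depth = 3, nrounds = 300, learning_rate = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written) > 0) unlink(written), add = TRUE)
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tbl, path)
    written <<- c(written, path)
    path
  }

  records <- read_interactions(interactions)
  meta <- read_metadata(metadata)
  networks <- build_group_networks(records, meta)
  egos <- ego_table(records, meta)
  retained <- apply_filters(egos, min_group_size = min_group_size,
                            min_partners = min_partners)
  audit <- filter_audit(retained)
  fits <- fit_egos(retained, delta = delta)
  emit(fits, "eta_estimates.csv")
  emit(
    dplyr::bind_rows(
      tibble(ego_id = "(summary)", group_id = NA_character_,
             reason = sprintf("groups %d/%d retained; egos %d/%d retained",
                              audit$groups_retained, audit$groups_in,
                              audit$egos_retained, audit$egos_in)),
      audit$exclusions
    ),
    "filter_audit.csv"
  )

  fitted_networks <- networks %>% filter(group_id %in% unique(fits$group_id))
  summary_tbl <- group_structure_table(fitted_networks, fits, seed = seed)
  emit(summary_tbl, "group_summary.csv")
  assignments <- purrr::map2_dfr(
    fitted_networks$group_id, fitted_networks$graph,
    function(g, gr) {
      tidy(detect_communities(symmetrize(gr), seed = seed)) %>%
        mutate(group_id = g) %>%
        select(group_id, individual_id, community)
    }
  )
  emit(assignments, "community_assignments.csv")

  hist_tbl <- eta_histogram(fits)
  emit(hist_tbl, "eta_histogram.csv")

  out <- list(egos = retained, audit = audit, fits = fits,
              group_summary = summary_tbl, histogram = hist_tbl)

  do_attr <- attribution %||% (nrow(fits) >= 30)
  if (do_attr) {
    ft <- build_feature_table(fits, meta)
    model <- fit_attribution_model(ft, max_depth = max_depth,
                                   nrounds = nrounds,
                                   learning_rate = learning_rate, seed = seed)
    shap <- shap_attributions(model)
    emit(model$importance, "importance.csv")
    emit(
      shap$values %>% mutate(ego_id = ft$ego_id, base_value = shap$base_value),
      "shap_values.csv"
    )
    pdps <- purrr::map(attribution_features, function(f) {
      pdp <- partial_dependence(model, ft, feature = f)
      emit(pdp, paste0("pdp_", f, ".csv"))
      pdp
    })
    out$importance <- model$importance
    out$shap <- shap
    out$pdp <- setNames(pdps, attribution_features)
    out$model <- model
  }

  manifest <- list(
    package = "groomcircles",
    version = as.character(utils::packageVersion("groomcircles")),
    r_version = as.character(getRversion()),
    settings = list(min_group_size = min_group_size,
                    min_partners = min_partners, delta = delta,
                    seed = as.integer(seed), attribution = do_attr,
                    max_depth = max_depth, nrounds = nrounds,
                    learning_rate = learning_rate),
    counts = list(groups_in = audit$groups_in,
                  groups_retained = audit$groups_retained,
                  egos_in = audit$egos_in,
                  egos_retained = audit$egos_retained)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, manifest_path)
  ok <- TRUE
  invisible(out)
}
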