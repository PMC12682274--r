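#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram geom_line
#'   geom_point geom_vline geom_jitter facet_wrap labs theme_minimal
#'   after_stat position_jitter
#' @export
ggplot2::autoplot

#' Plot per-species eta histograms
#'
#' Histogram of estimated \eqn{\eta} per species with frequency as the
#' proportion of individuals; the dashed line at 0 marks the change of
#' regime (inverted structures to the left, normal concentric structures
#' to the right), the dotted line each species' mean.
#'
#' @param object An `eta_fits` tibble from [fit_egos()].
#' @param binwidth Histogram bin width (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eta_fits <- function(object, binwidth = 1, ...) {
  df <- as_tibble(object)
  if (!"species" %in% names(df)) df$species <- "all"
  means <- df %>% group_by(species) %>% summarise(mean_eta = mean(eta))
  bins <- eta_histogram(df, binwidth = binwidth)
  ggplot(bins, aes(x = bin_mid, y = proportion)) +
    geom_col(width = binwidth, fill = "grey65", colour = "white") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    geom_vline(data = means, aes(xintercept = mean_eta),
               linetype = "dotted", colour = "blue") +
    facet_wrap(~species) +
    labs(x = expression(eta), y = "proportion of individuals") +
    theme_minimal()
}

#' Plot global feature importance
#'
#' @param object An `eta_booster` from [fit_attribution_model()].
#' @param ... Unused.
#' @return A ggplot bar chart of normalized total gain per feature.
#' @export
autoplot.eta_booster <- function(object, ...) {
  df <- object$importance %>%
    mutate(feature = factor(feature, levels = rev(feature)))
  ggplot(df, aes(x = importance, y = feature)) +
    geom_col(fill = "steelblue") +
    labs(x = "importance (normalized total gain)", y = NULL) +
    theme_minimal()
}

#' Plot per-ego Shapley attributions (summary beeswarm)
#'
#' One jittered point per ego and feature; horizontal position is the
#' signed attribution, colour the feature's value. Features ordered by mean
#' absolute attribution.
#'
#' @param object An `eta_shap` from [shap_attributions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eta_shap <- function(object, ...) {
  long <- tidy(object)
  ord <- long %>%
    group_by(feature) %>%
    summarise(m = mean(abs(shap))) %>%
    arrange(m) %>%
    pull(feature)
  long <- long %>%
    group_by(feature) %>%
    mutate(value = if (length(unique(value)) > 1) {
      (value - min(value)) / (max(value) - min(value))
    } else 0.5) %>%
    ungroup() %>%
    mutate(feature = factor(feature, levels = ord))
  ggplot(long, aes(x = shap, y = feature, colour = value)) +
    geom_jitter(height = 0.2, width = 0, alpha = 0.6, size = 1) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   name = "feature value\n(scaled)") +
    labs(x = expression("attribution to " * eta), y = NULL) +
    theme_minimal()
}

#' Plot a partial-dependence curve
#'
#' @param object An `eta_pdp` tibble from [partial_dependence()].
#' @param ... Unused.
#' @return A ggplot line (numeric features) or point (indicators) plot.
#' @export
autoplot.eta_pdp <- function(object, ...) {
  p <- ggplot(object, aes(x = grid_value, y = prediction))
  p <- if (nrow(object) > 2) p + geom_line() + geom_point() else p + geom_point(size = 3)
  p + labs(x = object$feature[1], y = expression("predicted " * eta)) +
    theme_minimal()
}

#' Scatter of group mean eta against modularity
#'
#' The group-level association between social-resource concentration and
#' network segmentation: groups whose members focus grooming on few
#' partners (higher mean \eqn{\eta}) tend to show higher modularity Q.
#'
#' @param summary_tbl Output of [group_structure_table()].
#' @return A ggplot object.
#' @export
plot_group_structure <- function(summary_tbl) {
  aes_args <- if (!all(is.na(summary_tbl$species))) {
    aes(x = mean_eta, y = q, colour = species)
  } else {
    aes(x = mean_eta, y = q)
  }
  ggplot(summary_tbl, aes_args) +
    geom_point(size = 3) +
    labs(x = expression("group mean " * hat(eta)), y = "modularity Q") +
    theme_minimal()
}
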