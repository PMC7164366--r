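# Bundled reference tables: the fossil-calibration table and the published
# clock-model marginal likelihoods used as a worked example.

#' Published fossil calibration table
#'
#' Minimum/maximum node-age bounds (Ma) with hard minima and soft (2.5%
#' tail) maxima for the cetartiodactyl dating analysis, including the root
#' bounds 52.40 (hard) / 164.6 (soft).
#'
#' @return Data frame: `node_label`, `t_min`, `min_type`, `t_max`,
#'   `max_type`, `p_lower`, `p_upper`.
#' @export
fossil_calibration_table <- function() {
  df <- read_tsv_stamped(system.file("extdata", "fossil_calibrations.tsv",
                                     package = "clockdate"))
  df$p_lower <- ifelse(df$min_type == "hard", 0, 0.025)
  df$p_upper <- ifelse(df$max_type == "hard", 0, 0.025)
  df
}

#' Published clock-model marginal likelihoods
#'
#' Stepping-stone log marginal likelihoods (with standard errors) and
#' posterior model probabilities for strict (STR), independent-rates (IR)
#' and autocorrelated-rates (AR) clocks on gene/species subsets; used as a
#' worked example for [model_posterior_probs()].
#'
#' @return Data frame: `data_label`, `model`, `log_ml`, `se`, `pr`.
#' @export
clock_model_logml_table <- function() {
  read_tsv_stamped(system.file("extdata", "clock_model_logml.tsv",
                               package = "clockdate"))
}
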