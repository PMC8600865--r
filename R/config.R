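#' Pipeline run configuration
#'
#' Bundles the tunable parameters shared across the pipeline stages.
#'
#' @param time_unit Unit of the survival times in the clinical table,
#'   `"days"` or `"months"`. Internal day-based thresholds (the 5-day
#'   minimum-survival rule) are converted with 1 month = 30.44 days.
#' @param n_imputations Number of multiply-imputed datasets M stacked before
#'   the weighted Cox fits (default 10).
#' @param missingness_cap Covariates missing at or above this fraction are
#'   excluded from the adjustment pool instead of imputed (default 0.20).
#' @param alpha Two-sided significance level used throughout (default 0.05).
#' @param min_survival_days Patients surviving fewer days than this are
#'   ineligible (default 5).
#' @param seed Integer seed controlling the imputation streams, the only
#'   stochastic step of discovery.
#' @param correlation_thresholds Length-2 cuts on |r| separating weak /
#'   moderate / strong Pearson correlation (default `c(0.3, 0.8)`).
#' @param cluster_k Number of patient clusters cut from the dendrogram
#'   (default 2).
#' @param require_ab_pvalue If `TRUE`, scenarios A/B additionally require a
#'   Wald p < `alpha` for radiotherapy on top of AIC retention with HR < 1.
#'   Off by default: retention with HR < 1 is the operative criterion.
#' @param reselect_cd If `TRUE`, scenarios C/D re-run fast-backward selection
#'   within their subsets instead of using the frozen cohort-level adjuster
#'   set. Off by default.
#' @param p_adjust_method Multiple-testing correction applied across genes to
#'   the scenario C/D p-values; `"none"` by default (no correction), any
#'   [stats::p.adjust] method otherwise.
#'
#' @return An object of class `rs_config` (a named list).
#' @export
rs_config <- function(time_unit = c("days", "months"),
                      n_imputations = 10L,
                      missingness_cap = 0.20,
                      alpha = 0.05,
                      min_survival_days = 5,
                      seed = 1L,
                      correlation_thresholds = c(0.3, 0.8),
                      cluster_k = 2L,
                      require_ab_pvalue = FALSE,
                      reselect_cd = FALSE,
                      p_adjust_method = "none") {
  time_unit <- match.arg(time_unit)
  stopifnot(alpha > 0, alpha < 1, n_imputations >= 1,
            missingness_cap > 0, missingness_cap <= 1,
            min_survival_days > 0,
            length(correlation_thresholds) == 2,
            correlation_thresholds[1] < correlation_thresholds[2])
  structure(list(
    time_unit = time_unit,
    n_imputations = as.integer(n_imputations),
    missingness_cap = missingness_cap,
    alpha = alpha,
    min_survival_days = min_survival_days,
    seed = as.integer(seed),
    correlation_thresholds = correlation_thresholds,
    cluster_k = as.integer(cluster_k),
    require_ab_pvalue = require_ab_pvalue,
    reselect_cd = reselect_cd,
    p_adjust_method = p_adjust_method
  ), class = "rs_config")
}

# days per month used when survival times are recorded in months
DAYS_PER_MONTH <- 30.44

# minimum survival threshold expressed in the configured unit
min_survival_threshold <- function(config) {
  if (config$time_unit == "months") {
    config$min_survival_days / DAYS_PER_MONTH
  } else {
    config$min_survival_days
  }
}
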