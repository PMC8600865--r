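# Cohort eligibility: tumor-sample filtering, removal of samples with
# missing survival/radiotherapy or survival under 5 days, and the
# dataset-level radiotherapy-protective screen.

#' Construct a cohort dataset
#'
#' Joins an expression matrix and a clinical table on their shared samples
#' (samples present on only one side are dropped with a message), keeping
#' the two in identical sample order.
#'
#' @param expression Genes x samples numeric matrix.
#' @param clinical Clinical `data.frame` with a `sample_id` column.
#' @param eligibility_log Optional named counts of samples removed per filter.
#' @return Object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(expression, clinical, eligibility_log = integer(0)) {
  shared <- intersect(colnames(expression), clinical$sample_id)
  n_only_expr <- ncol(expression) - length(shared)
  n_only_clin <- nrow(clinical) - length(shared)
  if (n_only_expr + n_only_clin > 0)
    message(sprintf("dropping unmatched samples: %d expression-only, %d clinical-only",
                    n_only_expr, n_only_clin))
  if (length(shared) < 2) stop("fewer than 2 samples shared by expression and clinical")
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  attr(clin, "schema") <- attr(clinical, "schema")
  structure(list(expression = expression[, shared, drop = FALSE],
                 clinical = clin,
                 eligibility_log = c(eligibility_log,
                                     unmatched = n_only_expr + n_only_clin)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("Cohort: %d samples, %d genes, %d events, %d (%.0f%%) irradiated\n",
              ncol(x$expression), nrow(x$expression),
              sum(x$clinical$os_event), sum(x$clinical$radiotherapy),
              100 * mean(x$clinical$radiotherapy)))
  if (length(x$eligibility_log))
    cat("removed:", paste(names(x$eligibility_log), x$eligibility_log,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Keep tumor samples of a TCGA-style expression matrix
#'
#' TCGA barcodes carry the sample type in characters 14-15 of the barcode;
#' codes 01-09 are tumors, 10-19 normals. When ids do not look like TCGA
#' barcodes and no annotation is supplied, all samples are retained with a
#' warning.
#'
#' @param expr Genes x samples matrix.
#' @param sample_types Optional named character vector of two-digit sample
#'   type codes per sample id, overriding barcode parsing.
#' @return The matrix restricted to tumor samples.
#' @export
filter_tumor_samples <- function(expr, sample_types = NULL) {
  ids <- colnames(expr)
  codes <- if (!is.null(sample_types)) {
    unname(sample_types[ids])
  } else if (all(grepl("^TCGA(-[A-Za-z0-9]+){3,}", ids))) {
    vapply(strsplit(ids, "-"), function(p) substr(p[4], 1, 2), character(1))
  } else {
    warning("sample ids are not TCGA barcodes and no sample_types given; retaining all samples")
    return(expr)
  }
  tumor <- !is.na(codes) & codes %in% sprintf("%02d", 1:9)
  if (!any(tumor)) stop("no tumor samples left after sample-type filtering")
  expr[, tumor, drop = FALSE]
}

#' Apply the eligibility filters
#'
#' In order: drop samples missing any of survival time, event indicator or
#' radiotherapy status; then drop samples surviving less than the 5-day
#' minimum (converted to the configured time unit). Removal counts per rule
#' are recorded in the eligibility log; applying the filter twice is a
#' no-op.
#'
#' @param expression Genes x samples matrix.
#' @param clinical Clinical `data.frame`.
#' @param config An [rs_config()].
#' @return A `cohort_dataset` of eligible samples.
#' @export
apply_eligibility <- function(expression, clinical, config = rs_config()) {
  cohort <- cohort_dataset(expression, clinical)
  clin <- cohort$clinical
  miss <- is.na(clin$os_time) | is.na(clin$os_event) | is.na(clin$radiotherapy)
  clin2 <- clin[!miss, , drop = FALSE]
  thr <- min_survival_threshold(config)
  short <- clin2$os_time < thr
  clin3 <- clin2[!short, , drop = FALSE]
  if (sum(clin3$os_event) < 2) stop("fewer than 2 events remain after eligibility filtering")
  attr(clin3, "schema") <- attr(clinical, "schema")
  out <- cohort_dataset(cohort$expression[, clin3$sample_id, drop = FALSE], clin3)
  out$eligibility_log <- c(unmatched = unname(cohort$eligibility_log[["unmatched"]]),
                           missing_surv_or_rt = sum(miss),
                           min_survival = sum(short))
  out
}

#' Dataset-level radiotherapy-protective screen
#'
#' Univariate Cox regression of overall survival on radiotherapy; the
#' cohort passes (verdict `keep`) only when radiotherapy is protective
#' (HR < 1) at p < alpha. Cohorts where one treatment arm has no events are
#' dropped as degenerate.
#'
#' @param cohort A `cohort_dataset`.
#' @param config An [rs_config()].
#' @return List with `keep` (logical), `hr`, `p`, `reason`.
#' @export
screen_rt_protective <- function(cohort, config = rs_config()) {
  clin <- cohort$clinical
  ev_by_arm <- tapply(clin$os_event, clin$radiotherapy, sum)
  if (length(ev_by_arm) < 2 || any(ev_by_arm == 0))
    return(list(keep = FALSE, hr = NA_real_, p = NA_real_, reason = "degenerate"))
  fit <- fit_cox(clin, "radiotherapy")
  row <- cox_term(fit, "radiotherapy")
  keep <- row$hr < 1 && row$p < config$alpha
  list(keep = keep, hr = row$hr, p = row$p,
       reason = if (keep) "protective" else "not protective")
}
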