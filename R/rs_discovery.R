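# Core procedure: per-gene median dichotomization, scenario A-D evaluation
# with covariate adjustment on the imputation stack, and Type I/II + RGH/RGL
# classification.

#' Median-dichotomize a gene
#'
#' Splits the cohort at the within-cohort median of one gene's expression:
#' label `H` when strictly above the median, `L` otherwise (ties go low).
#' Crossing with radiotherapy yields the four groups HRT / LRT / HNRT /
#' LNRT.
#'
#' @param cohort A `cohort_dataset`.
#' @param gene_id Gene to split on.
#' @return List of class `gene_dichotomy`: `gene_id`, `threshold`, `label`
#'   (named `H`/`L` per sample), `group_sizes` (named: HRT, LRT, HNRT,
#'   LNRT; sums to the cohort size).
#' @export
dichotomize_gene <- function(cohort, gene_id) {
  if (!gene_id %in% rownames(cohort$expression))
    stop("gene not in expression matrix: ", gene_id)
  x <- cohort$expression[gene_id, ]
  if (length(x) < 4) stop("cohort too small to dichotomize")
  if (length(unique(x)) < 2) stop("degenerate gene (constant expression): ", gene_id)
  thr <- median(x)
  lab <- ifelse(x > thr, "H", "L")
  rt <- cohort$clinical$radiotherapy[match(names(x), cohort$clinical$sample_id)]
  sizes <- c(HRT = sum(lab == "H" & rt == 1), LRT = sum(lab == "L" & rt == 1),
             HNRT = sum(lab == "H" & rt == 0), LNRT = sum(lab == "L" & rt == 0))
  structure(list(gene_id = gene_id, threshold = thr, label = lab,
                 group_sizes = sizes),
            class = "gene_dichotomy")
}

scenario_na <- function(reason) {
  list(evaluable = FALSE, holds = FALSE, hr = NA_real_, lower = NA_real_,
       upper = NA_real_, p = NA_real_, retained = NA, reason = reason)
}

scenario_row <- function(row, holds, retained = NA) {
  list(evaluable = TRUE, holds = holds, hr = row$hr, lower = row$lower,
       upper = row$upper, p = row$p, retained = retained, reason = "")
}

#' Evaluate the four radio-sensitivity scenarios for one gene
#'
#' All four analyses run on the imputation stack (weights 1/M, subject-
#' clustered variance for reported statistics):
#' * **A** — within the high-expression subset, AIC fast-backward selection
#'   over radiotherapy plus the cohort-level adjusters; holds when
#'   radiotherapy is retained with HR < 1.
#' * **B** — the same within the low-expression subset.
#' * **C** — within the radiotherapy subset, weighted Cox of survival on the
#'   high-expression indicator plus the adjusters; holds when the
#'   indicator's two-sided p < alpha.
#' * **D** — the same within the no-radiotherapy subset.
#'
#' A subset where the model cannot be fitted (no events, degenerate design)
#' leaves that scenario not evaluable with `holds = FALSE`.
#'
#' @param stack An `imputation_stack` of the cohort's clinical data.
#' @param dichotomy A `gene_dichotomy`.
#' @param adjusters Cohort-level adjustment covariates (frozen before the
#'   per-gene loop).
#' @param config An [rs_config()].
#' @return List of class `scenario_panel` with elements `A`, `B`, `C`, `D`
#'   (each: `evaluable`, `holds`, `hr`, `lower`, `upper`, `p`, `retained`,
#'   `reason`), plus `gene_id`, `adjusters`, `group_sizes`.
#' @export
evaluate_scenarios <- function(stack, dichotomy, adjusters,
                               config = rs_config()) {
  lab <- dichotomy$label
  stack$.high <- as.integer(lab[stack$sample_id] == "H")

  eval_ab <- function(ids) {
    sub <- stack_subset(stack, ids)
    tryCatch({
      fb <- fast_backward_aic(sub, c("radiotherapy", adjusters),
                              weights = sub$.weight, cluster = sub$sample_id)
      retained <- "radiotherapy" %in% fb$retained
      row <- if (retained) cox_term(fb$fit, "radiotherapy")
             else cox_term(fb$full_fit, "radiotherapy")
      holds <- retained && !is.null(row) && row$hr < 1
      if (config$require_ab_pvalue) holds <- holds && !is.na(row$p) && row$p < config$alpha
      scenario_row(row, holds, retained)
    }, error = function(e) scenario_na(conditionMessage(e)))
  }
  eval_cd <- function(rt_value) {
    ids <- unique(stack$sample_id[stack$radiotherapy == rt_value])
    sub <- stack_subset(stack, ids)
    tryCatch({
      if (config$reselect_cd) {
        fb <- fast_backward_aic(sub, c(".high", adjusters),
                                weights = sub$.weight, cluster = sub$sample_id)
        retained <- ".high" %in% fb$retained
        row <- if (retained) cox_term(fb$fit, ".high")
               else cox_term(fb$full_fit, ".high")
        scenario_row(row, retained && !is.na(row$p) && row$p < config$alpha, retained)
      } else {
        fit <- fit_cox(sub, c(".high", adjusters),
                       weights = sub$.weight, cluster = sub$sample_id)
        row <- cox_term(fit, ".high")
        if (is.null(row)) stop("high-expression indicator dropped (degenerate subset)")
        scenario_row(row, !is.na(row$p) && row$p < config$alpha)
      }
    }, error = function(e) scenario_na(conditionMessage(e)))
  }

  high_ids <- names(lab)[lab == "H"]
  low_ids <- names(lab)[lab == "L"]
  structure(list(gene_id = dichotomy$gene_id,
                 A = eval_ab(high_ids), B = eval_ab(low_ids),
                 C = eval_cd(1), D = eval_cd(0),
                 adjusters = adjusters,
                 group_sizes = dichotomy$group_sizes),
            class = "scenario_panel")
}

#' Classify a scenario panel into an RS-gene call
#'
#' A gene is radio-sensitive when scenario A and/or B holds and exactly one
#' of C or D holds: C alone gives Type I (expression matters only under
#' radiotherapy), D alone gives Type II (prognostic effect erased by
#' radiotherapy). Direction is RGH when A holds, RGL when B holds, `both`
#' when both do. Genes where C and D both hold are not RS and are flagged
#' ambiguous. A direction/effect-sign inconsistency (e.g. an RGH Type I gene
#' whose scenario-C hazard ratio favors the low group) never vetoes a call
#' but is reported in `direction_warning`.
#'
#' @param panel A `scenario_panel`.
#' @return One-row `data.frame`: `gene`, `is_rs`, `rs_type` (`"I"`, `"II"`,
#'   `"none"`), `direction` (`"RGH"`, `"RGL"`, `"both"`, `"none"`),
#'   `ambiguous`, `direction_warning`, per-scenario hold flags, HRs, CIs and
#'   p-values, and the four group sizes.
#' @export
classify_rs <- function(panel) {
  a <- panel$A$holds; b <- panel$B$holds
  c_ <- panel$C$holds; d <- panel$D$holds
  ambiguous <- (a || b) && c_ && d
  is_rs <- (a || b) && xor(c_, d)
  rs_type <- if (is_rs && c_) "I" else if (is_rs && d) "II" else "none"
  direction <- if (!is_rs) "none" else if (a && b) "both" else if (a) "RGH" else "RGL"
  warn <- FALSE
  if (is_rs) {
    # under the called pattern the interaction scenario's HR (high vs low)
    # should favor the benefiting expression group
    hr <- if (rs_type == "I") panel$C$hr else panel$D$hr
    expected_high_better <- if (rs_type == "I") direction %in% c("RGH", "both")
                            else direction %in% c("RGL", "both")
    if (!is.na(hr)) warn <- if (expected_high_better) hr > 1 else hr < 1
  }
  out <- data.frame(
    gene = panel$gene_id, is_rs = is_rs, rs_type = rs_type,
    direction = direction, ambiguous = ambiguous, direction_warning = warn,
    A_holds = a, B_holds = b, C_holds = c_, D_holds = d,
    A_hr = panel$A$hr, A_p = panel$A$p,
    B_hr = panel$B$hr, B_p = panel$B$p,
    C_hr = panel$C$hr, C_lower = panel$C$lower, C_upper = panel$C$upper, C_p = panel$C$p,
    D_hr = panel$D$hr, D_lower = panel$D$lower, D_upper = panel$D$upper, D_p = panel$D$p,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(panel$group_sizes)))
  out
}

#' Discover radio-sensitive genes across a panel
#'
#' The full per-cohort procedure: (1) require the cohort to pass the
#' radiotherapy-protective screen; (2) impute the clinical covariates once
#' (M stacked copies; the only stochastic step, controlled by
#' `config$seed`); (3) freeze the cohort-level adjuster set by AIC
#' fast-backward selection over radiotherapy plus all usable covariates on
#' the stack; (4) per gene: median-dichotomize, evaluate scenarios A-D, and
#' classify. Genes absent from the expression matrix or with constant
#' expression are skipped with a message.
#'
#' @param cohort A `cohort_dataset` (already eligibility-filtered).
#' @param gene_list Genes to screen; defaults to all genes in the matrix.
#' @param config An [rs_config()].
#' @return `data.frame` of per-gene calls (one row per screened gene; see
#'   [classify_rs()]), with attributes `adjusters`, `screen`, `selection`
#'   (the cohort-level elimination trace) and `config`.
#' @export
discover_rs <- function(cohort, gene_list = NULL, config = rs_config()) {
  screen <- screen_rt_protective(cohort, config)
  if (!screen$keep)
    stop(sprintf(paste0("cohort fails the radiotherapy-protective screen ",
                        "(HR = %.3f, p = %.3g, %s): RS discovery requires a ",
                        "protective radiotherapy effect"),
                 screen$hr, screen$p, screen$reason))
  clin <- cohort$clinical
  if (is.null(gene_list)) gene_list <- rownames(cohort$expression)
  missing_genes <- setdiff(gene_list, rownames(cohort$expression))
  if (length(missing_genes))
    message("skipping gene(s) absent from expression: ",
            paste(missing_genes, collapse = ", "))
  genes <- setdiff(gene_list, missing_genes)
  if (!length(genes)) stop("no usable genes in gene list")

  sel <- select_imputable(clin, config$missingness_cap)
  pool <- c(sel$complete, sel$imputable)
  mi <- impute_chained(clin, M = config$n_imputations, seed = config$seed,
                       covariates = pool)
  stack <- stack_imputations(mi)

  fb <- fast_backward_aic(stack, c("radiotherapy", pool),
                          weights = stack$.weight, cluster = stack$sample_id)
  adjusters <- setdiff(fb$retained, "radiotherapy")

  calls <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    calls[[i]] <- tryCatch({
      dich <- dichotomize_gene(cohort, g)
      classify_rs(evaluate_scenarios(stack, dich, adjusters, config))
    }, error = function(e) {
      message("skipping gene ", g, ": ", conditionMessage(e))
      NULL
    })
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls)) stop("no gene could be evaluated")

  if (config$p_adjust_method != "none") {
    calls <- reclassify_with_adjusted_p(calls, config)
  }
  # structural guarantee: no call is simultaneously Type I and Type II
  stopifnot(!any(calls$is_rs & calls$C_holds & calls$D_holds),
            all(calls$rs_type[calls$is_rs] %in% c("I", "II")),
            all(calls$rs_type[!calls$is_rs] == "none"))
  attr(calls, "adjusters") <- adjusters
  attr(calls, "screen") <- screen
  attr(calls, "selection") <- fb$trace
  attr(calls, "config") <- config
  calls
}

# re-threshold scenario C/D on BH-adjusted p-values and re-derive the calls
reclassify_with_adjusted_p <- function(calls, config) {
  cp <- stats::p.adjust(calls$C_p, method = config$p_adjust_method)
  dp <- stats::p.adjust(calls$D_p, method = config$p_adjust_method)
  c_ <- !is.na(cp) & cp < config$alpha & calls$C_holds
  d <- !is.na(dp) & dp < config$alpha & calls$D_holds
  ab <- calls$A_holds | calls$B_holds
  calls$C_holds <- c_
  calls$D_holds <- d
  calls$ambiguous <- ab & c_ & d
  calls$is_rs <- ab & xor(c_, d)
  calls$rs_type <- ifelse(calls$is_rs & c_, "I", ifelse(calls$is_rs & d, "II", "none"))
  calls$direction <- ifelse(!calls$is_rs, "none",
                            ifelse(calls$A_holds & calls$B_holds, "both",
                                   ifelse(calls$A_holds, "RGH", "RGL")))
  calls
}

#' Intersect RS calls across datasets
#'
#' @param call_tables Named list (>= 2) of call `data.frame`s from
#'   [discover_rs()].
#' @param filter Which genes to intersect: all RS genes, one type, or one
#'   direction.
#' @return List with `common` (genes passing the filter in every table),
#'   `per_table` (the filtered sets) and `pairwise` (named intersections for
#'   Venn reporting).
#' @export
intersect_calls <- function(call_tables,
                            filter = c("rs", "type1", "type2", "RGH", "RGL")) {
  filter <- match.arg(filter)
  stopifnot(length(call_tables) >= 2, !is.null(names(call_tables)))
  pick <- function(df) {
    keep <- switch(filter,
      rs = df$is_rs,
      type1 = df$is_rs & df$rs_type == "I",
      type2 = df$is_rs & df$rs_type == "II",
      RGH = df$is_rs & df$direction %in% c("RGH", "both"),
      RGL = df$is_rs & df$direction %in% c("RGL", "both"))
    df$gene[keep]
  }
  sets <- lapply(call_tables, pick)
  common <- Reduce(intersect, sets)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(p) intersect(sets[[p[1]]], sets[[p[2]]]))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = "&")
  list(common = common, per_table = sets, pairwise = pairwise)
}
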