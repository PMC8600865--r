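# Synthetic cohort generator: proportional-hazards survival with censoring,
# confounded treatment assignment, MAR covariate missingness, and planted
# gene-by-radiotherapy interactions with a known truth table.

#' Declare a planted gene effect
#'
#' Effect classes mirror the two interaction patterns a radio-sensitive gene
#' can show: `type1` genes have no prognostic main effect but their
#' high-expression group gains (or loses) extra benefit under radiotherapy
#' (`beta_main = 0`, `beta_interaction != 0`); `type2` genes are prognostic
#' without radiotherapy and the interaction exactly cancels the main effect
#' under treatment (`beta_main != 0`, `beta_main + beta_interaction = 0`);
#' `null` genes have neither.
#'
#' @param gene_id Gene identifier.
#' @param effect_class One of `"null"`, `"type1"`, `"type2"`.
#' @param beta_main Log-hazard of the high-expression indicator.
#' @param beta_interaction Log-hazard of the high-expression-by-radiotherapy
#'   product.
#' @return One-row `data.frame` describing the effect.
#' @export
gene_effect <- function(gene_id, effect_class = c("null", "type1", "type2"),
                        beta_main = 0, beta_interaction = 0) {
  effect_class <- match.arg(effect_class)
  ok <- switch(effect_class,
    null  = beta_main == 0 && beta_interaction == 0,
    type1 = beta_main == 0 && beta_interaction != 0,
    type2 = beta_main != 0 && abs(beta_main + beta_interaction) < 1e-12)
  if (!ok) stop("betas inconsistent with effect class '", effect_class, "'")
  data.frame(gene_id = gene_id, effect_class = effect_class,
             beta_main = beta_main, beta_interaction = beta_interaction,
             stringsAsFactors = FALSE)
}

#' The standard 70-gene recovery panel
#'
#' 50 null genes, 10 Type I genes (interaction log 0.4) and 10 Type II genes
#' (main effect log 2 cancelled under radiotherapy) — the panel used by the
#' pipeline's recovery experiments.
#'
#' @param n_null,n_type1,n_type2 Panel composition.
#' @param beta_int_type1 Interaction log-hazard of the Type I genes.
#' @param beta_main_type2 Main-effect log-hazard of the Type II genes.
#' @return `data.frame` of gene effects, one row per gene.
#' @export
standard_gene_panel <- function(n_null = 50, n_type1 = 10, n_type2 = 10,
                                beta_int_type1 = log(0.4),
                                beta_main_type2 = log(2)) {
  n <- n_null + n_type1 + n_type2
  ids <- sprintf("G%03d", seq_len(n))
  cls <- rep(c("null", "type1", "type2"), c(n_null, n_type1, n_type2))
  data.frame(
    gene_id = ids, effect_class = cls,
    beta_main = ifelse(cls == "type2", beta_main_type2, 0),
    beta_interaction = ifelse(cls == "type1", beta_int_type1,
                              ifelse(cls == "type2", -beta_main_type2, 0)),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defaults encode the standard recovery scenario: 1500 patients, a
#' protective radiotherapy main effect (HR 0.6), three clinical confounders
#' with Table-1-like effect sizes (age group HR 2.0, chemotherapy HR 0.4,
#' stage HR 2.1), mildly confounded treatment assignment, exponential
#' baseline hazard with administrative plus dropout censoring tuned to
#' roughly 20% censoring, and 10% missing-at-random masking of chemotherapy
#' and stage (missingness probability increasing with observed age).
#'
#' @param n_patients Cohort size (>= 2).
#' @param genes Gene effect table from [standard_gene_panel()] /
#'   [gene_effect()] rows bound together.
#' @param beta_rt Radiotherapy main-effect log-hazard (default `log(0.6)`).
#' @param covariate_betas Named log-hazards for the indicator of the non-
#'   reference level of the three built-in clinical covariates.
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param admin_horizon Administrative censoring horizon in days.
#' @param dropout_rate Rate of the independent exponential dropout process
#'   (per day; 0 disables dropout).
#' @param missing_rates Named fractions of cells masked MAR per covariate
#'   (only `chemotherapy` and `stage` may be masked; each must be < 1).
#' @param rt_assignment Function of the clinical `data.frame` returning the
#'   per-patient probability of receiving radiotherapy.
#' @param type2_block_cor Pairwise correlation planted between the Type II
#'   genes' expression (a shared patient factor), emulating the strongly
#'   co-expressed Type II blocks seen in real cohorts.
#' @param interaction_on `"indicator"` plants effects on the median-split
#'   indicator (the dichotomized analysis is then correctly specified);
#'   `"continuous"` plants them on centred continuous expression, a
#'   model-misspecification stress test.
#' @param expr_mean,expr_sd Normal parameters of the log2-scale expression.
#' @param missing_rt_rate Fraction of patients with radiotherapy status
#'   masked (ineligible; exercises the eligibility filters, default 0).
#' @param seed Integer seed; generation is bit-reproducible given the
#'   configuration and seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 1500,
                             genes = standard_gene_panel(),
                             beta_rt = log(0.6),
                             covariate_betas = c(age_group = log(2.0),
                                                 chemotherapy = log(0.4),
                                                 stage = log(2.1)),
                             baseline_hazard = 3e-3,
                             admin_horizon = 3000,
                             dropout_rate = 5e-5,
                             missing_rates = c(chemotherapy = 0.10, stage = 0.10),
                             rt_assignment = default_rt_assignment,
                             type2_block_cor = 0,
                             interaction_on = c("indicator", "continuous"),
                             expr_mean = 8, expr_sd = 1,
                             missing_rt_rate = 0,
                             seed = 1L) {
  interaction_on <- match.arg(interaction_on)
  stopifnot(n_patients >= 2, is.data.frame(genes),
            all(c("gene_id", "effect_class", "beta_main", "beta_interaction")
                %in% names(genes)),
            !anyDuplicated(genes$gene_id),
            all(missing_rates >= 0), all(missing_rates < 1),
            all(names(missing_rates) %in% c("chemotherapy", "stage")),
            type2_block_cor >= 0, type2_block_cor < 1,
            baseline_hazard > 0, admin_horizon > 0, dropout_rate >= 0,
            missing_rt_rate >= 0, missing_rt_rate < 1,
            is.function(rt_assignment))
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default (mildly confounded) radiotherapy assignment probability
#'
#' Later-stage and older patients are slightly more likely to be treated,
#' so treatment is not randomized and covariate adjustment is genuinely
#' exercised.
#' @param clin Clinical `data.frame` with `age_group` and `stage`.
#' @return Vector of treatment probabilities.
#' @export
default_rt_assignment <- function(clin) {
  plogis(0.1 + 0.25 * (clin$stage == "III/IV") +
           0.15 * (clin$age_group == ">=60"))
}

#' Generate a synthetic cohort with planted gene-radiotherapy interactions
#'
#' Survival times follow an exponential proportional-hazards model
#' `h0 * exp(b_clin Z + b_rt RT + sum_g (b_main_g High_g + b_int_g High_g RT))`
#' where `High_g` is the within-cohort median-split indicator of gene g
#' (ties low). Censoring is the minimum of an administrative horizon and an
#' independent exponential dropout time. Chemotherapy and stage cells are
#' masked missing-at-random with probability increasing in observed age.
#'
#' @param config A [synthetic_config()].
#' @return List with `expression` (genes x samples matrix), `clinical`
#'   (`data.frame` with schema attached, covariates `age`, `age_group`,
#'   `chemotherapy`, `stage`), and `truth` (`data.frame`: `gene_id`,
#'   `effect_class`, `n_high`), class `synthetic_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("SYN%05d", seq_len(n))

  age <- round(rnorm(n, 58, 12))
  age <- pmin(pmax(age, 25), 90)
  clin <- data.frame(
    sample_id = ids,
    age = age,
    age_group = factor(ifelse(age >= 60, ">=60", "<60"),
                       levels = c("<60", ">=60")),
    chemotherapy = factor(ifelse(runif(n) < 0.85, "Yes", "No"),
                          levels = c("No", "Yes")),
    stage = factor(ifelse(runif(n) < 0.25, "III/IV", "I/II"),
                   levels = c("I/II", "III/IV")),
    stringsAsFactors = FALSE)

  p_rt <- config$rt_assignment(clin)
  if (length(unique(p_rt)) == 1 && (p_rt[1] <= 0 || p_rt[1] >= 1))
    stop("non-identifiable config: degenerate radiotherapy assignment")
  rt <- rbinom(n, 1, p_rt)
  if (length(unique(rt)) < 2)
    stop("non-identifiable config: only one treatment arm realized")
  clin$radiotherapy <- rt

  genes <- config$genes
  G <- nrow(genes)
  expr <- matrix(rnorm(G * n, 0, 1), nrow = G,
                 dimnames = list(genes$gene_id, ids))
  if (config$type2_block_cor > 0) {
    block <- which(genes$effect_class == "type2")
    if (length(block) >= 2) {
      rho <- config$type2_block_cor
      shared <- rnorm(n)
      expr[block, ] <- sqrt(rho) * matrix(shared, length(block), n, byrow = TRUE) +
        sqrt(1 - rho) * expr[block, , drop = FALSE]
    }
  }
  expr <- config$expr_mean + config$expr_sd * expr

  med <- apply(expr, 1, median)
  high <- expr > med  # G x n logical, ties low
  gene_term <- if (config$interaction_on == "indicator") {
    high + 0
  } else {
    sweep(expr, 1, med)
  }

  cb <- config$covariate_betas
  lp <- cb[["age_group"]] * (clin$age_group == ">=60") +
    cb[["chemotherapy"]] * (clin$chemotherapy == "Yes") +
    cb[["stage"]] * (clin$stage == "III/IV") +
    config$beta_rt * rt +
    drop(crossprod(gene_term, genes$beta_main)) +
    drop(crossprod(gene_term, genes$beta_interaction)) * rt

  t_event <- rexp(n, rate = config$baseline_hazard * exp(lp))
  t_drop <- if (config$dropout_rate > 0) rexp(n, config$dropout_rate) else rep(Inf, n)
  t_cens <- pmin(t_drop, config$admin_horizon)
  clin$os_time <- pmax(round(pmin(t_event, t_cens), 2), 0.01)
  clin$os_event <- as.integer(t_event <= t_cens)

  # MAR masking: probability proportional to exp(0.03 (age - mean age)),
  # scaled to the configured marginal rate
  w <- exp(0.03 * (clin$age - mean(clin$age)))
  for (cv in names(config$missing_rates)) {
    rate <- config$missing_rates[[cv]]
    if (rate > 0) {
      p_miss <- pmin(rate * w / mean(w), 0.95)
      clin[[cv]][runif(n) < p_miss] <- NA
    }
  }
  if (config$missing_rt_rate > 0)
    clin$radiotherapy[runif(n) < config$missing_rt_rate] <- NA

  clin <- clin[, c("sample_id", "os_time", "os_event", "radiotherapy",
                   "age", "age_group", "chemotherapy", "stage")]
  attr(clin, "schema") <- list(
    cov_continuous("age"),
    cov_categorical("age_group", levels = c("<60", ">=60")),
    cov_categorical("chemotherapy", levels = c("No", "Yes")),
    cov_categorical("stage", levels = c("I/II", "III/IV")))

  truth <- data.frame(gene_id = genes$gene_id,
                      effect_class = genes$effect_class,
                      n_high = rowSums(high), stringsAsFactors = FALSE)
  class(truth) <- c("synthetic_truth", "data.frame")

  list(expression = expr, clinical = clin, truth = truth)
}

#' Score RS calls against the planted truth
#'
#' @param calls RS-call table from [discover_rs()].
#' @param truth `synthetic_truth` table from [generate_cohort()].
#' @return List with `sensitivity` (RS called among truly type1/type2 genes),
#'   `fpr` (RS called among null genes), `type_accuracy` (correct Type I/II
#'   assignment among true-positive calls; `NA` when there are none), and the
#'   underlying counts.
#' @export
score_recovery <- function(calls, truth) {
  if (!setequal(calls$gene, truth$gene_id))
    stop("gene sets of calls and truth differ")
  m <- match(calls$gene, truth$gene_id)
  cls <- truth$effect_class[m]
  is_effect <- cls %in% c("type1", "type2")
  tp <- calls$is_rs & is_effect
  expected_type <- ifelse(cls == "type1", "I", ifelse(cls == "type2", "II", "none"))
  list(
    sensitivity = if (any(is_effect)) mean(calls$is_rs[is_effect]) else NA_real_,
    fpr = if (any(!is_effect)) mean(calls$is_rs[!is_effect]) else NA_real_,
    type_accuracy = if (any(tp)) mean(calls$rs_type[tp] == expected_type[tp]) else NA_real_,
    n_true = sum(is_effect), n_null = sum(!is_effect),
    n_called = sum(calls$is_rs), n_true_positive = sum(tp))
}
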