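# Statistical core: Cox fitting, AIC fast-backward selection, Kaplan-Meier,
# log-rank, Wilcoxon, categorized Pearson correlation.

utils::globalVariables(c(".wts", ".clu"))

backtick <- function(x) paste0("`", x, "`")

#' Fit a Cox proportional hazards model
#'
#' Thin, validated wrapper around [survival::coxph()] with Efron tie
#' handling, returning a uniform fit summary used by every pipeline stage.
#' Constant covariate columns (including factors with a single observed
#' level) are dropped with a message before fitting; aliased terms that
#' `coxph` cannot estimate are dropped likewise and the model refitted.
#' When `cluster` is given, standard errors are robust sandwich estimates
#' aggregated over clusters (the variance used for stacked multiple
#' imputation). Confidence intervals are `exp(coef +/- 1.96 se)` and
#' p-values are two-sided Wald.
#'
#' @param data `data.frame` containing the outcome and covariate columns.
#' @param covariates Character vector of covariate column names (may be
#'   empty: the null model is fitted and only model-level quantities are
#'   returned).
#' @param time,event Names of the survival time and 0/1 event columns.
#' @param weights Optional per-record numeric weights.
#' @param cluster Optional vector (or column name) of grouping ids for
#'   cluster-robust variance.
#' @return An object of class `cox_fit`: list with `terms` (per-term
#'   `data.frame`: `term`, `variable`, `coef`, `se`, `hr`, `lower`, `upper`,
#'   `p`), `loglik`, `aic` (`-2 logPL + 2k`), `n`, `n_events`, `converged`,
#'   `separation`, `dropped`.
#' @export
fit_cox <- function(data, covariates, time = "os_time", event = "os_event",
                    weights = NULL, cluster = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 2)
  ev <- data[[event]]
  if (sum(ev) < 1) stop("no events in data: Cox model unfittable")
  if (anyDuplicated(covariates)) stop("duplicate covariate terms")

  d <- data
  if (length(cluster) == 1 && is.character(cluster) && cluster %in% names(data)) {
    cluster <- data[[cluster]]
  }
  d$.wts <- if (is.null(weights)) rep(1, nrow(d)) else weights
  has_cluster <- !is.null(cluster)
  if (has_cluster) d$.clu <- cluster

  # drop constant columns (single observed value/level) up front
  dropped <- character(0)
  keep <- covariates
  for (v in covariates) {
    x <- d[[v]]
    if (is.null(x)) stop("covariate column absent: ", v)
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2) {
      dropped <- c(dropped, v)
      keep <- setdiff(keep, v)
    }
  }
  if (length(dropped))
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))

  fit_once <- function(vars) {
    rhs <- if (length(vars)) paste(backtick(vars), collapse = " + ") else "1"
    fml <- as.formula(sprintf("Surv(%s, %s) ~ %s", backtick(time), backtick(event), rhs))
    if (has_cluster) {
      coxph(fml, data = d, weights = .wts, cluster = .clu,
            ties = "efron", x = FALSE, model = FALSE)
    } else {
      coxph(fml, data = d, weights = .wts, ties = "efron",
            x = FALSE, model = FALSE)
    }
  }

  # coxph's $assign is a list: element j holds the coefficient indices of
  # the j-th model term (in `keep` order)
  coef_variables <- function(fit, vars) {
    idx <- integer(length(coef(fit)))
    for (j in seq_along(fit$assign)) idx[fit$assign[[j]]] <- j
    vars[idx]
  }

  fit <- fit_once(keep)
  if (length(keep) && anyNA(coef(fit))) {
    av <- unique(coef_variables(fit, keep)[is.na(coef(fit))])
    warning("dropping aliased covariate(s): ", paste(av, collapse = ", "))
    dropped <- c(dropped, av)
    keep <- setdiff(keep, av)
    fit <- fit_once(keep)
  }

  null_model <- length(keep) == 0
  ll <- if (null_model) fit$loglik[1] else fit$loglik[2]
  k <- if (null_model) 0L else length(coef(fit))
  converged <- if (null_model) TRUE else {
    it <- fit$iter
    is.null(it) || it[1] < coxph.control()$iter.max
  }

  terms_df <- if (null_model) {
    data.frame(term = character(0), variable = character(0), coef = numeric(0),
               se = numeric(0), hr = numeric(0), lower = numeric(0),
               upper = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  } else {
    cf <- coef(fit)
    se <- sqrt(diag(fit$var))  # robust when cluster given
    data.frame(term = names(cf),
               variable = coef_variables(fit, keep),
               coef = unname(cf), se = unname(se),
               hr = exp(unname(cf)),
               lower = exp(unname(cf) - 1.96 * unname(se)),
               upper = exp(unname(cf) + 1.96 * unname(se)),
               p = 2 * pnorm(-abs(unname(cf) / unname(se))),
               stringsAsFactors = FALSE)
  }
  separation <- any(abs(terms_df$coef) > 20)
  if (separation) warning("possible complete separation: |coef| > 20")

  structure(list(terms = terms_df, loglik = ll, aic = -2 * ll + 2 * k,
                 n = fit$n, n_events = fit$nevent, converged = converged,
                 separation = separation, dropped = dropped,
                 covariates = keep),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: n = %d, events = %d, logPL = %.3f, AIC = %.3f\n",
              x$n, x$n_events, x$loglik, x$aic))
  if (nrow(x$terms)) {
    df <- x$terms
    df$hr <- sprintf("%.3f (%.3f, %.3f)", df$hr, df$lower, df$upper)
    print(df[, c("term", "coef", "se", "hr", "p")], row.names = FALSE, digits = 3)
  } else cat("(null model)\n")
  invisible(x)
}

#' Extract one variable's summary row from a `cox_fit`
#'
#' For a categorical variable with several indicator terms the first
#' indicator is returned; the scenario analyses only interrogate binary
#' variables (radiotherapy, the high-expression indicator).
#' @param fit A `cox_fit`.
#' @param variable Variable name.
#' @return One-row `data.frame`, or `NULL` if the variable is not in the fit.
#' @export
cox_term <- function(fit, variable) {
  rows <- fit$terms[fit$terms$variable == variable, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  rows[1, , drop = FALSE]
}

#' AIC fast-backward covariate elimination for Cox models
#'
#' Exact backward elimination: starting from the full model, every candidate
#' removal (a categorical variable's indicators leave as a group) is refitted
#' and the removal giving the largest AIC decrease is applied; the procedure
#' stops when no removal decreases AIC. This is the refit-per-candidate
#' version of fast-backward selection; at the model sizes used here it is
#' indistinguishable from the classical approximation and exactly testable.
#'
#' @inheritParams fit_cox
#' @param covariates Candidate covariates for elimination.
#' @return List of class `fb_result`: `retained` (character), `fit`
#'   (`cox_fit` of the final model, cluster-robust when `cluster` given),
#'   `trace` (`data.frame` with `step`, `removed`, `aic`; AIC strictly
#'   decreasing), `full_fit`.
#' @export
fast_backward_aic <- function(data, covariates, time = "os_time",
                              event = "os_event", weights = NULL,
                              cluster = NULL) {
  # selection needs only log partial likelihoods: fit without cluster for
  # speed, then refit the final model with the robust variance
  full <- fit_cox(data, covariates, time, event, weights)
  current <- full$covariates
  aic_cur <- full$aic
  trace <- data.frame(step = 0L, removed = "(full model)", aic = aic_cur,
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(current)) {
    aics <- vapply(current, function(v) {
      fit_cox(data, setdiff(current, v), time, event, weights)$aic
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= aic_cur) break
    step <- step + 1L
    aic_cur <- aics[best]
    trace <- rbind(trace, data.frame(step = step, removed = current[best],
                                     aic = aic_cur, stringsAsFactors = FALSE))
    current <- setdiff(current, current[best])
  }
  final <- fit_cox(data, current, time, event, weights, cluster)
  structure(list(retained = current, fit = final, trace = trace,
                 full_fit = full),
            class = "fb_result")
}

#' Kaplan-Meier product-limit curves
#'
#' At tied times events are handled before censorings (the product-limit
#' convention).
#'
#' @param times Survival times.
#' @param events 0/1 event indicators.
#' @param groups Optional group labels (one curve per group); a single curve
#'   when omitted.
#' @return Named list of `data.frame`s, one per group, with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing from 1).
#' @export
km_estimate <- function(times, events, groups = NULL) {
  stopifnot(length(times) == length(events))
  if (is.null(groups)) groups <- rep("all", length(times))
  g <- factor(groups)
  if (any(table(g) == 0)) stop("empty group in km_estimate")
  out <- lapply(levels(g), function(lev) {
    idx <- g == lev
    sf <- survfit(Surv(times[idx], events[idx]) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               n_censor = sf$n.censor, surv = sf$surv)
  })
  names(out) <- levels(g)
  out
}

#' Log-rank test for survival differences between groups
#'
#' Standard (unweighted) log-rank; p-value from a chi-square distribution
#' with (number of groups - 1) degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param groups Group labels, at least two distinct values.
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("log-rank test needs >= 2 groups")
  if (any(table(g) == 0)) stop("empty group in log-rank test")
  if (sum(events) < 1) stop("log-rank test needs >= 1 event")
  sd <- survdiff(Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration p-value for small tie-free samples, otherwise the
#' normal approximation with tie correction (no continuity correction);
#' two-sided throughout.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return List with `statistic` (rank-sum W for `x`) and `p`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    # every observation tied: no evidence of a shift in either direction
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation with strength category
#'
#' Categories follow the usual cuts on |r|: weak below 0.3, moderate between
#' 0.3 and 0.8, strong above 0.8. The cuts are strict inequalities, so the
#' boundary values 0.3 and 0.8 fall in the lower category.
#'
#' @param x,y Paired numeric vectors, length >= 3, neither constant.
#' @param thresholds Length-2 cuts on |r| (default `c(0.3, 0.8)`).
#' @return List with `r` and `category` in `{"weak","moderate","strong"}`.
#' @export
pearson_with_category <- function(x, y, thresholds = c(0.3, 0.8)) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  r <- cor(x, y, method = "pearson")
  a <- abs(r)
  category <- if (a > thresholds[2]) "strong"
              else if (a > thresholds[1]) "moderate"
              else "weak"
  list(r = r, category = category)
}
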