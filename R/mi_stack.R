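# Chained-equation multiple imputation of clinical covariates, stacking of
# the completed datasets, and weighted Cox fitting on the stack with
# subject-clustered sandwich variance.

clinical_core_cols <- c("sample_id", "os_time", "os_event", "radiotherapy")

covariate_columns <- function(clin) {
  setdiff(names(clin), clinical_core_cols)
}

#' Partition covariates by imputability
#'
#' Covariates with a positive missing fraction below the cap are imputable;
#' those at or above the cap are excluded from the adjustment pool; fully
#' observed covariates pass through untouched.
#'
#' @param clin Clinical `data.frame`.
#' @param cap Missingness cap (fraction; default 0.20).
#' @return List with `imputable`, `excluded`, `complete` (character vectors)
#'   and `fractions` (named missing fractions).
#' @export
select_imputable <- function(clin, cap = 0.20) {
  covs <- covariate_columns(clin)
  frac <- vapply(clin[covs], function(x) mean(is.na(x)), numeric(1))
  excluded <- covs[frac >= cap]
  if (length(excluded))
    message("excluding covariate(s) above the missingness cap: ",
            paste(sprintf("%s (%.0f%%)", excluded, 100 * frac[excluded]),
                  collapse = ", "))
  list(imputable = covs[frac > 0 & frac < cap],
       excluded = excluded,
       complete = covs[frac == 0],
       fractions = frac)
}

# one chained-equations pass producing a single completed copy
impute_once <- function(clin, targets, predictors, cycles, pmm_k) {
  d <- clin
  miss <- lapply(targets, function(v) which(is.na(clin[[v]])))
  names(miss) <- targets
  # initialize by random draws from the observed values
  for (v in targets) {
    obs <- d[[v]][!is.na(d[[v]])]
    d[[v]][miss[[v]]] <- sample(obs, length(miss[[v]]), replace = TRUE)
  }
  aux <- data.frame(.log_time = log(clin$os_time), .event = clin$os_event,
                    .rt = clin$radiotherapy)
  for (cyc in seq_len(cycles)) {
    for (v in targets) {
      mis_idx <- miss[[v]]
      if (!length(mis_idx)) next
      pred_df <- cbind(d[setdiff(predictors, v)], aux)
      X <- model.matrix(~ ., data = pred_df)
      obs_idx <- setdiff(seq_len(nrow(d)), mis_idx)
      y <- d[[v]]
      if (is.numeric(y)) {
        # predictive mean matching with a posterior draw of the coefficients
        fit <- lm.wfit(X[obs_idx, , drop = FALSE], y[obs_idx],
                       w = rep(1, length(obs_idx)))
        keep <- !is.na(fit$coefficients)
        Xk <- X[, keep, drop = FALSE]
        beta <- fit$coefficients[keep]
        res <- fit$residuals
        df_res <- length(obs_idx) - sum(keep)
        sigma2 <- sum(res^2) / max(df_res, 1)
        XtX <- crossprod(Xk[obs_idx, , drop = FALSE])
        V <- tryCatch(chol2inv(chol(XtX)) * sigma2, error = function(e) NULL)
        beta_star <- if (is.null(V)) beta else
          drop(beta + chol(V + diag(1e-10, length(beta))) %*% rnorm(length(beta)))
        yhat_obs <- drop(Xk[obs_idx, , drop = FALSE] %*% beta)
        yhat_mis <- drop(Xk[mis_idx, , drop = FALSE] %*% beta_star)
        k <- min(pmm_k, length(obs_idx))
        donors <- vapply(yhat_mis, function(mu) {
          nn <- order(abs(yhat_obs - mu))[seq_len(k)]
          obs_idx[sample(nn, 1)]
        }, integer(1))
        d[[v]][mis_idx] <- y[donors]
      } else {
        lev <- levels(y)
        yo <- droplevels(y[obs_idx])
        if (nlevels(yo) < 2) {
          # single observed level: nothing to model
          d[[v]][mis_idx] <- factor(rep(levels(yo), length(mis_idx)), levels = lev)
          next
        }
        if (nlevels(yo) == 2) {
          fit <- suppressWarnings(
            glm.fit(X[obs_idx, , drop = FALSE], as.integer(yo) - 1L,
                    family = stats::binomial()))
          eta <- drop(X[mis_idx, , drop = FALSE] %*%
                        ifelse(is.na(fit$coefficients), 0, fit$coefficients))
          p1 <- plogis(eta)
          draw <- rbinom(length(mis_idx), 1, p1)
          d[[v]][mis_idx] <- factor(levels(yo)[draw + 1L], levels = lev)
        } else {
          tmp <- data.frame(.y = yo, pred_df[obs_idx, , drop = FALSE])
          fit <- nnet::multinom(.y ~ ., data = tmp, trace = FALSE)
          probs <- predict(fit, newdata = pred_df[mis_idx, , drop = FALSE],
                           type = "probs")
          if (is.null(dim(probs))) probs <- rbind(probs)
          drawn <- apply(probs, 1, function(p) sample(colnames(probs), 1, prob = p))
          d[[v]][mis_idx] <- factor(drawn, levels = lev)
        }
      }
    }
  }
  d
}

#' Chained-equation multiple imputation of clinical covariates
#'
#' Fills missing covariate cells by iterated conditional models (10 cycles
#' by default): predictive mean matching with 5 donors for continuous
#' covariates, logistic or multinomial-logistic draws for categorical ones.
#' The survival outcome (event indicator and log time) and radiotherapy are
#' always included as predictors, the standard recommendation when the
#' imputed covariates feed a survival model. Survival time, event status and
#' radiotherapy themselves are never imputed. Produces M independent
#' completed copies; reproducible given the seed.
#'
#' @param clin Clinical `data.frame` (no missing `os_time`, `os_event`,
#'   `radiotherapy`).
#' @param M Number of imputations (default 10).
#' @param seed Integer seed.
#' @param cycles Chained-equation cycles per imputation (default 10).
#' @param pmm_k Predictive-mean-matching donor count (default 5).
#' @param covariates Covariates to impute/use; defaults to every non-core
#'   column.
#' @return Object of class `mi_set`: list with `imputations` (list of M
#'   completed `data.frame`s), `missing_pattern` (logical matrix of the
#'   originally missing covariate cells), `M`.
#' @export
impute_chained <- function(clin, M = 10L, seed = 1L, cycles = 10L, pmm_k = 5L,
                           covariates = NULL) {
  stopifnot(M >= 1, !anyNA(clin$os_time), !anyNA(clin$os_event),
            !anyNA(clin$radiotherapy))
  covs <- if (is.null(covariates)) covariate_columns(clin) else covariates
  for (v in covs) {
    x <- clin[[v]]
    if (is.factor(x) && anyNA(x)) {
      never_obs <- setdiff(levels(x), unique(as.character(x[!is.na(x)])))
      if (length(never_obs))
        stop("covariate '", v, "' has level(s) never observed: ",
             paste(never_obs, collapse = ", "))
    }
    if (all(is.na(x))) stop("covariate '", v, "' is entirely missing")
  }
  targets <- covs[vapply(clin[covs], anyNA, logical(1))]
  pattern <- vapply(covs, function(v) is.na(clin[[v]]), logical(nrow(clin)))
  pattern <- matrix(pattern, nrow = nrow(clin), dimnames = list(NULL, covs))

  imps <- vector("list", M)
  if (!length(targets)) {
    imps <- rep(list(clin), M)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    sub_seeds <- sample.int(.Machine$integer.max, M)
    for (m in seq_len(M)) {
      set.seed(sub_seeds[m])
      imps[[m]] <- impute_once(clin, targets, covs, cycles, pmm_k)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  structure(list(imputations = imps, missing_pattern = pattern, M = M,
                 targets = targets),
            class = "mi_set")
}

#' Stack multiply-imputed datasets
#'
#' Concatenates the M completed copies with per-record weight 1/M and the
#' subject id carried through, the input expected by the weighted Cox fit
#' with subject-clustered variance.
#'
#' @param mi An `mi_set` from [impute_chained()], or a plain list of
#'   completed `data.frame`s sharing sample ids.
#' @return A `data.frame` of class `imputation_stack` with extra columns
#'   `.imp` and `.weight`; weights sum to the number of subjects.
#' @export
stack_imputations <- function(mi) {
  if (inherits(mi, "mi_set")) {
    imps <- mi$imputations
    pattern <- mi$missing_pattern
  } else {
    imps <- mi
    pattern <- NULL
  }
  M <- length(imps)
  stopifnot(M >= 1)
  ids <- imps[[1]]$sample_id
  for (m in seq_along(imps)) {
    if (!identical(imps[[m]]$sample_id, ids))
      stop("imputed copies do not share sample ids")
    if (!is.null(pattern)) {
      for (v in colnames(pattern)) {
        same <- imps[[m]][[v]][!pattern[, v]] == imps[[1]][[v]][!pattern[, v]]
        if (!all(same))
          stop("observed cells altered across imputations in covariate '", v, "'")
      }
    }
  }
  stack <- do.call(rbind, lapply(seq_len(M), function(m) {
    d <- imps[[m]]
    d$.imp <- m
    d
  }))
  stack$.weight <- 1 / M
  rownames(stack) <- NULL
  attr(stack, "M") <- M
  attr(stack, "n_subjects") <- length(ids)
  class(stack) <- c("imputation_stack", "data.frame")
  stack
}

#' Weighted Cox fit on an imputation stack
#'
#' Delegates to [fit_cox()] with the stack weights (1/M) and subject-
#' clustered sandwich variance, the stacked-imputation analogue of pooling.
#'
#' @param stack An `imputation_stack`.
#' @param covariates Covariate column names.
#' @inheritParams fit_cox
#' @return A `cox_fit`.
#' @export
fit_cox_stacked <- function(stack, covariates, time = "os_time",
                            event = "os_event") {
  fit_cox(stack, covariates, time = time, event = event,
          weights = stack$.weight, cluster = stack$sample_id)
}

# restrict a stack to a set of subjects, keeping weights and class
stack_subset <- function(stack, ids) {
  out <- stack[stack$sample_id %in% ids, , drop = FALSE]
  attr(out, "M") <- attr(stack, "M")
  attr(out, "n_subjects") <- length(unique(out$sample_id))
  class(out) <- class(stack)
  out
}
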