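# Independent brute-force oracles, deliberately written without reference to
# the survival package: direct Efron partial likelihood, hand product-limit /
# log-rank formulas, and exact Wilcoxon enumeration.

# Efron-tie-corrected log partial likelihood for a design matrix X (n x p),
# computed by direct summation over distinct event times.
efron_loglik <- function(beta, time, event, X, weights = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (is.null(weights)) weights <- rep(1, length(time))
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)          # events at t
    R <- which(time >= t)                       # at risk at t
    wD <- weights[D]
    sum_risk <- sum(weights[R] * exp(eta[R]))
    sum_tied <- sum(wD * exp(eta[D]))
    d <- length(D)
    wbar <- mean(wD)
    ll <- ll + sum(wD * eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - wbar * log(sum_risk - (l / d) * sum_tied)
    }
  }
  ll
}

# maximize the Efron partial likelihood by numerical optimization (BFGS from
# zero, very tight tolerance); 1-d problems additionally refined by grid
# bisection so the oracle does not depend on optim's path
maximize_efron <- function(time, event, X, weights = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  p <- ncol(X)
  nll <- function(b) -efron_loglik(b, time, event, X, weights)
  opt <- optim(rep(0, p), nll, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 1000))
  if (p == 1) {
    lo <- opt$par - 0.1; hi <- opt$par + 0.1
    for (iter in 1:60) {
      grid <- seq(lo, hi, length.out = 21)
      vals <- vapply(grid, nll, numeric(1))
      i <- which.min(vals)
      lo <- grid[max(1, i - 1)]; hi <- grid[min(21, i + 1)]
    }
    return((lo + hi) / 2)
  }
  opt$par
}

# hand product-limit estimator: events before censorings at tied times
km_by_hand <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank statistic from the O - E / V formula
logrank_by_hand <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# choose(n1+n2, n1) group assignments (tie-free data)
wilcoxon_exact_enum <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  ranks <- rank(all_v)
  W_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(all_v), n1)
  Ws <- apply(combos, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# small survival fixtures with ties used by the Cox oracle tests
cox_toy_fixtures <- function() {
  list(
    list(time = c(4, 3, 1, 1, 2, 2, 3),
         event = c(1, 1, 1, 0, 1, 1, 0),
         X = c(0, 2, 1, 1, 1, 0, 0)),
    list(time = c(6, 7, 10, 15, 19, 25, 6, 6, 10, 12),
         event = c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1),
         X = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)),
    list(time = c(1, 1, 2, 2, 3, 4, 5, 5, 8, 8, 9, 11),
         event = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1),
         X = c(0.5, -1, 2, 0, 1, -0.5, 0, 1.5, -2, 1, 0.3, -0.7)),
    list(time = c(2, 2, 2, 4, 4, 6, 7, 9, 9, 9, 12, 14, 17, 20),
         event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 0),
         X = cbind(x1 = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
                   x2 = c(0.2, -0.4, 1.1, 0.0, -0.9, 0.7, 0.3, -1.2,
                          0.5, 0.8, -0.3, 1.4, -0.6, 0.1))),
    list(time = c(3, 3, 3, 5, 5, 6, 8, 8, 10, 12, 12, 15, 18, 21, 21, 24,
                  27, 30, 33, 36, 36, 40, 44, 48, 50),
         event = c(1, 1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 1,
                   1, 0, 1, 1, 1, 0, 1),
         X = cbind(x1 = rep(c(0, 1), length.out = 25),
                   x2 = sin(1:25)))
  )
}
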