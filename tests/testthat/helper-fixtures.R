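# Shared fixture builders: everything is generated in code at test time.

# small, fast synthetic configuration for pipeline-shape tests
tiny_config <- function(seed = 1, n = 300, ...) {
  synthetic_config(
    n_patients = n,
    genes = standard_gene_panel(n_null = 4, n_type1 = 2, n_type2 = 2),
    seed = seed, ...)
}

# fast run configuration: fewer imputations keep unit tests quick
fast_rs_config <- function(seed = 1, ...) {
  rs_config(n_imputations = 3L, seed = seed, ...)
}

# an eligible cohort_dataset plus its truth table
tiny_cohort <- function(seed = 1, n = 300, ...) {
  coh <- generate_cohort(tiny_config(seed = seed, n = n, ...))
  list(cohort = apply_eligibility(coh$expression, coh$clinical, rs_config()),
       truth = coh$truth)
}

# write a small expression matrix + clinical table to temp TSV files
write_tiny_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  coh <- generate_cohort(tiny_config(n = 60))
  ep <- file.path(dir, "expr.tsv")
  cp <- file.path(dir, "clin.tsv")
  write_expression(coh$expression, ep)
  write_clinical(coh$clinical, cp)
  list(expr = ep, clin = cp, cohort = coh)
}

# clinical frame with controllable MCAR missingness on a continuous and a
# categorical covariate; survival driven by the continuous covariate
make_missing_clin <- function(n, beta = log(2), miss_x = 0.1, miss_g = 0,
                              seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  grp <- factor(sample(c("a", "b", "c"), n, replace = TRUE),
                levels = c("a", "b", "c"))
  t <- rexp(n, rate = 0.05 * exp(beta * x))
  cens <- rexp(n, rate = 0.01)
  d <- data.frame(sample_id = sprintf("P%05d", seq_len(n)),
                  os_time = pmin(t, cens) + 0.01,
                  os_event = as.integer(t <= cens),
                  radiotherapy = rbinom(n, 1, 0.5),
                  x = x, grp = grp, stringsAsFactors = FALSE)
  d$x[runif(n) < miss_x] <- NA
  d$grp[runif(n) < miss_g] <- NA
  d
}

# schema matching the generator's clinical table
tiny_schema <- function() {
  list(cov_continuous("age"),
       cov_categorical("age_group", levels = c("<60", ">=60")),
       cov_categorical("chemotherapy", levels = c("No", "Yes")),
       cov_categorical("stage", levels = c("I/II", "III/IV")))
}
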