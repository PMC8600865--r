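test_that("gene-gene correlation matrices are symmetric with consistent categories", {
  tc <- tiny_cohort(seed = 3, n = 400)
  cohort <- tc$cohort
  # plant a near-duplicate gene pair
  cohort$expression["G002", ] <- cohort$expression["G001", ] +
    rnorm(ncol(cohort$expression), 0, 0.01)
  genes <- rownames(cohort$expression)[1:5]
  cc <- rs_correlation(cohort, genes)
  expect_equal(cc$r, t(cc$r))
  expect_equal(unname(diag(cc$r)), rep(1, 5))
  expect_gt(cc$r["G001", "G002"], 0.99)
  expect_identical(cc$category["G001", "G002"], "strong")
  # categories agree with recomputation from the r matrix
  recat <- ifelse(abs(cc$r) > 0.8, "strong", ifelse(abs(cc$r) > 0.3, "moderate", "weak"))
  expect_identical(cc$category, recat)
  # independent simulated genes at n = 400: off-diagonal correlations weak
  cc2 <- rs_correlation(tc$cohort, rownames(tc$cohort$expression)[3:8])
  off <- cc2$r[upper.tri(cc2$r)]
  expect_true(all(abs(off) < 0.3))
})

test_that("patient clustering recovers well-separated blobs and honors exclusions", {
  set.seed(10)
  n <- 120
  blob <- rep(1:2, each = n / 2)
  expr <- rbind(gA = rnorm(n, mean = ifelse(blob == 1, 0, 5)),
                gB = rnorm(n, mean = ifelse(blob == 1, 0, 5)),
                gC = rnorm(n, mean = ifelse(blob == 1, 0, 5)),
                gX = rnorm(n))
  colnames(expr) <- sprintf("s%03d", 1:n)
  clin <- data.frame(sample_id = colnames(expr), os_time = rexp(n, 0.01) + 1,
                     os_event = rbinom(n, 1, 0.7), radiotherapy = rbinom(n, 1, 0.5),
                     stringsAsFactors = FALSE)
  cd <- cohort_dataset(expr, clin)

  cl <- cluster_patients(cd, c("gA", "gB", "gC", "gX"), k = 2, exclusions = "gX")
  expect_identical(sort(cl$genes), c("gA", "gB", "gC"))
  agree <- max(mean(cl$labels == blob), mean(cl$labels == 3 - blob))
  expect_gt(agree, 0.95)

  # invariance to gene and patient order (up to label permutation)
  cd2 <- cohort_dataset(expr[c(3, 1, 4, 2), rev(colnames(expr))],
                        clin[rev(seq_len(n)), ])
  cl2 <- cluster_patients(cd2, c("gA", "gB", "gC"), k = 2)
  l1 <- cl$labels[colnames(expr)]
  l2 <- cl2$labels[colnames(expr)]
  expect_true(all(l1 == l2) || all(l1 == 3 - l2))

  expect_error(cluster_patients(cd, c("gA", "gB"), k = 200), "fewer patients")
  cd$expression["gA", ] <- 1
  expect_error(cluster_patients(cd, c("gA", "gB"), k = 2), "degenerate gene")
})

test_that("per-cluster survival comparison isolates the benefiting cluster", {
  set.seed(11)
  n <- 600
  blob <- rep(1:2, each = n / 2)
  expr <- rbind(gA = rnorm(n, ifelse(blob == 1, 0, 4)),
                gB = rnorm(n, ifelse(blob == 1, 0, 4)))
  colnames(expr) <- sprintf("s%03d", 1:n)
  rt <- rbinom(n, 1, 0.5)
  # radiotherapy benefit only in blob 2
  rate <- 0.01 * exp(log(0.25) * rt * (blob == 2))
  t <- rexp(n, rate); cens <- pmin(rexp(n, 0.002), 400)
  clin <- data.frame(sample_id = colnames(expr),
                     os_time = pmin(t, cens) + 0.1,
                     os_event = as.integer(t <= cens), radiotherapy = rt,
                     stringsAsFactors = FALSE)
  cd <- cohort_dataset(expr, clin)
  cl <- cluster_patients(cd, c("gA", "gB"), k = 2)
  res <- compare_cluster_survival(cd, cl)
  expect_identical(nrow(res$per_cluster), 2L)
  expect_length(res$km[[as.character(res$per_cluster$cluster[1])]], 2)  # RT and NRT curves
  # exactly one cluster shows the radiotherapy benefit
  benefit_cluster <- cl$labels[which(blob == 2)[1]]
  expect_identical(res$rs_cluster, unname(benefit_cluster))

  # k = 1 reduces to the cohort-wide RT log-rank
  one <- setNames(rep(1L, n), colnames(expr))
  res1 <- compare_cluster_survival(cd, one)
  whole <- logrank_test(clin$os_time, clin$os_event, clin$radiotherapy)
  expect_equal(res1$per_cluster$chisq, whole$statistic)

  # an empty treatment-by-cluster cell is reported not evaluable
  clin2 <- clin
  clin2$radiotherapy[cl$labels[clin$sample_id] == 1] <- 1
  cd2 <- cohort_dataset(expr, clin2)
  res2 <- compare_cluster_survival(cd2, cl$labels)
  expect_false(all(res2$per_cluster$evaluable))
})

test_that("extreme-survivor contrast compares planted expression differences", {
  set.seed(12)
  n <- 400
  benefit <- rbinom(n, 1, 0.5)  # latent benefit stratum
  expr <- rbind(gUp = rnorm(n, 5 + 2 * benefit),   # higher in the benefit stratum
                gFlat = rnorm(n, 5),
                gConst = rep(3, n))
  colnames(expr) <- sprintf("s%03d", 1:n)
  rt <- rep(1, n)
  rate <- 0.002 * exp(log(0.15) * benefit)  # benefit stratum survives much longer
  t <- rexp(n, rate)
  clin <- data.frame(sample_id = colnames(expr),
                     os_time = round(pmin(t, 4000), 1) + 0.1,
                     os_event = as.integer(t <= 4000), radiotherapy = rt,
                     stringsAsFactors = FALSE)
  cd <- cohort_dataset(expr, clin)

  res <- extreme_survivor_contrast(cd, c("gUp", "gFlat", "gConst"),
                                   rt_status = 1, long_cut = 8 * 365,
                                   short_cut = 3 * 365)
  expect_gt(attr(res, "n_alive"), 0)
  expect_gt(attr(res, "n_dead"), 0)
  up <- res[res$gene == "gUp", ]
  expect_gt(up$median_alive, up$median_dead)
  expect_lt(up$p, 0.05)
  expect_equal(res[res$gene == "gConst", "p"], 1)

  expect_error(extreme_survivor_contrast(cd, "gUp", 1, long_cut = 100,
                                         short_cut = 200), "exceed")
})
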