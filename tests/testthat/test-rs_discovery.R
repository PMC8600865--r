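make_panel <- function(a, b, c_, d, hrs = c(A = 0.5, B = 0.5, C = 0.6, D = 1.4)) {
  sc <- function(h, hr) list(evaluable = TRUE, holds = h, hr = hr,
                             lower = hr * 0.7, upper = hr * 1.4,
                             p = if (h) 0.01 else 0.5, retained = h, reason = "")
  structure(list(gene_id = "g", A = sc(a, hrs[["A"]]), B = sc(b, hrs[["B"]]),
                 C = sc(c_, hrs[["C"]]), D = sc(d, hrs[["D"]]),
                 adjusters = character(0),
                 group_sizes = c(HRT = 10, LRT = 10, HNRT = 10, LNRT = 10)),
            class = "scenario_panel")
}

test_that("median dichotomization splits at the median with ties going low", {
  expr <- matrix(c(1, 2, 3, 4,
                   1, 2, 2, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  clin <- data.frame(sample_id = sprintf("s%d", 1:4), os_time = c(10, 20, 30, 40),
                     os_event = c(1, 1, 0, 1), radiotherapy = c(1, 0, 1, 0),
                     stringsAsFactors = FALSE)
  cd <- cohort_dataset(expr, clin)

  d1 <- dichotomize_gene(cd, "g1")
  expect_equal(d1$threshold, 2.5)
  expect_identical(unname(d1$label), c("L", "L", "H", "H"))

  d2 <- dichotomize_gene(cd, "g2")
  expect_equal(d2$threshold, 2)
  expect_identical(unname(d2$label), c("L", "L", "L", "H"))  # ties at the median go low
  expect_equal(sum(d2$group_sizes), 4)
  expect_equal(unname(d2$group_sizes["HNRT"] + d2$group_sizes["LNRT"]), 2)

  cd$expression["g1", ] <- 7
  expect_error(dichotomize_gene(cd, "g1"), "degenerate gene")
})

test_that("classification implements the A/B + exactly-one-of-C/D rule", {
  # A & C only: Type I, RGH
  call <- classify_rs(make_panel(TRUE, FALSE, TRUE, FALSE))
  expect_true(call$is_rs)
  expect_identical(call$rs_type, "I")
  expect_identical(call$direction, "RGH")

  # A & D only: Type II, RGH
  call <- classify_rs(make_panel(TRUE, FALSE, FALSE, TRUE))
  expect_true(call$is_rs)
  expect_identical(call$rs_type, "II")
  expect_identical(call$direction, "RGH")

  # B & C: Type I, RGL; B & D: Type II, RGL
  expect_identical(classify_rs(make_panel(FALSE, TRUE, TRUE, FALSE))$direction, "RGL")
  expect_identical(classify_rs(make_panel(FALSE, TRUE, FALSE, TRUE))$rs_type, "II")

  # A & B with one interaction scenario: direction "both"
  expect_identical(classify_rs(make_panel(TRUE, TRUE, TRUE, FALSE))$direction, "both")

  # C and D both holding: ambiguous, not RS
  call <- classify_rs(make_panel(TRUE, FALSE, TRUE, TRUE))
  expect_false(call$is_rs)
  expect_true(call$ambiguous)
  expect_identical(call$rs_type, "none")

  # neither interaction scenario: not RS
  expect_false(classify_rs(make_panel(TRUE, TRUE, FALSE, FALSE))$is_rs)
  # interaction without treatment benefit in either half: not RS
  expect_false(classify_rs(make_panel(FALSE, FALSE, TRUE, FALSE))$is_rs)

  # direction warning when the interaction HR contradicts the benefit group:
  # RGH Type I should have scenario-C HR < 1 (high better under RT)
  warn <- classify_rs(make_panel(TRUE, FALSE, TRUE, FALSE,
                                 hrs = c(A = 0.5, B = 0.5, C = 1.6, D = 1)))
  expect_true(warn$is_rs)  # significance-based rules: the call stands
  expect_true(warn$direction_warning)
})

test_that("discovery recovers planted interactions and is seed-deterministic", {
  tc <- tiny_cohort(seed = 5, n = 1000)
  cfg <- fast_rs_config(seed = 42)
  calls <- discover_rs(tc$cohort, config = cfg)
  expect_identical(nrow(calls), 8L)

  # structural invariants on every output
  expect_false(any(calls$is_rs & calls$C_holds & calls$D_holds))
  expect_true(all(calls$rs_type[calls$is_rs] %in% c("I", "II")))
  expect_true(all(calls$rs_type[!calls$is_rs] == "none"))
  expect_true(all(calls$HRT + calls$LRT + calls$HNRT + calls$LNRT ==
                    ncol(tc$cohort$expression)))

  # planted effects dominate the calls at this n
  sc <- score_recovery(calls, tc$truth)
  expect_gte(sc$sensitivity, 0.5)
  if (sc$n_true_positive > 0) expect_gte(sc$type_accuracy, 0.5)

  # same seed reproduces the identical call table
  calls2 <- discover_rs(tc$cohort, config = cfg)
  expect_identical(calls, calls2)
})

test_that("discovery refuses cohorts failing the radiotherapy screen", {
  coh <- generate_cohort(synthetic_config(
    seed = 2, n_patients = 400, beta_rt = log(1.8),
    genes = standard_gene_panel(n_null = 4, n_type1 = 0, n_type2 = 0)))
  cd <- apply_eligibility(coh$expression, coh$clinical, rs_config())
  expect_error(discover_rs(cd, config = fast_rs_config()),
               "radiotherapy-protective screen")
})

test_that("negating a gene's expression swaps A/B and inverts the C/D effect direction", {
  tc <- tiny_cohort(seed = 9, n = 500)
  cohort <- tc$cohort
  clin <- cohort$clinical
  sel <- select_imputable(clin, 0.2)
  mi <- impute_chained(clin, M = 2, seed = 3,
                       covariates = c(sel$complete, sel$imputable))
  stack <- stack_imputations(mi)
  adjusters <- c("age_group", "stage")
  g <- rownames(cohort$expression)[5]

  p1 <- evaluate_scenarios(stack, dichotomize_gene(cohort, g), adjusters)

  flipped <- cohort
  flipped$expression[g, ] <- -flipped$expression[g, ]
  p2 <- evaluate_scenarios(stack, dichotomize_gene(flipped, g), adjusters)

  # H and L subsets exchange exactly (continuous expression: no ties)
  expect_equal(p2$A[c("holds", "hr", "p")], p1$B[c("holds", "hr", "p")])
  expect_equal(p2$B[c("holds", "hr", "p")], p1$A[c("holds", "hr", "p")])
  # the high-vs-low indicator flips: HRs invert, significance unchanged
  expect_equal(p2$C$hr, 1 / p1$C$hr, tolerance = 1e-6)
  expect_equal(p2$D$hr, 1 / p1$D$hr, tolerance = 1e-6)
  expect_equal(p2$C$p, p1$C$p, tolerance = 1e-6)
  expect_identical(classify_rs(p2)$is_rs, classify_rs(p1)$is_rs)
})

test_that("call-table intersection follows set algebra", {
  tab <- function(genes_rs, types = "I", dirs = "RGH") {
    data.frame(gene = c(genes_rs, "zz"), is_rs = c(rep(TRUE, length(genes_rs)), FALSE),
               rs_type = c(rep(types, length.out = length(genes_rs)), "none"),
               direction = c(rep(dirs, length.out = length(genes_rs)), "none"),
               stringsAsFactors = FALSE)
  }
  out <- intersect_calls(list(X = tab(c("g1", "g2")), Y = tab(c("g2", "g3"))))
  expect_identical(out$common, "g2")
  out2 <- intersect_calls(list(X = tab("g1"), Y = tab("g2")))
  expect_length(out2$common, 0)
  out3 <- intersect_calls(list(X = tab(c("g1", "g2", "g3")),
                               Y = tab(c("g1", "g2", "g4")),
                               Z = tab(c("g2", "g1", "g5"))))
  expect_identical(sort(out3$common), c("g1", "g2"))
  expect_identical(sort(out3$pairwise[["X&Y"]]), c("g1", "g2"))

  # type filter restricts the sets
  out4 <- intersect_calls(list(X = tab(c("g1", "g2"), types = c("I", "II")),
                               Y = tab(c("g1", "g2"), types = c("II", "II"))),
                          filter = "type2")
  expect_identical(out4$common, "g2")
})
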