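test_that("experiment generation is seed-deterministic", {
  spec <- synth_experiment_spec(toy_p53_network(), seed = 5)
  a <- generate_expression_experiment(spec)
  b <- generate_expression_experiment(spec)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
})

test_that("fully concordant experiments validate near 100% correct", {
  net <- random_network(120, 0.05, 0.3, seed = 8)
  spec <- synth_experiment_spec(net, concordance = 1, effect_size = 2,
                                noise_sd = 0.1, n_replicates = 5, seed = 9)
  exp <- generate_expression_experiment(spec)
  de <- differential_expression(exp$matrix, exp$groups, "control", "treated")
  summary <- suppressMessages(
    run_lssa_validation(net, de, exp$scenario_pair))
  expect_gte(summary$pct_correct, 95)
})

test_that("zero concordance gives a correct fraction near zero", {
  net <- random_network(120, 0.05, 0.3, seed = 10)
  spec <- synth_experiment_spec(net, concordance = 0, effect_size = 2,
                                noise_sd = 0.1, n_replicates = 5, seed = 11)
  exp <- generate_expression_experiment(spec)
  de <- differential_expression(exp$matrix, exp$groups, "control", "treated")
  summary <- suppressMessages(
    run_lssa_validation(net, de, exp$scenario_pair))
  # every intended call differs from E_mod, so only DE-calling noise can
  # produce an accidental match
  expect_lte(summary$pct_correct, 10)
})

test_that("invalid experiment specs are rejected", {
  net <- toy_p53_network()
  expect_error(synth_experiment_spec(net, concordance = 1.2), "concordance")
  expect_error(synth_experiment_spec(net, effect_size = 0.3),
               "exceed log2")
})

test_that("synthetic cohorts honour composition, censoring and invariants", {
  spec <- synth_cohort_spec(n_patients = 40,
                            group_fractions = c(wt_chemo = 0.4,
                                                wt_nochemo = 0.3,
                                                mut_chemo = 0.1,
                                                mut_nochemo = 0.2),
                            censoring_fraction = 0.25, seed = 2)
  coh <- generate_cohort(spec, toy_p53_network())
  rec <- coh$records
  expect_equal(nrow(rec), 40)
  expect_true(all(rec$survival_days > 0))
  expect_true(all(rec$stage %in% 1:4))
  expect_equal(sum(rec$event == 0), 10)  # exactly the requested fraction
  expect_true(all(dim(coh$scores) == c(length(model_genes(toy_p53_network())),
                                       40)))
  # determinism
  coh2 <- generate_cohort(spec, toy_p53_network())
  expect_identical(coh$expression, coh2$expression)
  expect_identical(coh$records, coh2$records)
})

test_that("default cohort composition mirrors a 71-patient surgical series", {
  spec <- synth_cohort_spec(seed = 3)
  coh <- generate_cohort(spec, toy_p53_network())
  groups <- suppressWarnings(stratify_patients(coh$records))
  expect_equal(unname(vapply(groups, nrow, 0L)), c(27L, 26L, 1L, 17L))
})

test_that("cohort generation rejects unknown genes and bad censoring", {
  expect_error(synth_cohort_spec(censoring_fraction = 1), "censoring")
  spec <- synth_cohort_spec(driver_genes = c(NOPE = 0.5), seed = 1)
  expect_error(generate_cohort(spec, toy_p53_network()), "absent")
})

test_that("a designated stage-effect gene is flagged by the staging analysis", {
  spec <- synth_cohort_spec(n_patients = 80,
                            group_fractions = c(wt_chemo = 0.25,
                                                wt_nochemo = 0.25,
                                                mut_chemo = 0.25,
                                                mut_nochemo = 0.25),
                            stage_effect_genes = c(ZMAT3 = 3),
                            censoring_fraction = 0, seed = 6)
  coh <- generate_cohort(spec, toy_p53_network())
  out <- suppressMessages(compare_stages(coh$scores, coh$records, "ZMAT3"))
  expect_lt(out$anova_p, 0.01)
  expect_equal(out$direction, "positive")
})
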