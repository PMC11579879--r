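test_that("Bonferroni thresholds reproduce the standard panel corrections", {
  expect_equal(signif(bonferroni_threshold(0.05, 191), 3), 2.62e-4)
  expect_equal(round(bonferroni_threshold(0.05, 3), 4), 0.0167)
  expect_equal(signif(bonferroni_threshold(0.05, 1398), 3), 3.58e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("a single-instrument exposure yields Wald-only output, no sensitivity", {
  sim <- sim_screen(n_exposures = 1, theta = 0.5, snps_per_exposure = 1,
                    seed = 3)
  scr <- run_screen(sim$exposures, sim$outcome,
                    config = screen_config(seed = 3))
  expect_equal(scr$results$method, "wald_ratio")
  expect_equal(scr$results$nsnp, 1L)
  expect_true(is.na(scr$results$q))
  expect_true(is.na(scr$results$egger_intercept))
  expect_equal(scr$m_tested, 1L)
})

test_that("a causal exposure among nulls is the sole hit and replicates", {
  sim <- sim_screen(n_exposures = 20, theta = c(0.5, rep(0, 19)),
                    replication = TRUE, seed = 8)
  scr <- run_screen(sim$exposures, sim$outcome, replication = sim$replication,
                    config = screen_config(seed = 8))
  expect_equal(scr$hits, "exposure_1")
  expect_equal(scr$m_tested, 20L)
  expect_equal(scr$bonferroni_threshold, 0.05 / 20)
  expect_true(scr$replication$replicated)
  expect_true(scr$replication$direction_consistent)
})

test_that("mediation runs on surviving hits with the mediator's own instruments", {
  sim <- sim_screen(n_exposures = 5, theta = c(0.6, rep(0, 4)),
                    snps_per_exposure = 2, b2 = 0.4, b3 = 0.5,
                    replication = TRUE, seed = 21)
  # the mediator needs instruments of its own for step 2: reuse another
  # simulated trait as the mediator's GWAS including its direct variants
  med_sim <- sim_study(n_snps = 10, theta = 0.5, seed = 22)
  mediator <- mrscreen:::new_sumstats(
    dplyr::bind_rows(tibble::as_tibble(sim$mediator),
                     tibble::as_tibble(med_sim$exposure)),
    "mediator", "quantitative")
  outcome <- mrscreen:::new_sumstats(
    dplyr::bind_rows(tibble::as_tibble(sim$outcome),
                     tibble::as_tibble(med_sim$outcome)),
    "outcome", "binary")
  scr <- run_screen(sim$exposures, outcome, replication = sim$replication,
                    mediator = mediator, config = screen_config(seed = 21))
  expect_false(is.null(scr$mediation))
  # with a shared mediated path every exposure carries a b2*b3 effect, so
  # mediation rows cover exactly the replicated hits
  expect_setequal(scr$mediation$exposure,
                  scr$replication$exposure[scr$replication$replicated])
  expect_true("exposure_1" %in% scr$mediation$exposure)
  expect_equal(scr$mediation$beta_indirect,
               scr$mediation$beta_exp_to_med * scr$mediation$beta_med_to_out,
               tolerance = 1e-12)
})

test_that("screen reports are reproducible from the config seed", {
  sim <- sim_screen(n_exposures = 6, theta = c(0.5, rep(0, 5)),
                    snps_per_exposure = 4, seed = 12)
  cfg <- screen_config(n_boot = 50, seed = 99)
  a <- run_screen(sim$exposures, sim$outcome, config = cfg)
  b <- run_screen(sim$exposures, sim$outcome, config = cfg)
  expect_identical(as.data.frame(a$results), as.data.frame(b$results))
})

test_that("unanalyzable exposures are skipped with reasons, all-fail is fatal", {
  sim <- sim_screen(n_exposures = 3, theta = 0.4, seed = 6)
  weak <- sim$exposures[[2]]
  weak$pvalue <- rep(0.5, nrow(weak)) # nothing genome-wide significant
  exposures <- list(sim$exposures[[1]], weak, sim$exposures[[3]])
  scr <- run_screen(exposures, sim$outcome, config = screen_config(seed = 6))
  expect_equal(scr$m_tested, 2L)
  expect_equal(sum(scr$results$skipped), 1L)
  expect_match(scr$results$skip_reason[scr$results$skipped], "no instruments")
  # nominal panel size still drives the Bonferroni denominator
  expect_equal(scr$bonferroni_threshold, 0.05 / 3)

  all_weak <- lapply(exposures, function(e) {
    e$pvalue <- rep(0.5, nrow(e)); e
  })
  expect_error(run_screen(all_weak, sim$outcome), "no exposure yields")
})

test_that("the m_tested convention can drive the Bonferroni denominator", {
  sim <- sim_screen(n_exposures = 4, theta = 0.4, seed = 30)
  weak <- sim$exposures[[4]]
  weak$pvalue <- rep(0.5, nrow(weak))
  exposures <- c(sim$exposures[1:3], list(weak))
  scr_nom <- run_screen(exposures, sim$outcome,
                        config = screen_config(seed = 1))
  scr_tested <- run_screen(exposures, sim$outcome,
                           config = screen_config(use_m_tested = TRUE, seed = 1))
  expect_equal(scr_nom$bonferroni_threshold, 0.05 / 4)
  expect_equal(scr_tested$bonferroni_threshold, 0.05 / 3)
  # a nominal panel larger than the supplied list is honoured
  scr191 <- run_screen(exposures, sim$outcome,
                       config = screen_config(m_nominal = 191, seed = 1))
  expect_equal(signif(scr191$bonferroni_threshold, 3), 2.62e-4)
})

test_that("the family-wise error rate under the global null is controlled", {
  fwer <- vapply(1:200, function(s) {
    sim <- sim_screen(n_exposures = 20, theta = 0, seed = s + 6000)
    scr <- run_screen(sim$exposures, sim$outcome,
                      config = screen_config(seed = s))
    length(scr$hits) > 0
  }, logical(1))
  # binomial 99% upper bound around alpha = 0.05 at 200 runs
  expect_lte(mean(fwer), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 200))
})

test_that("tidy and glance expose the screening report", {
  sim <- sim_screen(n_exposures = 3, theta = c(0.5, 0, 0), seed = 44)
  scr <- run_screen(sim$exposures, sim$outcome,
                    config = screen_config(seed = 44))
  td <- tidy(scr)
  expect_true(all(c("exposure", "beta", "pvalue", "hit") %in% names(td)))
  gl <- glance(scr)
  expect_equal(gl$m_tested, 3L)
  expect_equal(gl$n_hits, length(scr$hits))
})
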