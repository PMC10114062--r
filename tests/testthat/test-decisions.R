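# literal step-up transcription of the Benjamini-Hochberg definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

test_that("BH adjustment matches hand-computed and oracle values", {
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_fdr(0.02), 0.02)          # m = 1 is unchanged
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(14)
  for (case in 1:200) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("the Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 41), 0.05 / 41)
  # printed as 1.21E-03 at three figures (truncated)
  expect_lt(abs(bonferroni_threshold(0.05, 41) - 1.21e-3), 1e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
})

sens_case <- function(ivw_est = 0.3, fdr_p = 0.01,
                      med = stub_result(0.3, 0.01),
                      mode = stub_result(0.3, 0.01),
                      presso = stub_presso(0.3, 0.01),
                      steiger = stub_result(0.3, 0.01, "ivw_steiger"),
                      egger = stub_egger(0.3, 0.01, intercept_p = 0.5,
                                         i2gx = 0.95),
                      simex = NULL, f = list(mean_F = 30),
                      exposure_type = "continuous", ...) {
  evaluate_sensitivity(stub_result(ivw_est, 1e-6, "ivw_mre"), fdr_p,
                       battery = list(weighted_median = med,
                                      weighted_mode = mode),
                       presso = presso, steiger_ivw = steiger,
                       egger = egger, simex = simex, f_stats = f,
                       exposure_type = exposure_type, ...)
}

test_that("the sensitivity verdict reproduces the staged criteria", {
  # all concordant, significant, strong instruments -> pass
  expect_true(sens_case()$meets_sensitivity)
  # a single discordant direction fails criterion (ii)
  expect_false(sens_case(mode = stub_result(-0.3, 0.01))$meets_sensitivity)
  expect_false(sens_case(med = stub_result(0.3, 0.2))$meets_sensitivity)
  expect_false(sens_case(presso = stub_presso(-0.3, 0.01))$meets_sensitivity)
  expect_false(sens_case(steiger = stub_result(0.3, 0.5))$meets_sensitivity)
  # FDR gate (criterion i)
  expect_false(sens_case(fdr_p = 0.2)$meets_sensitivity)
  # weak instruments fail criterion (iii) for continuous exposures only
  expect_false(sens_case(f = list(mean_F = 5))$meets_sensitivity)
  expect_true(sens_case(f = NULL,
                        exposure_type = "binary")$meets_sensitivity)
})

test_that("the Egger track follows the pleiotropy evidence and the I2GX gates", {
  # no intercept evidence: Egger not required, its direction irrelevant
  r <- sens_case(egger = stub_egger(-0.3, 0.01, intercept_p = 0.2,
                                    i2gx = 0.95))
  expect_equal(unname(r$checks["egger_or_simex"]), "not-required")
  expect_true(r$meets_sensitivity)
  # intercept evidence with high i2gx: plain Egger must agree
  r2 <- sens_case(egger = stub_egger(-0.3, 0.01, intercept_p = 0.01,
                                     i2gx = 0.95))
  expect_false(r2$meets_sensitivity)
  # mid i2gx: the SIMEX result is judged instead
  r3 <- sens_case(egger = stub_egger(-0.3, 0.5, intercept_p = 0.01,
                                     i2gx = 0.75),
                  simex = stub_result(0.3, 0.01, "simex_egger"))
  expect_equal(unname(r3$checks["egger_or_simex"]), "pass")
  expect_true(r3$meets_sensitivity)
  expect_error(sens_case(egger = stub_egger(0.3, 0.01, intercept_p = 0.01,
                                            i2gx = 0.75)),
               "SIMEX")
  # low i2gx: disregarded; strict policy fails, lenient skips
  low <- stub_egger(0.3, 0.01, intercept_p = 0.01, i2gx = 0.4)
  r4 <- sens_case(egger = low)
  expect_equal(unname(r4$checks["egger_or_simex"]), "disregarded")
  expect_false(r4$meets_sensitivity)
  expect_true(sens_case(egger = low,
                        egger_policy = "lenient")$meets_sensitivity)
})

test_that("missing required components raise errors rather than passing", {
  expect_error(sens_case(med = NULL), "weighted_median")
  expect_error(sens_case(presso = NULL), "required")
})

test_that("classification follows the monotone gate chain", {
  ivw <- stub_result(0.3, 1e-6, "ivw_mre")
  # FDR failure stops at none; the model comparison never runs
  r <- classify_pair("X", "Y", "X -> Y", ivw, fdr_p = 0.2)
  expect_equal(r$final_class, "none")
  s_pass <- sens_case()
  r2 <- classify_pair("X", "Y", "X -> Y", ivw, 0.01, s_pass,
                      cause_p = 1e-4, cause_alpha_bonf = 1.21e-3)
  expect_equal(r2$final_class, "cause_confirmed")
  r3 <- classify_pair("X", "Y", "X -> Y", ivw, 0.01, s_pass,
                      cause_p = 0.01, cause_alpha_bonf = 1.21e-3)
  expect_equal(r3$final_class, "mr_sensitivity")
  s_fail <- sens_case(mode = stub_result(-0.3, 0.01))
  r4 <- classify_pair("X", "Y", "X -> Y", ivw, 0.01, s_fail,
                      cause_p = 1e-4, cause_alpha_bonf = 1.21e-3)
  expect_equal(r4$final_class, "mr_main")  # no skipping stages
  rank <- c(none = 0, mr_main = 1, mr_sensitivity = 2, cause_confirmed = 3)
  for (rec in list(r, r2, r3, r4)) {
    if (rec$final_class == "cause_confirmed") {
      expect_true(rec$meets_sensitivity)
    }
    if (rec$meets_sensitivity) expect_gte(rank[rec$final_class], 2)
  }
})

test_that("bidirectionality requires the same class at or above sensitivity", {
  ivw <- stub_result(0.3, 1e-6, "ivw_mre")
  s <- sens_case()
  fwd <- classify_pair("X", "Y", "X -> Y", ivw, 0.01, s, 1e-4, 1.21e-3)
  rev <- classify_pair("Y", "X", "Y -> X", ivw, 0.01, s, 1e-4, 1.21e-3)
  both <- mark_bidirectional(rbind(fwd, rev))
  expect_true(all(both$bidirectional))
  rev2 <- classify_pair("Y", "X", "Y -> X", ivw, 0.2)
  mixed <- mark_bidirectional(rbind(fwd, rev2))
  expect_false(any(mixed$bidirectional))
  only_main <- mark_bidirectional(rbind(
    classify_pair("X", "Y", "X -> Y", ivw, 0.01),
    classify_pair("Y", "X", "Y -> X", ivw, 0.01)))
  expect_false(any(only_main$bidirectional))  # mr_main is below the bar
})

test_that("report tables have the expected shape and consistent counts", {
  empty <- build_report(NULL)
  expect_equal(nrow(empty$mr_table), 0)
  expect_equal(nrow(empty$cause_table), 0)
  expect_true(all(c("n_snps", "ivw_p_fdr") %in% names(empty$mr_table)))

  ivw <- stub_result(0.3, 1e-6, "ivw_mre")
  s <- sens_case()
  recs <- mark_bidirectional(rbind(
    classify_pair("X", "Y", "X -> Y", ivw, 0.01, s, 1e-4, 1.21e-3,
                  category = "anthropometry"),
    classify_pair("Y", "X", "Y -> X", ivw, 0.01, s, 0.5, 1.21e-3,
                  category = "anthropometry")))
  rep <- build_report(recs)
  expect_equal(nrow(rep$mr_table), 2)
  counts <- rep$stage_counts
  all_rows <- counts[counts$category == "all", ]
  expect_true(all(all_rows$n_cause <= all_rows$n_mr_sens))
  expect_true(all(all_rows$n_mr_sens <= all_rows$n_mr_main))
  expect_true(all(all_rows$n_mr_main <= all_rows$n_all))
  expect_equal(sum(counts$n_cause[counts$category == "all"]), 1)
})
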