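test_that("Wald ratios follow the delta method and exclude null instruments", {
  inp <- mr_input(c(1, -1), c(0.1, 0.1), c(0.5, 0.5), c(0.1, 0.1))
  wr <- wald_ratios(inp)
  expect_equal(wr$ratio, c(0.5, -0.5))
  expect_equal(wr$ratio_se, c(0.1, 0.1))
  inp0 <- mr_input(c(1, 0), c(0.1, 0.1), c(0.5, 0.5), c(0.1, 0.1))
  expect_warning(wr0 <- wald_ratios(inp0), "zero exposure effect")
  expect_equal(nrow(wr0), 1)
})

test_that("first-order ratio SEs agree with second order for strong instruments", {
  # second-order delta: var = se_y^2/bx^2 + by^2 se_x^2 / bx^4
  bx <- 1; sex <- 0.04; by <- 0.5; sey <- 0.3
  first <- sey / abs(bx)
  second <- sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)
  expect_lt(abs(second - first) / second, 0.01)
  wr <- wald_ratios(mr_input(bx, sex, by, sey))
  expect_equal(wr$ratio_se, first)
})

test_that("IVW matches the closed-form weighted regression through the origin", {
  inp <- mr_input(c(1, 1), c(0.01, 0.01), c(0.5, 0.7), c(1, 1))
  fit <- mr_ivw(inp)
  expect_equal(fit$estimate, 0.6)
  expect_equal(fit$het$Q, 0.02)
  expect_equal(fit$het$i2_percent, 0)      # Q < df
  expect_equal(fit$se, sqrt(0.5))          # floored at the fixed-effect SE
  expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
})

test_that("identical ratios give zero heterogeneity", {
  inp <- mr_input(c(1, 2, 3), rep(0.01, 3), c(0.5, 1.0, 1.5), rep(0.1, 3))
  fit <- mr_ivw(inp)
  expect_equal(fit$estimate, 0.5)
  expect_equal(fit$het$Q, 0, tolerance = 1e-20)
  expect_equal(fit$het$i2_percent, 0)
})

test_that("I2 is (Q - df)/Q when overdispersed", {
  # b_X all 1, outcome values chosen so Q = 8 on 4 df
  inp <- mr_input(rep(1, 5), rep(0.01, 5), c(-2, 0, 0, 0, 2), rep(1, 5))
  fit <- mr_ivw(inp)
  expect_equal(fit$het$Q, 8)
  expect_equal(fit$het$df, 4)
  expect_equal(fit$het$i2_percent, 50)
  # multiplicative scaling inflates the SE by sqrt(Q/df)
  expect_equal(fit$se, sqrt(1 / 5) * sqrt(2))
  expect_equal(mr_ivw(inp, re_floor = FALSE)$se, fit$se)
})

test_that("IVW is invariant to jointly flipping instrument signs", {
  inp <- random_input(20, gamma = 0.25, seed = 5)
  base <- mr_ivw(inp)
  set.seed(6)
  for (r in 1:10) {
    flip <- sample(c(-1, 1), 20, replace = TRUE)
    flipped <- mr_input(inp$b_exp * flip, inp$se_exp,
                        inp$b_out * flip, inp$se_out)
    fit <- mr_ivw(flipped)
    expect_equal(fit$estimate, base$estimate, tolerance = 1e-12)
    expect_equal(fit$se, base$se, tolerance = 1e-12)
  }
})

test_that("single-instrument input yields a not-applicable IVW result", {
  fit <- mr_ivw(mr_input(1, 0.1, 0.5, 0.1))
  expect_true(is.na(fit$estimate))
  expect_match(fit$extra$not_applicable, "fewer than 2")
})

test_that("Egger recovers exact affine data and tests the intercept", {
  inp <- mr_input(c(1, 2, 3), rep(0.01, 3), c(1.1, 2.1, 3.1), rep(1, 3))
  fit <- mr_egger(inp)
  expect_equal(fit$estimate, 1.0, tolerance = 1e-10)
  expect_equal(fit$extra$egger_intercept, 0.1, tolerance = 1e-10)
  expect_gt(fit$extra$i2gx, 0.99)
})

test_that("Egger flags a design with no exposure-effect spread", {
  inp <- mr_input(rep(0.05, 4), rep(0.01, 4), rnorm(4, 0, 0.01),
                  rep(0.01, 4))
  fit <- mr_egger(inp)
  expect_true(is.na(fit$estimate))
  expect_true(isTRUE(fit$extra$degenerate))
  expect_equal(fit$extra$i2gx, 0)
})

test_that("with negligible exposure error the Egger slope is unbiased and i2gx is 1", {
  set.seed(31)
  est <- i2 <- numeric(200)
  for (r in 1:200) {
    beta <- rnorm(30, 0.1, 0.05)
    inp <- mr_input(beta + rnorm(30, 0, 1e-6), rep(1e-6, 30),
                    0.4 * beta + rnorm(30, 0, 0.01), rep(0.01, 30))
    fit <- mr_egger(inp)
    est[r] <- fit$estimate
    i2[r] <- fit$extra$i2gx
  }
  expect_gt(min(i2), 0.999)
  expect_equal(mean(est), 0.4, tolerance = 0.01)
})

# independent scan of every interpolation segment of the weighted-median
# cumulative curve
weighted_median_oracle <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  for (j in seq_len(length(r) - 1)) {
    if (s[j] <= 0.5 && 0.5 <= s[j + 1]) {
      return(r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j]))
    }
  }
  r[length(r)]
}

test_that("the weighted median interpolates the cumulative weight midpoints", {
  inp <- ratio_input(c(0.4, 0.5, 0.9))
  fit <- mr_weighted_median(inp, boot_B = 200, seed = 1)
  expect_equal(fit$estimate, 0.5)   # midpoint hits 1/2 exactly
  expect_false(is.na(fit$se))
})

test_that("the weighted median matches a segment-scan oracle on random instances", {
  set.seed(9)
  for (case in 1:300) {
    L <- sample(5:15, 1)
    ratio <- rnorm(L)
    rse <- runif(L, 0.05, 2)
    est <- mrscreen:::weighted_median_estimate(ratio, 1 / rse^2)
    expect_equal(est, weighted_median_oracle(ratio, 1 / rse^2),
                 tolerance = 1e-12)
  }
})

test_that("the weighted median resists a single wild outlier", {
  ratios <- c(rnorm(9, 0.5, 0.01), 25)
  inp <- ratio_input(ratios, ratio_se = rep(0.1, 10))
  fit <- mr_weighted_median(inp, boot_B = 300, seed = 2)
  expect_lt(abs(fit$estimate - 0.5), fit$se)
})

test_that("the weighted mode finds the dominant ratio cluster", {
  fit <- mr_weighted_mode(ratio_input(c(0.5, 0.5, 0.5, 2.0)), boot_B = 0)
  expect_equal(fit$estimate, 0.5, tolerance = 0.02)
  all_same <- mr_weighted_mode(ratio_input(rep(0.7, 4)), boot_B = 0)
  expect_equal(all_same$estimate, 0.7)
})

test_that("the weighted-mode argmax agrees with a dense-grid scan", {
  set.seed(12)
  for (case in 1:20) {
    L <- sample(5:12, 1)
    ratio <- rnorm(L, 0.3, 0.2)
    w <- runif(L, 0.5, 2)
    est <- mrscreen:::weighted_mode_estimate(ratio, w, grid_n = 4001)
    s <- 0.9 * min(sd(ratio), mad(ratio)) * L^(-1 / 5)
    h <- max(1e-8, s)
    grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 40001)
    dens <- colSums(outer(ratio, grid, function(r, g) dnorm(g, r, h)) *
                      (w / sum(w)))
    spacing <- diff(range(grid)) / 4000
    expect_lt(abs(est - grid[which.max(dens)]), 1.5 * spacing)
  }
})

test_that("leave-one-out produces L reduced fits and isolates an outlier", {
  inp <- ratio_input(c(0.5, 0.5, 0.5))
  loo <- mr_leave_one_out(inp)
  expect_equal(nrow(loo), 3)
  expect_true(all(loo$L_used == 2))

  base <- rnorm(9, 0.5, 0.005)
  inp2 <- ratio_input(c(base, 3), ratio_se = rep(0.05, 10))
  loo2 <- mr_leave_one_out(inp2)
  shift <- abs(loo2$estimate - mr_ivw(inp2)$estimate)
  expect_equal(which.max(shift), 10)  # dropping the outlier moves the most
})

test_that("plot frames carry the per-instrument and pooled geometry", {
  inp <- random_input(8, seed = 3)
  fit <- mr_fit(inp, boot_B = 50, seed = 1, simex_B = 50)
  frames <- plot_frames(inp, mrscreen:::mr_fit_results(fit))
  expect_equal(nrow(frames$funnel), 8)
  n_methods <- length(Filter(function(r) !is.na(r$estimate),
                             mrscreen:::mr_fit_results(fit)))
  expect_equal(sum(frames$forest$kind == "pooled"), n_methods)
  expect_equal(nrow(frames$scatter), 8)
  ln <- frames$scatter_lines
  expect_equal(ln$slope[ln$method == "ivw_mre"], fit$ivw$estimate)
  expect_equal(ln$slope[ln$method == "mr_egger"], fit$egger$estimate)
})

test_that("SIMEX needs a usable lambda grid and collapses to Egger without error", {
  inp <- random_input(10, seed = 4, se_exp = 1e-7)
  expect_error(mr_simex_egger(inp, lambda_grid = 1), "quadratic")
  fit <- mr_simex_egger(inp, B = 200, seed = 1)
  naive <- mr_egger(inp)
  expect_equal(fit$estimate, naive$estimate, tolerance = 1e-4)
  expect_true(isTRUE(fit$extra$simex_applied))
})

test_that("SIMEX moves an attenuated Egger slope toward the truth", {
  set.seed(41)
  wins <- c()
  for (r in 1:40) {
    L <- 100
    beta <- rnorm(L, 0.15, 0.07)
    bx <- beta + rnorm(L, 0, 0.04)
    by <- 0.5 * beta + rnorm(L, 0, 0.005)
    inp <- mr_input(bx, rep(0.04, L), by, rep(0.005, L))
    eg <- mr_egger(inp)
    i2 <- eg$extra$i2gx
    if (is.na(i2) || i2 <= 0.6 || i2 > 0.9) next
    sfit <- mr_simex_egger(inp, B = 400, seed = r)
    wins <- c(wins, abs(sfit$estimate - 0.5) < abs(eg$estimate - 0.5))
  }
  expect_gt(length(wins), 20)
  expect_gte(mean(wins), 0.8)
})

test_that("the battery object exposes the usual modelling verbs", {
  inp <- random_input(12, gamma = 0.3, seed = 10)
  fit <- mr_fit(inp, boot_B = 100, seed = 2, simex_B = 100)
  expect_s3_class(fit, "mr_fit")
  expect_true(all(c("ivw_mre", "mr_egger", "weighted_median",
                    "weighted_mode") %in% names(coef(fit))))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= ci[, 2]))
  df <- as.data.frame(fit)
  expect_true(all(c("method", "estimate", "pval") %in% names(df)))
  expect_output(print(fit), "ivw_mre")
  tab <- summary(fit)
  expect_s3_class(tab, "summary.mr_fit")
})
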