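# Weighted simple linear regression (intercept + slope) with closed-form
# coefficients and multiplicative random-effects SE scaling. Returns NULL
# when the design is degenerate (no spread in x).
egger_wls <- function(x, y, w, re_floor = TRUE) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0) return(NULL)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  Q <- sum(w * (y - intercept - slope * x)^2)
  df <- length(x) - 2
  scale2 <- if (df > 0) {
    if (re_floor) max(1, Q / df) else Q / df
  } else 1
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(scale2 / sxx),
       intercept_se = sqrt(scale2 * (1 / sw + xbar^2 / sxx)),
       Q = Q, df = df)
}

# Regression-dilution I2 for the instrument-exposure effects: the
# precision-weighted analogue of Cochran's Q on b_X measures how far the
# no-measurement-error (NOME) assumption holds; values near 1 mean the
# exposure effects are measured essentially without error.
i2_gx <- function(b_exp, se_exp) {
  L <- length(b_exp)
  wbar <- sum(b_exp / se_exp^2) / sum(1 / se_exp^2)
  q_gx <- sum((b_exp - wbar)^2 / se_exp^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (L - 1)) / q_gx)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after orienting every instrument so its exposure effect is
#' positive (required for the intercept's interpretation as average
#' directional pleiotropy). The intercept test is the pleiotropy test; the
#' `i2gx` diagnostic quantifies regression dilution of the exposure effects
#' (NOME assumption): below 0.9 the slope is attenuated, and below 0.6 the
#' Egger result should be disregarded; between the two, use
#' [mr_simex_egger()].
#'
#' @param input an `mr_input` with at least three instruments.
#' @param re_floor,dist as in [mr_ivw()].
#' @return An `mr_result` for the slope; `$extra` carries `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`, `i2gx` and, when the
#'   exposure effects have no spread, `degenerate = TRUE`.
#' @export
mr_egger <- function(input, re_floor = TRUE, dist = c("normal", "t")) {
  dist <- match.arg(dist)
  L <- length(input$b_exp)
  if (L < 3) return(mr_result_na("mr_egger", L, "fewer than 3 instruments"))
  o <- orient_egger(input)
  fit <- egger_wls(o$x, o$y, o$w, re_floor = re_floor)
  i2 <- i2_gx(o$x, o$sx)
  if (is.null(fit)) {
    res <- mr_result_na("mr_egger", L, "no spread in exposure effects")
    res$extra$i2gx <- i2
    res$extra$degenerate <- TRUE
    return(res)
  }
  pval <- if (dist == "normal") z_pvalue(fit$slope, fit$slope_se) else {
    max(2 * stats::pt(-abs(fit$slope / fit$slope_se), fit$df),
        .Machine$double.xmin)
  }
  int_p <- if (dist == "normal") z_pvalue(fit$intercept, fit$intercept_se)
  else max(2 * stats::pt(-abs(fit$intercept / fit$intercept_se), fit$df),
           .Machine$double.xmin)
  mr_result("mr_egger", fit$slope, fit$slope_se, pval, L,
            extra = list(egger_intercept = fit$intercept,
                         egger_intercept_se = fit$intercept_se,
                         egger_intercept_p = int_p,
                         i2gx = i2),
            het = heterogeneity_stats(fit$Q, fit$df))
}

orient_egger <- function(input) {
  sgn <- sign(input$b_exp)
  sgn[sgn == 0] <- 1
  list(x = input$b_exp * sgn, y = input$b_out * sgn,
       sx = input$se_exp, w = 1 / input$se_out^2)
}

#' SIMEX-corrected MR-Egger slope
#'
#' Simulation extrapolation for the regression dilution of the Egger slope
#' when the exposure effects carry non-negligible measurement error
#' (`0.6 < i2gx <= 0.9`). For each `lambda` in the grid, `B` replicates add
#' `N(0, lambda * se_exp^2)` noise to the (oriented) exposure effects, the
#' Egger slope is refit and averaged; a quadratic in `lambda` is then
#' extrapolated to `lambda = -1`, the error-free limit. The standard error
#' comes from a jackknife over simulation batches.
#'
#' @param input an `mr_input` with at least three instruments.
#' @param lambda_grid added-noise multipliers; together with the naive point
#'   at 0 at least three distinct values are needed for the quadratic.
#' @param B simulation replicates per lambda (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param n_batches jackknife batches for the standard error.
#' @return An `mr_result`; `$extra` carries `i2gx`, `simex_applied = TRUE`,
#'   `naive_estimate`, the per-lambda means, and the Egger intercept
#'   diagnostics from the naive fit.
#' @export
mr_simex_egger <- function(input, lambda_grid = c(0.5, 1, 1.5, 2), B = 1000,
                           seed = NULL, n_batches = 20) {
  L <- length(input$b_exp)
  if (L < 3) return(mr_result_na("simex_egger", L, "fewer than 3 instruments"))
  lambda_grid <- sort(unique(c(0, lambda_grid)))
  if (length(lambda_grid) < 3) {
    stop_domain("lambda grid too small: the quadratic extrapolation needs ",
                "at least three distinct lambda values (including 0)")
  }
  naive <- mr_egger(input)
  if (is.na(naive$estimate)) return(naive)
  o <- orient_egger(input)
  n_batches <- max(2, min(n_batches, B))
  batch <- rep(seq_len(n_batches), length.out = B)

  slope_mat <- with_seed(seed, {
    sapply(lambda_grid, function(lam) {
      if (lam == 0) return(rep(naive$estimate, B))
      vapply(seq_len(B), function(b) {
        xs <- o$x + stats::rnorm(L, 0, sqrt(lam) * o$sx)
        f <- egger_wls(xs, o$y, o$w)
        if (is.null(f)) NA_real_ else f$slope
      }, numeric(1))
    })
  })

  extrapolate <- function(means) {
    fit <- stats::lm.fit(cbind(1, lambda_grid, lambda_grid^2), means)
    sum(fit$coefficients * c(1, -1, 1))
  }
  lam_means <- colMeans(slope_mat, na.rm = TRUE)
  est <- extrapolate(lam_means)
  jack <- vapply(seq_len(n_batches), function(k) {
    extrapolate(colMeans(slope_mat[batch != k, , drop = FALSE], na.rm = TRUE))
  }, numeric(1))
  se_mc <- sqrt((n_batches - 1) / n_batches * sum((jack - mean(jack))^2))
  # sampling SE of the naive slope still applies; extrapolation adds MC error
  se <- sqrt(naive$se^2 + se_mc^2)
  mr_result("simex_egger", est, se, z_pvalue(est, se), L,
            extra = list(i2gx = naive$extra$i2gx, simex_applied = TRUE,
                         naive_estimate = naive$estimate,
                         lambda_grid = lambda_grid, lambda_means = lam_means,
                         egger_intercept = naive$extra$egger_intercept,
                         egger_intercept_p = naive$extra$egger_intercept_p),
            het = naive$het)
}
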