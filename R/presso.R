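# Leave-one-out IVW estimates from sufficient statistics: for matrices with
# one simulation per row this is fully vectorised.
loo_ivw_estimates <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

# Observed weighted squared residual of each variant against its
# leave-one-out IVW prediction; their sum is the global RSS.
presso_residuals <- function(bx, by, w) {
  beta_loo <- loo_ivw_estimates(bx, by, w)
  w * (by - beta_loo * bx)^2
}

# Null-simulation draws for one variant: per-variant RNG stream keyed by the
# variant id so the global test is invariant to instrument order.
presso_sim_one <- function(n_sim, seed, id, mu_x, sd_x, mu_y, sd_y) {
  with_seed(variant_seed(seed, id), {
    z <- stats::rnorm(2 * n_sim)
    list(x = mu_x + sd_x * z[seq_len(n_sim)],
         y = mu_y + sd_y * z[n_sim + seq_len(n_sim)])
  })
}

#' MR-PRESSO: global pleiotropy test, outlier test and corrected estimate
#'
#' The global test statistic is the residual sum of squares of each outcome
#' effect against its leave-one-out IVW prediction,
#' `RSS = sum_j w_j (b_Yj - beta_(-j) b_Xj)^2` with `w_j = 1/se_Yj^2`. Its
#' null distribution is simulated parametrically: exposure effects are drawn
#' `N(b_Xj, se_Xj)` and outcome effects `N(beta_(-j) b_Xj, se_Yj)`, and the
#' statistic recomputed (with the leave-one-out estimates refit on the
#' simulated data). The add-one Monte-Carlo p-value
#' `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)` is never exactly zero.
#'
#' When the global test is significant at `alpha`, each variant's observed
#' residual is compared with its own simulated null distribution; per-SNP
#' p-values are Bonferroni-adjusted over the `L` tests and variants below
#' `alpha` are removed, after which the IVW estimator is refit on the
#' survivors. Per-variant RNG streams are keyed by variant id, so results do
#' not depend on instrument order.
#'
#' @param input an `mr_input` with at least four instruments.
#' @param n_sim null simulations (default 1000; must be positive).
#' @param seed RNG seed.
#' @param alpha significance level for the global gate and the (adjusted)
#'   per-SNP outlier test.
#' @param outlier_test run the outlier stage when the global test fires
#'   (default TRUE).
#' @return An object of class `mr_presso`: list with `global_rss_obs`,
#'   `global_p`, `n_sim`, `outliers` (data frame `variant_id`, `outlier_p`
#'   of flagged variants), `corrected` (IVW `mr_result` on survivors, or
#'   `NULL` when every instrument is flagged), `estimate` (the result the
#'   pipeline consumes: corrected IVW when outliers were removed, full IVW
#'   otherwise), and `distortion_note` comparing the two.
#' @export
mr_presso <- function(input, n_sim = 1000, seed = NULL, alpha = 0.05,
                      outlier_test = TRUE) {
  L <- length(input$b_exp)
  if (L < 4) {
    return(structure(list(global_rss_obs = NA_real_, global_p = NA_real_,
                          n_sim = n_sim, outliers = NULL, corrected = NULL,
                          estimate = mr_result_na("mr_presso", L,
                                                  "fewer than 4 instruments"),
                          distortion_note = "not applicable"),
                     class = "mr_presso"))
  }
  if (!is_count(n_sim) || n_sim < 1) stop_domain("n_sim must be a positive integer")
  seed <- seed %||% 0L
  w <- 1 / input$se_out^2
  res_obs <- presso_residuals(input$b_exp, input$b_out, w)
  rss_obs <- sum(res_obs)

  beta_loo <- loo_ivw_estimates(input$b_exp, input$b_out, w)
  # n_sim x L matrices of simulated effects, one column per variant
  sim_x <- matrix(NA_real_, n_sim, L)
  sim_y <- matrix(NA_real_, n_sim, L)
  for (j in seq_len(L)) {
    s <- presso_sim_one(n_sim, seed, input$variant_ids[j],
                        input$b_exp[j], input$se_exp[j],
                        beta_loo[j] * input$b_exp[j], input$se_out[j])
    sim_x[, j] <- s$x
    sim_y[, j] <- s$y
  }
  wm <- matrix(w, n_sim, L, byrow = TRUE)
  sxy <- rowSums(wm * sim_x * sim_y)
  sxx <- rowSums(wm * sim_x^2)
  bloo <- (sxy - wm * sim_x * sim_y) / (sxx - wm * sim_x^2)
  res_sim <- wm * (sim_y - bloo * sim_x)^2
  rss_sim <- rowSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  full_ivw <- mr_ivw(input)
  full_ivw$method <- "mr_presso"
  outliers <- NULL
  corrected <- NULL
  estimate <- full_ivw
  note <- "global test not significant; estimate is the full IVW"
  if (outlier_test && global_p < alpha) {
    p_snp <- (1 + colSums(res_sim >= matrix(res_obs, n_sim, L, byrow = TRUE))) /
      (n_sim + 1)
    p_adj <- pmin(1, p_snp * L)
    flag <- p_adj < alpha
    outliers <- data.frame(variant_id = input$variant_ids[flag],
                           outlier_p = p_adj[flag], stringsAsFactors = FALSE)
    if (all(flag)) {
      corrected <- NULL
      estimate <- mr_result_na("mr_presso", 0, "all instruments flagged as outliers")
      note <- "all instruments flagged; no corrected estimate"
    } else if (any(flag)) {
      corrected <- mr_ivw(subset_mr_input(input, !flag))
      corrected$method <- "mr_presso"
      estimate <- corrected
      note <- sprintf(
        "distortion: full IVW %.4g vs outlier-corrected %.4g (%d outlier(s) removed)",
        full_ivw$estimate, corrected$estimate, sum(flag))
    } else {
      corrected <- full_ivw
      estimate <- full_ivw
      note <- "global test significant but no per-SNP outlier identified"
    }
  }
  structure(list(global_rss_obs = rss_obs, global_p = global_p,
                 n_sim = n_sim, outliers = outliers, corrected = corrected,
                 estimate = estimate, distortion_note = note),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, p = %.4g (%d simulations)\n",
              x$global_rss_obs, x$global_p, x$n_sim))
  if (!is.null(x$outliers) && nrow(x$outliers)) {
    cat("Outliers:", paste(x$outliers$variant_id, collapse = ", "), "\n")
  }
  cat(x$distortion_note, "\n")
  print(x$estimate)
  invisible(x)
}
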