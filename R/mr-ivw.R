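#' Multiplicative random-effects inverse-variance-weighted estimator
#'
#' Weighted regression of the outcome effects on the exposure effects through
#' the origin with weights `1/se_out^2`:
#' `estimate = sum(w b_X b_Y) / sum(w b_X^2)`. Cochran's
#' `Q = sum(w (b_Y - est b_X)^2)` on `L - 1` degrees of freedom measures
#' residual over-dispersion; the multiplicative random-effects standard error
#' scales the fixed-effect one by `max(1, sqrt(Q/df))` (never shrinking below
#' fixed effect; set `re_floor = FALSE` for the pure multiplicative variant).
#'
#' @param input an `mr_input` with at least two instruments.
#' @param re_floor floor the over-dispersion scale at 1 (default TRUE).
#' @param dist reference distribution for the p-value: `"normal"` (default
#'   convention) or `"t"` on `L - 1` degrees of freedom.
#' @return An `mr_result` with heterogeneity statistics (`Q`, `df`, `q_pval`,
#'   `i2_percent`) in `$het`. With fewer than two instruments a
#'   not-applicable result is returned.
#' @export
mr_ivw <- function(input, re_floor = TRUE, dist = c("normal", "t")) {
  dist <- match.arg(dist)
  L <- length(input$b_exp)
  if (L < 2) return(mr_result_na("ivw_mre", L, "fewer than 2 instruments"))
  w <- 1 / input$se_out^2
  sxx <- sum(w * input$b_exp^2)
  est <- sum(w * input$b_exp * input$b_out) / sxx
  Q <- sum(w * (input$b_out - est * input$b_exp)^2)
  df <- L - 1
  scale <- if (re_floor) max(1, sqrt(Q / df)) else sqrt(Q / df)
  se <- sqrt(1 / sxx) * scale
  pval <- if (dist == "normal") z_pvalue(est, se) else {
    max(2 * stats::pt(-abs(est / se), df), .Machine$double.xmin)
  }
  mr_result("ivw_mre", est, se, pval, L,
            het = heterogeneity_stats(Q, df))
}

#' Leave-one-out IVW analysis
#'
#' Refits the multiplicative random-effects IVW estimator `L` times, each
#' omitting one instrument, to expose estimates driven by a single variant.
#'
#' @param input an `mr_input` with at least three instruments.
#' @param ... passed to [mr_ivw()].
#' @return Data frame with one row per left-out variant: `left_out`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pval`, `L_used`.
#' @export
mr_leave_one_out <- function(input, ...) {
  L <- length(input$b_exp)
  if (L < 3) stop_domain("leave-one-out requires at least 3 instruments")
  rows <- lapply(seq_len(L), function(j) {
    fit <- mr_ivw(subset_mr_input(input, -j), ...)
    cbind(data.frame(left_out = input$variant_ids[j],
                     stringsAsFactors = FALSE),
          as.data.frame(fit)[, -1])
  })
  do.call(rbind, rows)
}
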