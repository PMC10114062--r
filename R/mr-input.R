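#' Bundle per-instrument effect estimates for MR estimation
#'
#' @param b_exp,se_exp instrument-exposure effects and standard errors.
#' @param b_out,se_out instrument-outcome effects and standard errors.
#' @param variant_ids optional ids; defaults to `v1..vL`.
#' @param exposure,outcome trait labels.
#' @param direction optional direction label.
#' @return An object of class `mr_input`.
#' @export
mr_input <- function(b_exp, se_exp, b_out, se_out, variant_ids = NULL,
                     exposure = "exposure", outcome = "outcome",
                     direction = NULL) {
  L <- length(b_exp)
  if (length(se_exp) != L || length(b_out) != L || length(se_out) != L) {
    stop_domain("effect and se vectors must have equal length")
  }
  if (L < 1) stop_domain("at least one instrument is required")
  if (any(se_exp <= 0) || any(se_out <= 0)) {
    stop_domain("standard errors must be positive")
  }
  if (any(!is.finite(c(b_exp, se_exp, b_out, se_out)))) {
    stop_domain("effects and standard errors must be finite")
  }
  variant_ids <- variant_ids %||% paste0("v", seq_len(L))
  structure(list(b_exp = as.numeric(b_exp), se_exp = as.numeric(se_exp),
                 b_out = as.numeric(b_out), se_out = as.numeric(se_out),
                 variant_ids = as.character(variant_ids),
                 exposure = exposure, outcome = outcome,
                 direction = direction %||% paste(exposure, "->", outcome)),
            class = "mr_input")
}

#' Coerce an instrument set to an `mr_input`
#'
#' @param set an `instrument_set`.
#' @return An `mr_input` over the set's instruments.
#' @export
as_mr_input <- function(set) {
  mr_input(set$b_X, set$se_X, set$b_Y, set$se_Y,
           variant_ids = set$variant_id,
           exposure = attr(set, "exposure_id") %||% "exposure",
           outcome = attr(set, "outcome_id") %||% "outcome",
           direction = attr(set, "direction"))
}

#' @export
print.mr_input <- function(x, ...) {
  cat(sprintf("MR input %s: %d instruments\n", x$direction, length(x$b_exp)))
  invisible(x)
}

subset_mr_input <- function(input, idx) {
  mr_input(input$b_exp[idx], input$se_exp[idx],
           input$b_out[idx], input$se_out[idx],
           variant_ids = input$variant_ids[idx],
           exposure = input$exposure, outcome = input$outcome,
           direction = input$direction)
}

#' Per-variant Wald ratio estimates
#'
#' `ratio_j = b_out_j / b_exp_j` with first-order delta standard error
#' `se_out_j / |b_exp_j|`. Instruments with a zero exposure effect are
#' excluded with a warning.
#'
#' @param input an `mr_input`.
#' @return Data frame with columns `variant_id`, `ratio`, `ratio_se`.
#' @export
wald_ratios <- function(input) {
  keep <- input$b_exp != 0
  if (any(!keep)) {
    warning(sprintf("excluded %d instrument(s) with zero exposure effect",
                    sum(!keep)), call. = FALSE)
  }
  data.frame(variant_id = input$variant_ids[keep],
             ratio = input$b_out[keep] / input$b_exp[keep],
             ratio_se = input$se_out[keep] / abs(input$b_exp[keep]),
             stringsAsFactors = FALSE)
}

# ---- result container ------------------------------------------------------

mr_result <- function(method, estimate, se, pval, L_used,
                      extra = list(), het = NULL, ci_level = 0.95) {
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = estimate - zq * se, ci_high = estimate + zq * se,
                 pval = pval, L_used = L_used, extra = extra, het = het),
            class = "mr_result")
}

mr_result_na <- function(method, L_used, reason) {
  structure(list(method = method, estimate = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                 L_used = L_used, extra = list(not_applicable = reason),
                 het = NULL),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  if (is.na(x$estimate)) {
    cat(sprintf("%s: not applicable (%s)\n", x$method,
                x$extra$not_applicable %||% "unknown"))
  } else {
    cat(sprintf("%s: estimate %.4g (se %.3g, 95%% CI %.4g to %.4g), p = %.3g, L = %d\n",
                x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval,
                x$L_used))
  }
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  c(estimate = object$estimate, se = object$se)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             L_used = x$L_used, stringsAsFactors = FALSE)
}

heterogeneity_stats <- function(Q, df) {
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df,
       q_pval = if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE)
       else NA_real_,
       i2_percent = i2)
}
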