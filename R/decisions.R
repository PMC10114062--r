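#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegated to
#' [stats::p.adjust()]): adjusted values are monotone in rank, never below
#' the raw p, and capped at 1.
#'
#' @param pvals p-values in (0, 1].
#' @return Adjusted p-values in input order (empty in, empty out).
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop_domain("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 41) # 1.21e-03 to printed precision
bonferroni_threshold <- function(alpha, m) {
  if (!is_count(m) || m < 1) stop_domain("m must be a positive integer")
  alpha / m
}

check_verdict <- function(result, ivw_sign, alpha = 0.05) {
  if (is.null(result) || is.na(result$estimate) || is.na(result$pval)) {
    return("fail")
  }
  if (sign(result$estimate) == ivw_sign && result$pval < alpha) "pass"
  else "fail"
}

#' Evaluate the staged sensitivity criteria for one analysis direction
#'
#' Encodes the three evidence criteria: (i) IVW FDR p below 0.05; (ii) the
#' weighted median, weighted mode, MR-PRESSO and Steiger-filtered IVW
#' estimates all share the IVW direction with p below 0.05, and — only when
#' the Egger intercept signals pleiotropy (intercept p below 0.05) — so does
#' MR-Egger (I2GX above 0.9) or SIMEX-corrected Egger (I2GX in (0.6, 0.9]);
#' when I2GX is 0.6 or less the Egger result is disregarded, which under the
#' default strict policy fails the pair whenever pleiotropy evidence exists
#' (set `egger_policy = "lenient"` to skip the check instead); (iii) mean
#' per-SNP F above 10 for continuous exposures.
#'
#' @param ivw the main-analysis `mr_result`.
#' @param fdr_p the FDR-adjusted IVW p-value.
#' @param battery named list with `weighted_median` and `weighted_mode`
#'   `mr_result`s.
#' @param presso an `mr_presso` object (its `$estimate` is judged).
#' @param steiger_ivw `mr_result` of IVW after Steiger filtering.
#' @param egger the `mr_egger` result (carries the intercept test and
#'   `i2gx`); `simex` the SIMEX result when computed.
#' @param f_stats output of [f_statistics()], or `NULL` for non-continuous
#'   exposures.
#' @param exposure_type `"continuous"`, `"binary"` or
#'   `"ordered-categorical"` (the F-statistic rule applies to continuous
#'   exposures; ordered-categorical traits are analysed as continuous).
#' @param alpha significance level for criteria (i) and (ii).
#' @param egger_policy `"strict"` (default) or `"lenient"`, see above.
#' @return List with the per-check verdict map (`pass`/`fail`/
#'   `not-required`/`disregarded`), `f_ok`, and `meets_sensitivity`.
#' @export
evaluate_sensitivity <- function(ivw, fdr_p, battery, presso, steiger_ivw,
                                 egger, simex = NULL, f_stats = NULL,
                                 exposure_type = "continuous", alpha = 0.05,
                                 egger_policy = c("strict", "lenient")) {
  egger_policy <- match.arg(egger_policy)
  if (is.null(ivw) || is.na(ivw$estimate)) {
    stop_domain("IVW result is required")
  }
  for (nm in c("weighted_median", "weighted_mode")) {
    if (is.null(battery[[nm]])) stop_domain("missing required component: ", nm)
  }
  if (is.null(presso) || is.null(steiger_ivw) || is.null(egger)) {
    stop_domain("presso, steiger_ivw and egger components are required")
  }
  ivw_sign <- sign(ivw$estimate)
  checks <- c(
    weighted_median = check_verdict(battery$weighted_median, ivw_sign, alpha),
    weighted_mode = check_verdict(battery$weighted_mode, ivw_sign, alpha),
    mr_presso = check_verdict(presso$estimate, ivw_sign, alpha),
    ivw_steiger = check_verdict(steiger_ivw, ivw_sign, alpha)
  )
  intercept_p <- egger$extra$egger_intercept_p %||% NA_real_
  i2 <- egger$extra$i2gx %||% NA_real_
  pleiotropy_evidence <- !is.na(intercept_p) && intercept_p < alpha
  checks["egger_or_simex"] <- if (!pleiotropy_evidence) {
    "not-required"
  } else if (is.na(i2) || i2 <= 0.6) {
    "disregarded"
  } else if (i2 > 0.9) {
    check_verdict(egger, ivw_sign, alpha)
  } else {
    if (is.null(simex)) stop_domain("SIMEX result required when 0.6 < i2gx <= 0.9")
    check_verdict(simex, ivw_sign, alpha)
  }
  f_ok <- if (exposure_type == "binary" || is.null(f_stats)) {
    "not-applicable"
  } else if (f_stats$mean_F > 10) "pass" else "fail"

  required_pass <- all(checks[c("weighted_median", "weighted_mode",
                                "mr_presso", "ivw_steiger")] == "pass")
  egger_ok <- switch(checks[["egger_or_simex"]],
                     "not-required" = TRUE,
                     "pass" = TRUE,
                     "fail" = FALSE,
                     "disregarded" = egger_policy == "lenient")
  meets <- !is.na(fdr_p) && fdr_p < alpha && required_pass && egger_ok &&
    f_ok != "fail"
  list(checks = checks, f_ok = f_ok, fdr_p = fdr_p,
       meets_sensitivity = meets)
}

#' Assemble and classify the evidence record for one direction
#'
#' Applies the staged gate chain: `mr_main` when the IVW FDR p is below
#' `alpha`; `mr_sensitivity` when additionally the sensitivity battery
#' passes; `cause_confirmed` when the model-comparison p additionally meets
#' its Bonferroni threshold. The chain is monotone by construction.
#'
#' @param exposure_id,outcome_id,direction identifiers.
#' @param ivw the main-analysis `mr_result`.
#' @param fdr_p FDR-adjusted IVW p.
#' @param sensitivity output of [evaluate_sensitivity()], or `NULL` when not
#'   run (gate failed earlier).
#' @param cause_p one-sided model-comparison p, or `NA` when not run.
#' @param cause_alpha_bonf Bonferroni threshold for the model-comparison
#'   stage (see [bonferroni_threshold()]).
#' @param alpha main-stage significance level.
#' @param category optional trait category label.
#' @return A one-row data frame of class `decision_record`.
#' @export
classify_pair <- function(exposure_id, outcome_id, direction, ivw, fdr_p,
                          sensitivity = NULL, cause_p = NA_real_,
                          cause_alpha_bonf = NA_real_, alpha = 0.05,
                          category = NA_character_) {
  mr_main <- !is.na(fdr_p) && fdr_p < alpha
  meets_sens <- mr_main && !is.null(sensitivity) &&
    isTRUE(sensitivity$meets_sensitivity)
  cause_pass <- meets_sens && !is.na(cause_p) && !is.na(cause_alpha_bonf) &&
    cause_p < cause_alpha_bonf
  final <- if (cause_pass) "cause_confirmed" else if (meets_sens) {
    "mr_sensitivity"
  } else if (mr_main) "mr_main" else "none"
  checks <- sensitivity$checks %||% NULL
  rec <- data.frame(
    exposure_id = exposure_id, outcome_id = outcome_id,
    direction = direction, category = category,
    ivw_estimate = ivw$estimate, ivw_se = ivw$se,
    ivw_ci_low = ivw$ci_low, ivw_ci_high = ivw$ci_high,
    ivw_p_raw = ivw$pval, ivw_p_fdr = fdr_p, L_used = ivw$L_used,
    weighted_median = checks[["weighted_median"]] %||% NA_character_,
    weighted_mode = checks[["weighted_mode"]] %||% NA_character_,
    mr_presso = checks[["mr_presso"]] %||% NA_character_,
    ivw_steiger = checks[["ivw_steiger"]] %||% NA_character_,
    egger_or_simex = checks[["egger_or_simex"]] %||% NA_character_,
    f_ok = sensitivity$f_ok %||% NA_character_,
    meets_sensitivity = meets_sens,
    cause_p = cause_p, cause_bonferroni_pass = if (meets_sens) cause_pass
    else NA,
    final_class = final, bidirectional = NA,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("decision_record", "data.frame")
  rec
}

#' Mark bidirectional relationships across decision records
#'
#' A trait pair is bidirectional when both directions reach the same final
#' class at or above the sensitivity stage.
#'
#' @param records data frame of stacked decision records.
#' @return The records with the `bidirectional` column filled.
#' @export
mark_bidirectional <- function(records) {
  if (!nrow(records)) return(records)
  rank <- c(none = 0, mr_main = 1, mr_sensitivity = 2, cause_confirmed = 3)
  key <- apply(records[, c("exposure_id", "outcome_id")], 1,
               function(r) paste(sort(r), collapse = "|"))
  for (k in unique(key)) {
    idx <- which(key == k)
    cls <- records$final_class[idx]
    records$bidirectional[idx] <- length(idx) == 2 &&
      cls[1] == cls[2] && rank[cls[1]] >= 2
  }
  records
}

#' Assemble report tables from decision records
#'
#' Produces the per-direction MR summary (instrument count, effect with CI,
#' FDR p, sensitivity verdict), the model-comparison summary (posterior
#' median with credible interval, delta ELPD with SE and p), and the
#' stage-count summary per category and direction.
#'
#' @param records stacked decision records (see [classify_pair()]).
#' @param cause_results optional data frame with per-direction model-
#'   comparison output: columns `exposure_id`, `outcome_id`, `direction`,
#'   `gamma_median`, `gamma_ci_low`, `gamma_ci_high`, `delta_elpd`,
#'   `se_delta`, `p_one_sided`.
#' @param out_dir optional directory; when given the three tables are
#'   written tab-delimited.
#' @return List with `mr_table`, `cause_table`, `stage_counts`.
#' @export
build_report <- function(records, cause_results = NULL, out_dir = NULL) {
  if (is.null(records) || !nrow(records)) {
    records <- classify_pair("x", "y", "x -> y",
                             mr_result("ivw_mre", 0, 1, 1, 0), NA)[0, ]
  }
  mr_table <- records[, c("exposure_id", "outcome_id", "direction",
                          "category", "L_used", "ivw_estimate", "ivw_ci_low",
                          "ivw_ci_high", "ivw_p_fdr", "meets_sensitivity",
                          "final_class", "bidirectional")]
  names(mr_table)[names(mr_table) == "L_used"] <- "n_snps"
  cause_table <- if (!is.null(cause_results) && nrow(cause_results)) {
    cause_results
  } else {
    data.frame(exposure_id = character(0), outcome_id = character(0),
               direction = character(0), gamma_median = numeric(0),
               gamma_ci_low = numeric(0), gamma_ci_high = numeric(0),
               delta_elpd = numeric(0), se_delta = numeric(0),
               p_one_sided = numeric(0))
  }
  cats <- unique(stats::na.omit(c(records$category, "all")))
  dirs <- unique(records$direction)
  rows <- list()
  for (d in dirs) {
    sub_d <- records[records$direction == d, , drop = FALSE]
    for (cat in cats) {
      sub <- if (cat == "all") sub_d else {
        sub_d[!is.na(sub_d$category) & sub_d$category == cat, , drop = FALSE]
      }
      rows[[length(rows) + 1]] <- data.frame(
        direction = d, category = cat, n_all = nrow(sub),
        n_mr_main = sum(sub$final_class %in%
                          c("mr_main", "mr_sensitivity", "cause_confirmed")),
        n_mr_sens = sum(sub$final_class %in%
                          c("mr_sensitivity", "cause_confirmed")),
        n_cause = sum(sub$final_class == "cause_confirmed"),
        stringsAsFactors = FALSE
      )
    }
  }
  stage_counts <- do.call(rbind, rows) %||%
    data.frame(direction = character(0), category = character(0),
               n_all = integer(0), n_mr_main = integer(0),
               n_mr_sens = integer(0), n_cause = integer(0))
  out <- list(mr_table = mr_table, cause_table = cause_table,
              stage_counts = stage_counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.table(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
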