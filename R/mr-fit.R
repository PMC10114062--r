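#' Fit the two-sample MR estimator battery
#'
#' The workhorse fitting function: runs the multiplicative random-effects
#' IVW main analysis plus the sensitivity battery (MR-Egger with the I2GX
#' diagnostic and, when `0.6 < I2GX <= 0.9`, the SIMEX-corrected slope;
#' weighted median; weighted mode) on one harmonized instrument set.
#'
#' The Egger track follows the I2GX gates: above 0.9 the plain Egger fit is
#' used; in (0.6, 0.9] SIMEX is applied; at or below 0.6 the Egger result is
#' disregarded (kept in the object, flagged).
#'
#' @param input an `mr_input`, or anything [as_mr_input()] accepts
#'   (an `instrument_set`).
#' @param boot_B bootstrap replicates for the median/mode standard errors.
#' @param seed RNG seed for the bootstrap and SIMEX draws.
#' @param simex_B SIMEX replicates per lambda.
#' @param re_floor,dist passed to the regression estimators.
#' @param bandwidth_factor passed to [mr_weighted_mode()].
#' @return An object of class `mr_fit`: list with the input, one
#'   `mr_result` per method (`ivw`, `egger`, `simex` when applied,
#'   `weighted_median`, `weighted_mode`), the heterogeneity statistics of
#'   the IVW fit, `i2gx`, and `egger_track` (`"egger"`, `"simex"` or
#'   `"disregarded"`).
#' @seealso [mr_leave_one_out()], [mr_presso()], [plot_frames()]
#' @export
mr_fit <- function(input, boot_B = 1000, seed = NULL, simex_B = 1000,
                   re_floor = TRUE, dist = "normal", bandwidth_factor = 1) {
  if (inherits(input, "instrument_set")) input <- as_mr_input(input)
  stopifnot(inherits(input, "mr_input"))
  ivw <- mr_ivw(input, re_floor = re_floor, dist = dist)
  egger <- mr_egger(input, re_floor = re_floor, dist = dist)
  i2 <- egger$extra$i2gx %||% NA_real_
  simex <- NULL
  track <- if (is.na(egger$estimate)) {
    "unavailable"
  } else if (!is.na(i2) && i2 > 0.9) {
    "egger"
  } else if (!is.na(i2) && i2 > 0.6) {
    simex <- mr_simex_egger(input, B = simex_B,
                            seed = if (is.null(seed)) NULL else seed + 1L)
    "simex"
  } else {
    "disregarded"
  }
  med <- mr_weighted_median(input, boot_B = boot_B,
                            seed = if (is.null(seed)) NULL else seed + 2L)
  mode <- mr_weighted_mode(input, bandwidth_factor = bandwidth_factor,
                           boot_B = boot_B,
                           seed = if (is.null(seed)) NULL else seed + 3L)
  structure(list(input = input, ivw = ivw, egger = egger, simex = simex,
                 weighted_median = med, weighted_mode = mode,
                 het = ivw$het, i2gx = i2, egger_track = track),
            class = "mr_fit")
}

mr_fit_results <- function(fit) {
  res <- list(fit$ivw, fit$egger)
  if (!is.null(fit$simex)) res <- c(res, list(fit$simex))
  c(res, list(fit$weighted_median, fit$weighted_mode))
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR fit: %s (%d instruments)\n",
              x$input$direction, length(x$input$b_exp)))
  for (r in mr_fit_results(x)) print(r)
  if (!is.null(x$het)) {
    cat(sprintf("Heterogeneity: Q = %.3g on %d df (p = %.3g), I2 = %.1f%%\n",
                x$het$Q, x$het$df, x$het$q_pval, x$het$i2_percent))
  }
  cat(sprintf("I2GX = %.3f; Egger track: %s\n", x$i2gx, x$egger_track))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  out <- as.data.frame(object)
  class(out) <- c("summary.mr_fit", "data.frame")
  out
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(mr_fit_results(x), as.data.frame))
  cbind(data.frame(exposure = x$input$exposure, outcome = x$input$outcome,
                   direction = x$input$direction,
                   stringsAsFactors = FALSE)[rep(1, nrow(out)), ],
        out, row.names = NULL)
}

#' @export
coef.mr_fit <- function(object, ...) {
  res <- mr_fit_results(object)
  stats::setNames(vapply(res, function(r) r$estimate, numeric(1)),
                  vapply(res, function(r) r$method, character(1)))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  res <- mr_fit_results(object)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- t(vapply(res, function(r) {
    c(r$estimate - zq * r$se, r$estimate + zq * r$se)
  }, numeric(2)))
  dimnames(out) <- list(vapply(res, function(r) r$method, character(1)),
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Tidy data frames backing scatter, funnel and forest plots
#'
#' @param input an `mr_input`.
#' @param results list of `mr_result` objects (e.g. from an `mr_fit`) whose
#'   estimates supply the fitted lines and pooled forest rows.
#' @return List of data frames `scatter` (per-SNP effects with ses, plus one
#'   `slope`/`intercept` row per method), `funnel` (ratio vs precision),
#'   `forest` (per-SNP ratio with CI, then one pooled row per method).
#' @export
plot_frames <- function(input, results = list()) {
  results <- Filter(function(r) !is.na(r$estimate), results)
  wr <- suppressWarnings(wald_ratios(input))
  zq <- stats::qnorm(0.975)
  scatter <- data.frame(
    variant_id = input$variant_ids,
    b_exp = input$b_exp, se_exp = input$se_exp,
    b_out = input$b_out, se_out = input$se_out,
    stringsAsFactors = FALSE
  )
  lines <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, slope = r$estimate,
               intercept = r$extra$egger_intercept %||% 0,
               stringsAsFactors = FALSE)
  })) %||% data.frame(method = character(0), slope = numeric(0),
                      intercept = numeric(0))
  funnel <- data.frame(variant_id = wr$variant_id, ratio = wr$ratio,
                       precision = 1 / wr$ratio_se, stringsAsFactors = FALSE)
  forest_snp <- data.frame(
    label = wr$variant_id, kind = "snp", estimate = wr$ratio,
    ci_low = wr$ratio - zq * wr$ratio_se, ci_high = wr$ratio + zq * wr$ratio_se,
    stringsAsFactors = FALSE
  )
  forest_pooled <- do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$method, kind = "pooled", estimate = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  })) %||% forest_snp[0, ]
  list(scatter = scatter, scatter_lines = lines, funnel = funnel,
       forest = rbind(forest_snp, forest_pooled))
}

#' @export
plot.mr_fit <- function(x, which = c("scatter", "funnel"), ...) {
  which <- match.arg(which)
  frames <- plot_frames(x$input, mr_fit_results(x))
  if (which == "scatter") {
    s <- frames$scatter
    plot(s$b_exp, s$b_out, pch = 19,
         xlab = "instrument effect on exposure",
         ylab = "instrument effect on outcome", ...)
    graphics::segments(s$b_exp, s$b_out - s$se_out,
                       s$b_exp, s$b_out + s$se_out, col = "grey60")
    ln <- frames$scatter_lines
    if (nrow(ln)) {
      for (i in seq_len(nrow(ln))) {
        graphics::abline(ln$intercept[i], ln$slope[i], col = i + 1)
      }
      graphics::legend("topleft", legend = ln$method, col = seq_len(nrow(ln)) + 1,
                       lty = 1, bty = "n", cex = 0.8)
    }
  } else {
    f <- frames$funnel
    plot(f$ratio, f$precision, pch = 19,
         xlab = "Wald ratio", ylab = "1 / ratio SE", ...)
    graphics::abline(v = x$ivw$estimate, col = 2)
  }
  invisible(frames)
}

#' Serialize MR results as a tidy table
#'
#' One row per (exposure, outcome, direction, method), suitable for
#' delimited output.
#'
#' @param fits list of `mr_fit` objects (or a single one).
#' @param path optional output file; when given the table is also written
#'   tab-delimited.
#' @return The combined data frame, invisibly when `path` is given.
#' @export
write_results_table <- function(fits, path = NULL) {
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  out <- do.call(rbind, lapply(fits, as.data.frame))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
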