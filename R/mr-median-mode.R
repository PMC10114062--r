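# Weighted median of ratio estimates: order the ratios, form cumulative
# weight midpoints s_j = cumsum(w)_j - w_j/2 (normalised weights), and
# linearly interpolate to s = 1/2.
weighted_median_estimate <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap over the instrument-level normals; returns the sd of
# the re-estimated statistic. est_fun(b_exp, b_out) -> scalar.
parametric_boot_se <- function(input, est_fun, B, seed) {
  if (B <= 0) return(NA_real_)
  L <- length(input$b_exp)
  with_seed(seed, {
    reps <- vapply(seq_len(B), function(b) {
      bx <- stats::rnorm(L, input$b_exp, input$se_exp)
      by <- stats::rnorm(L, input$b_out, input$se_out)
      est_fun(bx, by)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted median estimator
#'
#' Consistent when instruments carrying at least half of the weight are valid.
#' Ratio estimates are ordered and the inverse-variance-weighted median is
#' found by linear interpolation of the cumulative weight midpoints; the
#' standard error comes from a parametric bootstrap resampling the per-
#' instrument effects from their sampling normals.
#'
#' @param input an `mr_input` with at least three instruments.
#' @param boot_B bootstrap replicates (default 1000; 0 skips the bootstrap,
#'   leaving `se` and `pval` as `NA` for estimate-only use).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(input, boot_B = 1000, seed = NULL) {
  L <- length(input$b_exp)
  if (L < 3) {
    return(mr_result_na("weighted_median", L, "fewer than 3 instruments"))
  }
  wr <- suppressWarnings(wald_ratios(input))
  if (nrow(wr) < 3) {
    return(mr_result_na("weighted_median", L, "fewer than 3 usable ratios"))
  }
  est <- weighted_median_estimate(wr$ratio, 1 / wr$ratio_se^2)
  se <- parametric_boot_se(input, function(bx, by) {
    keep <- bx != 0
    weighted_median_estimate(by[keep] / bx[keep], (abs(bx[keep]) / input$se_out[keep])^2)
  }, boot_B, seed)
  pval <- if (is.na(se)) NA_real_ else z_pvalue(est, se)
  mr_result("weighted_median", est, if (is.na(se)) NA_real_ else se, pval, L,
            extra = list(boot_B = boot_B))
}

# Weighted normal-kernel density over the ratios evaluated on a dense grid;
# returns the argmax. Bandwidth: modified Silverman rule
# 0.9 * min(sd, mad) * L^(-1/5), scaled by bandwidth_factor.
weighted_mode_estimate <- function(ratio, weight, bandwidth_factor = 1,
                                   grid_n = 2001) {
  if (length(unique(ratio)) == 1) return(ratio[1])
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * length(ratio)^(-1 / 5)
  h <- max(1e-8, s * bandwidth_factor)
  w <- weight / sum(weight)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, ratio, h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' Consistent when the largest group of instruments sharing the same ratio
#' is valid (the "plurality valid" assumption). The estimate is the argmax
#' of an inverse-variance-weighted normal-kernel density over the ratio
#' estimates, with a modified-Silverman bandwidth; the standard error comes
#' from a parametric bootstrap.
#'
#' @param input an `mr_input` with at least three instruments.
#' @param bandwidth_factor multiplier on the modified-Silverman bandwidth.
#' @param boot_B,seed as in [mr_weighted_median()].
#' @return An `mr_result`.
#' @export
mr_weighted_mode <- function(input, bandwidth_factor = 1, boot_B = 1000,
                             seed = NULL) {
  L <- length(input$b_exp)
  if (L < 3) {
    return(mr_result_na("weighted_mode", L, "fewer than 3 instruments"))
  }
  wr <- suppressWarnings(wald_ratios(input))
  if (nrow(wr) < 3) {
    return(mr_result_na("weighted_mode", L, "fewer than 3 usable ratios"))
  }
  est <- weighted_mode_estimate(wr$ratio, 1 / wr$ratio_se^2, bandwidth_factor)
  se <- parametric_boot_se(input, function(bx, by) {
    keep <- bx != 0
    weighted_mode_estimate(by[keep] / bx[keep],
                           (abs(bx[keep]) / input$se_out[keep])^2,
                           bandwidth_factor, grid_n = 501)
  }, boot_B, seed)
  pval <- if (is.na(se)) NA_real_ else z_pvalue(est, se)
  mr_result("weighted_mode", est, if (is.na(se)) NA_real_ else se, pval, L,
            extra = list(boot_B = boot_B, bandwidth_factor = bandwidth_factor))
}
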