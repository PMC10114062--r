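#' Variance explained by a variant for a continuous trait
#'
#' Standard t-statistic conversion: with `t = beta/se`,
#' `r2 = t^2 / (t^2 + n - 2)`.
#'
#' @param beta,se per-allele effect and standard error (vectorised).
#' @param n total sample size (> 2).
#' @return Variance explained in `[0, 1)`.
#' @export
r2_continuous <- function(beta, se, n) {
  if (any(n <= 2)) stop_domain("n must exceed 2")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Liability-scale variance explained by a variant for a binary trait
#'
#' Converts a per-allele log odds ratio into variance explained on the
#' liability scale. The observed-scale R2 on the logistic scale is
#' `vg / (vg + pi^2/3)` with `vg = lor^2 * 2 * eaf * (1 - eaf)`, then the
#' case-control to liability transformation
#' `R2_l = C * R2_o / (1 + C * theta * R2_o)` is applied, where, with `K` the
#' population prevalence, `P` the sample case proportion, `x` the liability
#' threshold `qnorm(1 - K)`, `z = dnorm(x)` and mean case liability
#' `i = z / K`:
#' `C  = K(1-K)/z^2 * K(1-K)/(P(1-P))` and
#' `theta = i * (P-K)/(1-K) * (i * (P-K)/(1-K) - x)`.
#'
#' @param log_or per-allele log odds ratio (vectorised).
#' @param eaf effect-allele frequency in (0, 1).
#' @param n_case,n_control case and control counts.
#' @param prevalence population prevalence in (0, 1); defaults to the sample
#'   case proportion (logged, since ascertained samples bias this choice).
#' @return Liability-scale variance explained in `[0, 1)`.
#' @export
r2_binary_liability <- function(log_or, eaf, n_case, n_control,
                                prevalence = NULL) {
  if (any(eaf <= 0 | eaf >= 1)) stop_domain("eaf must be in (0, 1)")
  if (any(n_case <= 0) || any(n_control <= 0)) {
    stop_domain("n_case and n_control must be positive")
  }
  p_case <- n_case / (n_case + n_control)
  if (is.null(prevalence)) {
    message("prevalence not supplied; using sample case proportion ",
            paste(signif(unique(p_case), 4), collapse = ", "))
    prevalence <- p_case
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_domain("prevalence must be in (0, 1)")
  }
  vg <- log_or^2 * 2 * eaf * (1 - eaf)
  r2_obs <- vg / (vg + pi^2 / 3)
  k <- prevalence
  x <- stats::qnorm(1 - k)
  z <- stats::dnorm(x)
  i_mean <- z / k
  cc <- k * (1 - k) / z^2 * k * (1 - k) / (p_case * (1 - p_case))
  d <- i_mean * (p_case - k) / (1 - k)
  theta <- d * (d - x)
  cc * r2_obs / (1 + cc * theta * r2_obs)
}

#' Build an instrument set from a harmonized pair
#'
#' Subsets the harmonized pair to selected instruments and computes per-SNP
#' variance explained in both traits (continuous or liability-scale as the
#' trait type dictates) so Steiger filtering and F statistics can run.
#'
#' @param pair a `harmonized_pair` (after clumping/proxy substitution/shared-
#'   significant removal have flagged the rows to keep).
#' @param keep variant ids to retain; defaults to all usable rows.
#' @param n_exposure,n_outcome total sample sizes for the two traits.
#' @param exposure_binary,outcome_binary case/control counts as
#'   `c(n_case, n_control)`, or `NULL` for a continuous trait.
#' @param prevalence_exposure,prevalence_outcome population prevalences for
#'   binary traits (default: sample case proportion).
#' @param direction label such as `"A->B"`.
#' @return An object of class `instrument_set`: a data frame of instruments
#'   (`variant_id`, `b_X`, `se_X`, `p_X`, `b_Y`, `se_Y`, `p_Y`,
#'   `r2_exposure`, `r2_outcome`, `proxy_of`) with selection metadata in
#'   attributes.
#' @export
instrument_set <- function(pair, keep = NULL, n_exposure, n_outcome,
                           exposure_binary = NULL, outcome_binary = NULL,
                           prevalence_exposure = NULL,
                           prevalence_outcome = NULL,
                           direction = NULL) {
  rows <- harmonized_rows(pair)
  if (!is.null(keep)) rows <- rows[rows$variant_id %in% keep, , drop = FALSE]
  if (anyDuplicated(rows$variant_id)) stop_domain("duplicated variant ids")
  r2x <- if (is.null(exposure_binary)) {
    r2_continuous(rows$b_X, rows$se_X, n_exposure)
  } else {
    suppressMessages(r2_binary_liability(
      rows$b_X, pmin(pmax(rows$eaf_X, 1e-6), 1 - 1e-6),
      exposure_binary[1], exposure_binary[2], prevalence_exposure))
  }
  r2y <- if (is.null(outcome_binary)) {
    r2_continuous(rows$b_Y, rows$se_Y, n_outcome)
  } else {
    suppressMessages(r2_binary_liability(
      rows$b_Y, pmin(pmax(rows$eaf_Y %||% rows$eaf_X, 1e-6), 1 - 1e-6),
      outcome_binary[1], outcome_binary[2], prevalence_outcome))
  }
  out <- data.frame(
    variant_id = rows$variant_id,
    b_X = rows$b_X, se_X = rows$se_X, p_X = rows$p_X,
    b_Y = rows$b_Y, se_Y = rows$se_Y, p_Y = rows$p_Y,
    r2_exposure = if (nrow(rows)) r2x else numeric(0),
    r2_outcome = if (nrow(rows)) r2y else numeric(0),
    proxy_of = ifelse(rows$action == "proxy-substituted",
                      rows$variant_id, NA_character_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(pair, "exposure_id"),
            outcome_id = attr(pair, "outcome_id"),
            direction = direction %||%
              paste(attr(pair, "exposure_id"), "->", attr(pair, "outcome_id")),
            n_exposure = n_exposure, n_outcome = n_outcome,
            selection_log = list(),
            class = c("instrument_set", "data.frame"))
}

#' Steiger directionality filter
#'
#' Removes instruments that do not explain more variance in the exposure than
#' in the outcome (strict inequality `r2_exposure > r2_outcome`); such
#' variants are more plausibly acting on the outcome first, and retaining
#' them lets reverse causation masquerade as a forward effect. Optionally a
#' directionality z-test (Fisher z on the correlations) can additionally be
#' required at `test_alpha`.
#'
#' @param set an `instrument_set` with `r2_exposure`/`r2_outcome` populated.
#' @param require_test also require the directionality test p below
#'   `test_alpha` (default off: the strict inequality is the filter).
#' @param test_alpha significance level for the optional test.
#' @return The filtered `instrument_set`; the number removed is recorded in
#'   attribute `n_steiger_removed`. Idempotent.
#' @export
steiger_filter <- function(set, require_test = FALSE, test_alpha = 0.05) {
  if (any(is.na(set$r2_exposure)) || any(is.na(set$r2_outcome))) {
    stop_domain("r2_exposure and r2_outcome must be populated")
  }
  keep <- set$r2_exposure > set$r2_outcome
  if (require_test && nrow(set)) {
    nx <- attr(set, "n_exposure"); ny <- attr(set, "n_outcome")
    z <- (atanh(sqrt(set$r2_exposure)) - atanh(sqrt(set$r2_outcome))) /
      sqrt(1 / (nx - 3) + 1 / (ny - 3))
    keep <- keep & (stats::pnorm(-z) < test_alpha)
  }
  removed <- sum(!keep)
  out <- set[keep, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(set)
  for (a in setdiff(names(attrs), c("row.names", "names"))) {
    attr(out, a) <- attrs[[a]]
  }
  attr(out, "n_steiger_removed") <- removed
  out
}

#' Instrument-strength F statistics
#'
#' Per-SNP `F_j = (b_Xj / se_Xj)^2`, their mean, and the aggregate
#' `F = ((n - L - 1) / L) * R2 / (1 - R2)` with `R2` the summed per-SNP
#' variance explained in the exposure. Values above 10 are conventionally
#' read as strong instruments; the statistic is meaningful for continuous
#' exposures.
#'
#' @param set an `instrument_set`.
#' @param n_exposure exposure sample size (default: from the set).
#' @return List with `per_snp`, `mean_F`, `aggregate_F`, `L`, `r2_sum`.
#' @export
f_statistics <- function(set, n_exposure = attr(set, "n_exposure")) {
  L <- nrow(set)
  if (L == 0) stop_domain("instrument set is empty")
  per_snp <- (set$b_X / set$se_X)^2
  r2 <- sum(set$r2_exposure)
  list(per_snp = per_snp,
       mean_F = mean(per_snp),
       aggregate_F = ((n_exposure - L - 1) / L) * r2 / (1 - r2),
       L = L, r2_sum = r2)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set %s: %d instruments\n",
              attr(x, "direction"), nrow(x)))
  invisible(x)
}

#' Write the instrument selection audit log
#'
#' @param set an `instrument_set`.
#' @param path output file path.
#' @export
write_selection_log <- function(set, path) {
  utils::write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
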