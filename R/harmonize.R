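ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) ALLELE_COMPLEMENT[ea] == oa

# Actions that leave a variant usable downstream.
HARMONIZE_KEPT_ACTIONS <- c("kept", "sign-flipped", "proxy-substituted")

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Aligns the outcome association of every exposure variant to the exposure's
#' effect allele. Same-allele rows are kept unchanged; swapped-allele rows
#' (including strand-complement matches) get the outcome beta sign flipped
#' and the effect-allele frequency complemented; palindromic variants (A/T or
#' C/G) are oriented by allele frequency when both frequencies are informative
#' (minor-allele frequency at or below `palindrome_maf_limit`) and dropped
#' otherwise; variants absent from the outcome are flagged `missing-dropped`
#' (proxy substitution is a separate step, see [substitute_proxies()]).
#'
#' @param exposure,outcome `sumstats` objects (see [sumstats_table()]).
#' @param palindrome_maf_limit palindromic rows whose minor-allele frequency
#'   exceeds this (or with missing frequency) are unresolvable and dropped.
#'   Default 0.42, a conservative standard choice.
#' @return An object of class `harmonized_pair`: a data frame with one row per
#'   exposure variant (`variant_id`, `chrom`, `pos`, `b_X`, `se_X`, `p_X`,
#'   `b_Y`, `se_Y`, `p_Y`, `eaf_X`, `eaf_Y`, `action`), with attributes
#'   `exposure_id` and `outcome_id`. Rows whose `action` is not in
#'   `kept`/`sign-flipped`/`proxy-substituted` carry `NA` outcome columns and
#'   are excluded by downstream selection. An empty intersection yields an
#'   empty pair, not an error.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  out_idx <- match(exposure$variant_id, outcome$variant_id)
  n <- nrow(exposure)
  res <- data.frame(
    variant_id = exposure$variant_id,
    chrom = exposure$chrom, pos = exposure$pos,
    b_X = exposure$beta, se_X = exposure$se, p_X = exposure$pval,
    b_Y = NA_real_, se_Y = NA_real_, p_Y = NA_real_,
    eaf_X = exposure$eaf, eaf_Y = NA_real_,
    action = rep("missing-dropped", n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    j <- out_idx[i]
    if (is.na(j)) next
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j];  oa_y <- outcome$other_allele[j]
    b_y <- outcome$beta[j]; eaf_y <- outcome$eaf[j]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      # palindromic: allele labels cannot distinguish strands; orient by
      # frequency if informative, otherwise drop
      same_pair <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == oa_x && oa_y == ea_x) ||
        (ea_y == ALLELE_COMPLEMENT[ea_x] && oa_y == ALLELE_COMPLEMENT[oa_x]) ||
        (ea_y == ALLELE_COMPLEMENT[oa_x] && oa_y == ALLELE_COMPLEMENT[ea_x])
      if (!same_pair) { res$action[i] <- "allele-mismatch-dropped"; next }
      eaf_x <- exposure$eaf[i]
      if (is.na(eaf_x) || is.na(eaf_y) ||
          min(eaf_x, 1 - eaf_x) > palindrome_maf_limit ||
          min(eaf_y, 1 - eaf_y) > palindrome_maf_limit) {
        res$action[i] <- "palindromic-dropped"
        next
      }
      flip <- (eaf_x < 0.5) != (eaf_y < 0.5)
      res$b_Y[i] <- if (flip) -b_y else b_y
      res$eaf_Y[i] <- if (flip) 1 - eaf_y else eaf_y
      res$se_Y[i] <- outcome$se[j]; res$p_Y[i] <- outcome$pval[j]
      res$action[i] <- if (flip) "sign-flipped" else "kept"
      next
    }

    aligned <- (ea_y == ea_x && oa_y == oa_x) ||
      (ea_y == ALLELE_COMPLEMENT[ea_x] && oa_y == ALLELE_COMPLEMENT[oa_x])
    swapped <- (ea_y == oa_x && oa_y == ea_x) ||
      (ea_y == ALLELE_COMPLEMENT[oa_x] && oa_y == ALLELE_COMPLEMENT[ea_x])
    if (aligned) {
      res$b_Y[i] <- b_y; res$eaf_Y[i] <- eaf_y
      res$se_Y[i] <- outcome$se[j]; res$p_Y[i] <- outcome$pval[j]
      res$action[i] <- "kept"
    } else if (swapped) {
      res$b_Y[i] <- -b_y
      res$eaf_Y[i] <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
      res$se_Y[i] <- outcome$se[j]; res$p_Y[i] <- outcome$pval[j]
      res$action[i] <- "sign-flipped"
    } else {
      res$action[i] <- "allele-mismatch-dropped"
    }
  }
  structure(res,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            exposure_type = attr(exposure, "trait_type"),
            outcome_type = attr(outcome, "trait_type"),
            class = c("harmonized_pair", "data.frame"))
}

#' Usable rows of a harmonized pair
#'
#' @param pair a `harmonized_pair`.
#' @return The subset of rows whose action keeps them in the analysis.
#' @export
harmonized_rows <- function(pair) {
  pair[pair$action %in% HARMONIZE_KEPT_ACTIONS, , drop = FALSE]
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %s -> %s\n",
              attr(x, "exposure_id"), attr(x, "outcome_id")))
  print(table(x$action))
  invisible(x)
}

#' Write the harmonization audit log
#'
#' One row per exposure variant with its action code, as a delimited file.
#'
#' @param pair a `harmonized_pair`.
#' @param path output file path.
#' @export
write_harmonization_log <- function(pair, path) {
  utils::write.table(as.data.frame(pair), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove variants genome-wide significant in both traits
#'
#' Rows whose exposure and outcome p-values are both below the threshold are
#' excluded (action `shared-significant-dropped`): such variants are as
#' strongly associated with the outcome as the exposure and violate the
#' exclusion-restriction spirit of instrument selection.
#'
#' @param pair a `harmonized_pair`.
#' @param p_thresh significance threshold, default `5e-8`.
#' @return The pair with offending rows re-flagged; the number removed is
#'   recorded in attribute `n_shared_removed`.
#' @export
remove_shared_significant <- function(pair, p_thresh = 5e-8) {
  usable <- pair$action %in% HARMONIZE_KEPT_ACTIONS
  hit <- usable & !is.na(pair$p_X) & !is.na(pair$p_Y) &
    pair$p_X < p_thresh & pair$p_Y < p_thresh
  pair$action[hit] <- "shared-significant-dropped"
  attr(pair, "n_shared_removed") <- sum(hit)
  pair
}
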