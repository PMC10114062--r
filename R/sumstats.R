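#' Default column dialect for summary-statistics files
#'
#' Maps the canonical field names used internally to the column names found in
#' a delimited GWAS summary-statistics export. Override individual entries to
#' adapt to other providers.
#'
#' @return Named list mapping canonical names to file column names.
#' @export
default_dialect <- function() {
  list(
    variant_id = "SNP", chrom = "chr", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval",
    n = "n", n_case = "ncase", n_control = "ncontrol"
  )
}

#' Read a column-dialect configuration file
#'
#' Accepts a YAML or JSON file whose top-level keys are canonical field names
#' (see [default_dialect()]); unspecified fields fall back to the default.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list usable as the `dialect` argument of [read_sumstats()].
#' @export
read_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop_domain("reading a JSON dialect requires the jsonlite package")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_domain("reading a YAML dialect requires the yaml package")
    }
    yaml::read_yaml(path)
  }
  utils::modifyList(default_dialect(), as.list(cfg))
}

REQUIRED_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "beta", "se", "pval")

#' Construct a validated summary-statistics table
#'
#' Applies the row-level validation rules: rows with missing beta or standard
#' error are dropped, non-positive standard errors and non-biallelic or
#' identical allele codes reject the row, duplicated variant ids keep the
#' first occurrence, and p-values are checked (warn-only) for consistency
#' with `beta/se` under the two-sided normal approximation.
#'
#' @param records data frame with canonical columns (`variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `n_case`, `n_control`; the last four optional).
#' @param trait_id identifier for the trait.
#' @param trait_type one of `"continuous"`, `"binary"`,
#'   `"ordered-categorical"`. Ordered-categorical traits are analysed exactly
#'   as continuous; the label is kept for reporting.
#' @param unit_note free-text unit annotation (e.g. `"SD"`, `"log-OR"`).
#' @param p_rel_tol relative tolerance for the p-value consistency check.
#' @return An object of class `sumstats`: a data frame of validated records
#'   with trait metadata attached as attributes.
#' @export
sumstats_table <- function(records, trait_id, trait_type = "continuous",
                           unit_note = NULL, p_rel_tol = 0.25) {
  trait_type <- match.arg(trait_type,
                          c("continuous", "binary", "ordered-categorical"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_FIELDS, names(records))
  if (length(missing_cols)) {
    stop_domain("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("eaf", "n", "n_case", "n_control")) {
    if (!opt %in% names(records)) records[[opt]] <- NA_real_
  }
  records <- records[, c(REQUIRED_FIELDS[1:5], "eaf", "beta", "se", "pval",
                         "n", "n_case", "n_control")]

  n0 <- nrow(records)
  miss <- is.na(records$beta) | is.na(records$se)
  if (any(miss)) {
    message(sprintf("[%s] dropped %d row(s) with missing beta or se",
                    trait_id, sum(miss)))
    records <- records[!miss, , drop = FALSE]
  }
  bad_se <- records$se <= 0
  if (any(bad_se)) {
    warning(sprintf("[%s] rejected %d row(s) with non-positive se",
                    trait_id, sum(bad_se)), call. = FALSE)
    records <- records[!bad_se, , drop = FALSE]
  }
  ea <- toupper(records$effect_allele)
  oa <- toupper(records$other_allele)
  ok_allele <- ea %in% c("A", "C", "G", "T") & oa %in% c("A", "C", "G", "T") &
    ea != oa
  if (any(!ok_allele)) {
    warning(sprintf("[%s] rejected %d row(s) with non-biallelic or identical alleles",
                    trait_id, sum(!ok_allele)), call. = FALSE)
    records <- records[ok_allele, , drop = FALSE]
    ea <- ea[ok_allele]; oa <- oa[ok_allele]
  }
  records$effect_allele <- ea
  records$other_allele <- oa
  dup <- duplicated(records$variant_id)
  if (any(dup)) {
    warning(sprintf("[%s] %d duplicated variant id(s); keeping first occurrence",
                    trait_id, sum(dup)), call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  bad_p <- !is.na(records$pval) & (records$pval <= 0 | records$pval > 1)
  if (any(bad_p)) {
    warning(sprintf("[%s] rejected %d row(s) with p outside (0, 1]",
                    trait_id, sum(bad_p)), call. = FALSE)
    records <- records[!bad_p, , drop = FALSE]
  }
  # warn-only consistency: public summary stats routinely carry rounded p
  if (nrow(records)) {
    p_expect <- 2 * stats::pnorm(-abs(records$beta / records$se))
    chk <- !is.na(records$pval) & p_expect > 1e-300
    off <- chk & abs(log(records$pval / p_expect)) > log(1 + p_rel_tol) &
      abs(records$pval - p_expect) > 1e-4
    if (any(off)) {
      warning(sprintf("[%s] %d p-value(s) inconsistent with beta/se (kept)",
                      trait_id, sum(off)), call. = FALSE)
    }
  }
  if (trait_type == "binary" &&
      (all(is.na(records$n_case)) || all(is.na(records$n_control)))) {
    stop_domain("binary trait '", trait_id,
                "' requires n_case and n_control columns")
  }
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_type = trait_type,
            unit_note = unit_note %||%
              if (trait_type == "binary") "log-OR" else "SD",
            n_input_rows = n0,
            class = c("sumstats", "data.frame"))
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path tab- or comma-delimited file with a header row. The separator
#'   is sniffed from the header line.
#' @param dialect named list mapping canonical field names to file columns;
#'   see [default_dialect()] and [read_dialect()].
#' @param trait_id trait identifier; defaults to the file name.
#' @param trait_type,unit_note passed to [sumstats_table()].
#' @return A validated `sumstats` object.
#' @export
read_sumstats <- function(path, dialect = default_dialect(),
                          trait_id = NULL, trait_type = "continuous",
                          unit_note = NULL) {
  dialect <- utils::modifyList(default_dialect(), as.list(dialect))
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  out <- list()
  for (field in names(default_dialect())) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) {
      out[[field]] <- raw[[col]]
    } else if (field %in% REQUIRED_FIELDS) {
      stop_domain("missing mandatory column '", col, "' (field ", field,
                  ") in ", path)
    }
  }
  sumstats_table(as.data.frame(out, stringsAsFactors = FALSE),
                 trait_id = trait_id %||% basename(path),
                 trait_type = trait_type, unit_note = unit_note)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s, %s)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), attr(x, "unit_note")))
  cat(sprintf("  %d variants\n", nrow(x)))
  invisible(x)
}

#' Effective sample size for a case-control study
#'
#' `4 * n_case * n_control / (n_case + n_control)`: the size of a balanced
#' study with equivalent power. Equals the total sample size when cases and
#' controls are balanced, and is smaller otherwise.
#'
#' @param n_case,n_control positive case and control counts (vectorised).
#' @return Numeric vector of effective sample sizes.
#' @export
#' @examples
#' effective_sample_size(5000, 5000) # 10000
#' effective_sample_size(100, 300)   # 300
effective_sample_size <- function(n_case, n_control) {
  if (any(!is.finite(n_case)) || any(!is.finite(n_control)) ||
      any(n_case <= 0) || any(n_control <= 0)) {
    stop_domain("n_case and n_control must be positive")
  }
  4 * n_case * n_control / (n_case + n_control)
}

#' Default trait-screening thresholds
#'
#' Sample size (effective size for binary traits) above 5000, more than
#' 450 000 variants, European ancestry, non-sex-specific, more than three
#' independent genome-wide significant signals, heritability Z above 4 and
#' genetic-correlation (with the index trait) Z above 2.
#'
#' @return Named list of thresholds.
#' @export
screen_defaults <- function() {
  list(min_n = 5000, min_variants = 450000, ancestry = "European",
       min_gws_signals = 3, min_h2_z = 4, min_rg_z = 2)
}

#' Screen candidate traits on study-level metadata
#'
#' Partitions trait metadata into kept and excluded sets. Each excluded trait
#' carries the first failing rule, applied in order: completeness, sample
#' size, variant count, ancestry, sex-specificity, genome-wide significant
#' signal count, heritability Z, genetic-correlation Z. Heritability and
#' correlation rules are keep-if-strictly-greater (a trait at Z exactly equal
#' to the threshold is removed).
#'
#' @param metas data frame with columns `trait_id`, `n`, `n_case`,
#'   `n_control`, `n_variants`, `ancestry`, `sex_specific`, `n_gws_signals`,
#'   `h2_Z`, `rg_with_index_Z` (optional `category`, `trait_type`).
#' @param cfg thresholds, see [screen_defaults()].
#' @return List with elements `kept` (data frame) and `excluded` (data frame
#'   with a `reason` column).
#' @export
screen_traits <- function(metas, cfg = screen_defaults()) {
  cfg <- utils::modifyList(screen_defaults(), as.list(cfg))
  metas <- as.data.frame(metas, stringsAsFactors = FALSE)
  if (!"category" %in% names(metas)) metas$category <- NA_character_
  reason <- rep(NA_character_, nrow(metas))
  for (i in seq_len(nrow(metas))) {
    m <- metas[i, ]
    binary <- !is.na(m$n_case) && !is.na(m$n_control)
    eff_n <- if (binary) {
      if (m$n_case > 0 && m$n_control > 0) {
        effective_sample_size(m$n_case, m$n_control)
      } else NA_real_
    } else m$n
    reason[i] <- if (anyNA(c(m$n_variants, m$ancestry, m$sex_specific,
                             m$n_gws_signals, m$h2_Z, m$rg_with_index_Z)) ||
                     is.na(eff_n)) {
      "incomplete"
    } else if (eff_n <= cfg$min_n) {
      "sample-size"
    } else if (m$n_variants <= cfg$min_variants) {
      "variant-count"
    } else if (m$ancestry != cfg$ancestry) {
      "ancestry"
    } else if (isTRUE(as.logical(m$sex_specific))) {
      "sex-specific"
    } else if (m$n_gws_signals <= cfg$min_gws_signals) {
      "gws-signals"
    } else if (m$h2_Z <= cfg$min_h2_z) {
      "heritability-z"
    } else if (m$rg_with_index_Z <= cfg$min_rg_z) {
      "genetic-correlation-z"
    } else NA_character_
  }
  kept <- metas[is.na(reason), , drop = FALSE]
  excluded <- metas[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}
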