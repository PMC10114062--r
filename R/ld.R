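#' Construct an LD reference from pairwise r-squared records
#'
#' The reference is interpreted as symmetric; absent pairs have r2 = 0 and
#' every variant has r2 = 1 with itself.
#'
#' @param pairs data frame with columns `variant_a`, `variant_b`, `r2`.
#' @param positions data frame with columns `variant_id`, `chrom`, `pos`
#'   (optional; positions may also come from the summary statistics).
#' @return An object of class `ld_ref`.
#' @export
ld_reference <- function(pairs = NULL, positions = NULL) {
  env <- new.env(parent = emptyenv())
  if (!is.null(pairs) && nrow(pairs)) {
    stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(pairs)))
    if (any(pairs$r2 < 0 | pairs$r2 > 1)) stop_domain("r2 must be in [0, 1]")
    a <- as.character(pairs$variant_a); b <- as.character(pairs$variant_b)
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    for (i in seq_along(key)) assign(key[i], pairs$r2[i], envir = env)
  }
  structure(list(env = env, pairs = pairs, positions = positions),
            class = "ld_ref")
}

#' Read an LD reference from delimited files
#'
#' @param pair_path file with header `variant_a variant_b r2`.
#' @param pos_path optional file with header `variant_id chrom pos`.
#' @return An `ld_ref` object.
#' @export
read_ld_reference <- function(pair_path, pos_path = NULL) {
  pairs <- utils::read.table(pair_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  positions <- if (!is.null(pos_path)) {
    utils::read.table(pos_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  ld_reference(pairs, positions)
}

#' Pairwise r-squared lookup
#'
#' @param ld an `ld_ref` (or `NULL`, in which case all pairs are 0).
#' @param a,b variant ids (scalars).
#' @return r2 in `[0, 1]`; 1 when `a == b`, 0 for unrecorded pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  if (is.null(ld)) return(0)
  key <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  get0(key, envir = ld$env, ifnotfound = 0)
}

#' Greedy LD clumping
#'
#' Candidates below `p_max` are ranked by ascending p (ties broken by
#' lexicographic variant id for determinism) and accepted greedily: a variant
#' is kept iff its r2 with every already-accepted variant on the same
#' chromosome within `window_kb` is below `r2_max`. Variants outside the
#' window (or on another chromosome) are treated as independent. When no LD
#' reference is supplied, distance-only clumping is applied with a warning:
#' any candidate within the window of an accepted variant is rejected.
#'
#' @param x a `sumstats` object, `harmonized_pair`, or data frame with
#'   columns `variant_id`, `chrom`, `pos` and a p-value column (`pval` or
#'   `p_X`).
#' @param ld an `ld_ref` or `NULL`.
#' @param r2_max clump threshold, default 0.001.
#' @param window_kb window in kilobases, default 10000.
#' @param p_max candidate significance threshold, default 5e-8.
#' @return Character vector of kept variant ids (possibly empty).
#' @export
clump <- function(x, ld = NULL, r2_max = 0.001, window_kb = 10000,
                  p_max = 5e-8) {
  df <- as.data.frame(x)
  pcol <- if ("pval" %in% names(df)) "pval" else if ("p_X" %in% names(df)) "p_X"
  else stop_domain("no p-value column found")
  cand <- df[!is.na(df[[pcol]]) & df[[pcol]] < p_max, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  cand <- cand[order(cand[[pcol]], cand$variant_id), , drop = FALSE]
  distance_only <- is.null(ld)
  if (distance_only) {
    warning("no LD reference supplied; distance-only clumping", call. = FALSE)
  }
  window_bp <- window_kb * 1000
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      if (cand$chrom[i] != cand$chrom[j]) next
      if (abs(cand$pos[i] - cand$pos[j]) > window_bp) next
      if (distance_only ||
          ld_r2(ld, cand$variant_id[i], cand$variant_id[j]) >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  cand$variant_id[kept]
}

#' Find LD proxies for instruments missing from the outcome
#'
#' For each missing exposure instrument, returns the outcome-present variant
#' with the highest r2 at or above `r2_min` (ties broken by variant id); no
#' substitution when no variant qualifies.
#'
#' @param missing character vector of missing variant ids.
#' @param outcome a `sumstats` object for the outcome trait.
#' @param ld an `ld_ref`; without one no proxies can be found.
#' @param r2_min minimum r2 for a proxy, default 0.8.
#' @return Data frame with columns `original`, `proxy`, `r2` (zero rows when
#'   nothing qualifies).
#' @export
substitute_proxies <- function(missing, outcome, ld, r2_min = 0.8) {
  empty <- data.frame(original = character(0), proxy = character(0),
                      r2 = numeric(0), stringsAsFactors = FALSE)
  if (!length(missing) || is.null(ld) || is.null(ld$pairs) ||
      !nrow(ld$pairs)) return(empty)
  present <- outcome$variant_id
  out <- empty
  for (v in missing) {
    sel <- ld$pairs$variant_a == v | ld$pairs$variant_b == v
    if (!any(sel)) next
    partner <- ifelse(ld$pairs$variant_a[sel] == v,
                      ld$pairs$variant_b[sel], ld$pairs$variant_a[sel])
    r2 <- ld$pairs$r2[sel]
    qual <- partner %in% present & r2 >= r2_min & partner != v
    if (!any(qual)) next
    partner <- partner[qual]; r2 <- r2[qual]
    best <- order(-r2, partner)[1]
    out <- rbind(out, data.frame(original = v, proxy = partner[best],
                                 r2 = r2[best], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
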