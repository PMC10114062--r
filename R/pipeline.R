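#' Default pipeline thresholds
#'
#' Every stage threshold with its standard default: genome-wide instrument
#' significance 5e-8 with clumping at r2 < 0.001 over 10 Mb windows, proxy
#' substitution at r2 >= 0.8, shared-significance removal at 5e-8, FDR 0.05
#' at the main stage, mean F above 10, I2GX gates at 0.6/0.9, looser
#' selection (p < 1e-3, r2 < 0.01, 250 kb) for the Bayesian model
#' comparison, and a Bonferroni correction over the model-comparison tests
#' actually run.
#'
#' @return Named list of thresholds and tuning constants.
#' @export
pipeline_config <- function() {
  list(instrument_p = 5e-8, clump_r2 = 0.001, clump_window_kb = 10000,
       proxy_r2_min = 0.8, shared_p = 5e-8, palindrome_maf_limit = 0.42,
       alpha = 0.05, fdr_alpha = 0.05, f_min = 10,
       i2gx_low = 0.6, i2gx_high = 0.9,
       cause_p_max = 1e-3, cause_r2 = 0.01, cause_window_kb = 250,
       cause_alpha = 0.05,
       boot_B = 500, simex_B = 500, presso_n_sim = 1000,
       egger_policy = "strict", K_prior = 5,
       gamma_sd = 0.6, eta_sd = 0.6, q_a = 1, q_b = 10)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; unspecified keys keep their defaults.
#'
#' @param path config file path.
#' @return The merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop_domain("JSON configs require the jsonlite package")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_domain("YAML configs require the yaml package")
    }
    yaml::read_yaml(path)
  }
  utils::modifyList(pipeline_config(), as.list(cfg))
}

table_n <- function(tbl) {
  n <- stats::median(tbl$n, na.rm = TRUE)
  if (!is.finite(n)) stop_domain("summary statistics carry no sample size")
  n
}

table_binary <- function(tbl) {
  if (attr(tbl, "trait_type") != "binary") return(NULL)
  c(stats::median(tbl$n_case, na.rm = TRUE),
    stats::median(tbl$n_control, na.rm = TRUE))
}

# One direction of the MR battery: instrument selection through estimation.
run_direction <- function(exposure, outcome, ld, cfg, seed) {
  direction <- paste(attr(exposure, "trait_id"), "->",
                     attr(outcome, "trait_id"))
  kept <- suppressWarnings(clump(exposure, ld, cfg$clump_r2,
                                 cfg$clump_window_kb, cfg$instrument_p))
  if (!length(kept)) {
    return(list(status = "no-instruments", direction = direction))
  }
  pair <- harmonize(exposure, outcome, cfg$palindrome_maf_limit)
  missing <- kept[pair$action[match(kept, pair$variant_id)] ==
                    "missing-dropped"]
  prox <- substitute_proxies(missing, outcome, ld, cfg$proxy_r2_min)
  if (nrow(prox)) {
    # the proxy's outcome association stands in for the missing variant;
    # alleles are taken as tagging the exposure variant's effect allele
    for (i in seq_len(nrow(prox))) {
      ri <- match(prox$original[i], pair$variant_id)
      oj <- match(prox$proxy[i], outcome$variant_id)
      pair$b_Y[ri] <- outcome$beta[oj]
      pair$se_Y[ri] <- outcome$se[oj]
      pair$p_Y[ri] <- outcome$pval[oj]
      pair$eaf_Y[ri] <- outcome$eaf[oj]
      pair$action[ri] <- "proxy-substituted"
    }
  }
  pair <- remove_shared_significant(pair, cfg$shared_p)
  iset <- instrument_set(pair, keep = kept,
                         n_exposure = table_n(exposure),
                         n_outcome = table_n(outcome),
                         exposure_binary = table_binary(exposure),
                         outcome_binary = table_binary(outcome),
                         direction = direction)
  if (nrow(iset) < 2) {
    return(list(status = "too-few-instruments", direction = direction,
                instruments = iset))
  }
  input <- as_mr_input(iset)
  fit <- mr_fit(input, boot_B = cfg$boot_B, seed = seed,
                simex_B = cfg$simex_B)
  presso <- mr_presso(input, n_sim = cfg$presso_n_sim, seed = seed + 10L,
                      alpha = cfg$alpha)
  steiger_set <- steiger_filter(iset)
  steiger_ivw <- if (nrow(steiger_set) >= 2) {
    r <- mr_ivw(as_mr_input(steiger_set))
    r$method <- "ivw_steiger"
    r
  } else mr_result_na("ivw_steiger", nrow(steiger_set),
                      "fewer than 2 instruments after Steiger filtering")
  exposure_type <- attr(exposure, "trait_type")
  fstats <- if (exposure_type != "binary") f_statistics(iset) else NULL
  loo <- if (length(input$b_exp) >= 3) mr_leave_one_out(input) else NULL
  list(status = "ok", direction = direction,
       exposure_id = attr(exposure, "trait_id"),
       outcome_id = attr(outcome, "trait_id"),
       exposure_type = exposure_type,
       pair = pair, instruments = iset, input = input,
       fit = fit, presso = presso, steiger_ivw = steiger_ivw,
       f_stats = fstats, leave_one_out = loo,
       n_steiger_removed = attr(steiger_set, "n_steiger_removed"))
}

direction_sensitivity <- function(bundle, fdr_p, cfg) {
  evaluate_sensitivity(
    ivw = bundle$fit$ivw, fdr_p = fdr_p,
    battery = list(weighted_median = bundle$fit$weighted_median,
                   weighted_mode = bundle$fit$weighted_mode),
    presso = bundle$presso, steiger_ivw = bundle$steiger_ivw,
    egger = bundle$fit$egger, simex = bundle$fit$simex,
    f_stats = bundle$f_stats, exposure_type = bundle$exposure_type,
    alpha = cfg$alpha, egger_policy = cfg$egger_policy
  )
}

direction_cause <- function(bundle, cfg) {
  cause_lite(bundle$pair, ld = bundle$ld, r2_max = cfg$cause_r2,
             window_kb = cfg$cause_window_kb, p_max = cfg$cause_p_max,
             K = cfg$K_prior, gamma_sd = cfg$gamma_sd, eta_sd = cfg$eta_sd,
             q_a = cfg$q_a, q_b = cfg$q_b)
}

#' Run the full bidirectional analysis for one trait pair
#'
#' Executes the staged analysis in both directions: instrument selection
#' (clumping, proxies, shared-significance removal), the estimator battery
#' with heterogeneity and leave-one-out, MR-PRESSO, Steiger-filtered IVW, F
#' statistics, the sensitivity verdict, and — for directions passing the
#' sensitivity gate (or always/never, per `run_cause`) — the
#' sharing-versus-causal model comparison. In a standalone pair the FDR
#' correction is Benjamini-Hochberg over the two directions' IVW p-values;
#' in a screen use [run_screen()], which pools over all tests. The
#' model-comparison Bonferroni denominator is the number of such tests
#' actually run.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param ld optional `ld_ref`.
#' @param cfg configuration list, see [pipeline_config()].
#' @param seed RNG seed for the stochastic components.
#' @param run_cause `"auto"` (gate on sensitivity), `"always"`, `"never"`.
#' @return An object of class `mr_screen_pair`: per-direction bundles,
#'   decision records, and the report tables.
#' @export
run_pair <- function(exposure, outcome, ld = NULL, cfg = pipeline_config(),
                     seed = 1, run_cause = c("auto", "always", "never")) {
  run_cause <- match.arg(run_cause)
  cfg <- utils::modifyList(pipeline_config(), as.list(cfg))
  bundles <- list(
    forward = run_direction(exposure, outcome, ld, cfg, seed),
    reverse = run_direction(outcome, exposure, ld, cfg, seed + 1000L)
  )
  bundles$forward$ld <- ld
  bundles$reverse$ld <- ld
  ok <- vapply(bundles, function(b) b$status == "ok", logical(1))
  praw <- vapply(bundles, function(b) {
    if (b$status == "ok") b$fit$ivw$pval else NA_real_
  }, numeric(1))
  fdr <- rep(NA_real_, 2)
  fdr[ok] <- bh_fdr(praw[ok])
  records <- list()
  cause_fits <- list()
  # stage 2: sensitivity for directions passing the FDR gate
  sens <- list(forward = NULL, reverse = NULL)
  for (d in names(bundles)[ok]) {
    if (!is.na(fdr[match(d, names(bundles))]) &&
        fdr[match(d, names(bundles))] < cfg$fdr_alpha) {
      sens[[d]] <- direction_sensitivity(bundles[[d]],
                                         fdr[match(d, names(bundles))], cfg)
    }
  }
  # stage 3: model comparison
  for (d in names(bundles)[ok]) {
    gate <- switch(run_cause,
                   always = TRUE,
                   never = FALSE,
                   auto = isTRUE(sens[[d]]$meets_sensitivity))
    if (gate) {
      cause_fits[[d]] <- tryCatch(direction_cause(bundles[[d]], cfg),
                                  error = function(e) NULL)
    }
  }
  m_cause <- length(Filter(Negate(is.null), cause_fits))
  bonf <- if (m_cause) bonferroni_threshold(cfg$cause_alpha, m_cause)
  else NA_real_
  for (i in seq_along(bundles)) {
    d <- names(bundles)[i]
    b <- bundles[[d]]
    if (b$status != "ok") next
    cp <- if (!is.null(cause_fits[[d]])) {
      cause_fits[[d]]$comparison$p_one_sided
    } else NA_real_
    records[[d]] <- classify_pair(b$exposure_id, b$outcome_id, b$direction,
                                  b$fit$ivw, fdr[i], sens[[d]], cp, bonf,
                                  alpha = cfg$fdr_alpha)
  }
  records <- if (length(records)) {
    mark_bidirectional(do.call(rbind, records))
  } else NULL
  cause_tab <- do.call(rbind, lapply(names(cause_fits), function(d) {
    cf <- cause_fits[[d]]
    if (is.null(cf)) return(NULL)
    b <- bundles[[d]]
    data.frame(exposure_id = b$exposure_id, outcome_id = b$outcome_id,
               direction = b$direction,
               gamma_median = cf$causal$gamma$median,
               gamma_ci_low = cf$causal$gamma$ci_low,
               gamma_ci_high = cf$causal$gamma$ci_high,
               delta_elpd = cf$comparison$delta_elpd,
               se_delta = cf$comparison$se_delta,
               p_one_sided = cf$comparison$p_one_sided,
               stringsAsFactors = FALSE)
  }))
  structure(list(bundles = bundles, records = records,
                 cause_fits = cause_fits,
                 report = build_report(records, cause_tab),
                 cause_bonferroni = bonf, seed = seed),
            class = "mr_screen_pair")
}

#' @export
print.mr_screen_pair <- function(x, ...) {
  cat("Bidirectional MR screen\n")
  if (!is.null(x$records)) {
    print(x$records[, c("direction", "L_used", "ivw_estimate", "ivw_p_fdr",
                        "meets_sensitivity", "cause_p", "final_class",
                        "bidirectional")], row.names = FALSE, digits = 4)
  } else {
    cat("  no direction could be analysed\n")
  }
  invisible(x)
}

#' Screen many candidate traits against an index trait
#'
#' Applies the metadata screen, then runs the bidirectional pipeline for
#' every kept trait against the index trait. IVW p-values are pooled over
#' all tests run (both directions, all pairs) for the Benjamini-Hochberg
#' correction; the sensitivity battery runs for tests passing the FDR gate;
#' the model comparison runs for those passing sensitivity, with a
#' Bonferroni threshold over the comparisons actually run. Per-pair
#' failures are quarantined and reported, not fatal.
#'
#' @param index `sumstats` for the index trait.
#' @param traits named list of `sumstats` for candidate traits.
#' @param metas trait metadata (see [screen_traits()]); `NULL` skips the
#'   metadata screen.
#' @param ld optional `ld_ref` shared by all pairs.
#' @param cfg configuration list, see [pipeline_config()].
#' @param seed base seed; each pair derives its own stream.
#' @return An object of class `mr_screen`: `screen` (kept/excluded
#'   metadata), `pairs` (per-trait `mr_screen_pair`-like bundles),
#'   `records`, `report`, `failures`.
#' @export
run_screen <- function(index, traits, metas = NULL, ld = NULL,
                       cfg = pipeline_config(), seed = 1) {
  cfg <- utils::modifyList(pipeline_config(), as.list(cfg))
  screen <- if (!is.null(metas)) screen_traits(metas) else {
    list(kept = data.frame(trait_id = names(traits),
                           stringsAsFactors = FALSE),
         excluded = NULL)
  }
  keep_ids <- intersect(screen$kept$trait_id, names(traits))
  failures <- list()
  bundles <- list()
  for (tid in keep_ids) {
    res <- tryCatch({
      list(
        forward = run_direction(index, traits[[tid]], ld, cfg,
                                seed + hash_id(tid) %% 100000L),
        reverse = run_direction(traits[[tid]], index, ld, cfg,
                                seed + hash_id(tid) %% 100000L + 1L)
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[tid]] <- conditionMessage(res)
    } else {
      res$forward$ld <- ld
      res$reverse$ld <- ld
      bundles[[tid]] <- res
    }
  }
  # pool every IVW test for the FDR correction
  flat <- list()
  for (tid in names(bundles)) {
    for (d in c("forward", "reverse")) {
      b <- bundles[[tid]][[d]]
      if (b$status == "ok") flat[[paste(tid, d)]] <- b
    }
  }
  praw <- vapply(flat, function(b) b$fit$ivw$pval, numeric(1))
  fdr <- if (length(praw)) bh_fdr(praw) else numeric(0)
  sens <- cause_fits <- stats::setNames(vector("list", length(flat)),
                                        names(flat))
  for (i in seq_along(flat)) {
    if (fdr[i] < cfg$fdr_alpha) {
      sens[[i]] <- tryCatch(direction_sensitivity(flat[[i]], fdr[i], cfg),
                            error = function(e) NULL)
      if (isTRUE(sens[[i]]$meets_sensitivity)) {
        cause_fits[[i]] <- tryCatch(direction_cause(flat[[i]], cfg),
                                    error = function(e) NULL)
      }
    }
  }
  m_cause <- length(Filter(Negate(is.null), cause_fits))
  bonf <- if (m_cause) bonferroni_threshold(cfg$cause_alpha, m_cause)
  else NA_real_
  meta_cat <- function(id) {
    if (is.null(metas) || !"category" %in% names(metas)) return(NA_character_)
    cat <- metas$category[metas$trait_id == id]
    if (length(cat)) cat[1] else NA_character_
  }
  records <- list()
  cause_rows <- list()
  for (i in seq_along(flat)) {
    b <- flat[[i]]
    cf <- cause_fits[[i]]
    cp <- if (!is.null(cf)) cf$comparison$p_one_sided else NA_real_
    other <- setdiff(c(b$exposure_id, b$outcome_id),
                     attr(index, "trait_id"))
    records[[i]] <- classify_pair(b$exposure_id, b$outcome_id, b$direction,
                                  b$fit$ivw, fdr[i], sens[[i]], cp, bonf,
                                  alpha = cfg$fdr_alpha,
                                  category = meta_cat(other[1]))
    if (!is.null(cf)) {
      cause_rows[[length(cause_rows) + 1]] <- data.frame(
        exposure_id = b$exposure_id, outcome_id = b$outcome_id,
        direction = b$direction, gamma_median = cf$causal$gamma$median,
        gamma_ci_low = cf$causal$gamma$ci_low,
        gamma_ci_high = cf$causal$gamma$ci_high,
        delta_elpd = cf$comparison$delta_elpd,
        se_delta = cf$comparison$se_delta,
        p_one_sided = cf$comparison$p_one_sided, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(records)) {
    mark_bidirectional(do.call(rbind, records))
  } else NULL
  structure(list(screen = screen, pairs = bundles, records = records,
                 cause_fits = cause_fits,
                 report = build_report(records, do.call(rbind, cause_rows)),
                 cause_bonferroni = bonf, failures = failures),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("Trait screen: %d kept, %d excluded, %d pair failure(s)\n",
              nrow(x$screen$kept),
              if (is.null(x$screen$excluded)) 0 else nrow(x$screen$excluded),
              length(x$failures)))
  if (!is.null(x$records)) {
    print(x$report$stage_counts, row.names = FALSE)
  }
  invisible(x)
}
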