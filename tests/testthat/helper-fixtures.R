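# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except what a test itself writes.

toy_records <- function(n = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1e6,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = runif(n, 0.1, 0.5),
    beta = rnorm(n, 0, 0.05), se = runif(n, 0.005, 0.02),
    pval = NA_real_, n = 10000, n_case = NA_real_, n_control = NA_real_,
    stringsAsFactors = FALSE
  ) |> within(pval <- 2 * pnorm(-abs(beta / se)))
}

toy_sumstats <- function(records = toy_records(), trait_id = "toy", ...) {
  suppressWarnings(sumstats_table(records, trait_id = trait_id, ...))
}

# mr_input with ratios exactly beta (no noise added), unit exposure effects
ratio_input <- function(ratios, ratio_se = rep(0.1, length(ratios)),
                        se_exp = rep(1e-6, length(ratios))) {
  mr_input(b_exp = rep(1, length(ratios)), se_exp = se_exp,
           b_out = ratios, se_out = ratio_se)
}

# draws a well-behaved random MR instance around slope `gamma`
random_input <- function(L, gamma = 0.3, sd_beta = 0.05, se_exp = 0.003,
                         se_out = 0.01, seed = 1) {
  set.seed(seed)
  beta <- rnorm(L, 0, sd_beta)
  mr_input(beta + rnorm(L, 0, se_exp), rep(se_exp, L),
           gamma * beta + rnorm(L, 0, se_out), rep(se_out, L))
}

# quick mr_result stub for decision-logic tests
stub_result <- function(estimate, pval, method = "stub") {
  mrscreen:::mr_result(method, estimate, se = abs(estimate) / 2, pval = pval,
                       L_used = 10)
}

stub_egger <- function(estimate, pval, intercept_p, i2gx) {
  r <- stub_result(estimate, pval, "mr_egger")
  r$extra <- list(egger_intercept = 0.01, egger_intercept_se = 0.005,
                  egger_intercept_p = intercept_p, i2gx = i2gx)
  r
}

stub_presso <- function(estimate, pval) {
  structure(list(global_rss_obs = 1, global_p = 0.5, n_sim = 100,
                 outliers = NULL, corrected = NULL,
                 estimate = stub_result(estimate, pval, "mr_presso"),
                 distortion_note = ""), class = "mr_presso")
}

default_meta <- function(trait_id = "t", n = 50000, n_case = NA,
                         n_control = NA, n_variants = 5e5,
                         ancestry = "European", sex_specific = FALSE,
                         n_gws_signals = 10, h2_Z = 6, rg_with_index_Z = 3,
                         category = "lifestyle") {
  data.frame(trait_id = trait_id, n = n, n_case = n_case,
             n_control = n_control, n_variants = n_variants,
             ancestry = ancestry, sex_specific = sex_specific,
             n_gws_signals = n_gws_signals, h2_Z = h2_Z,
             rg_with_index_Z = rg_with_index_Z, category = category,
             stringsAsFactors = FALSE)
}
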