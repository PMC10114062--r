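#' Configuration for the synthetic two-sample GWAS generator
#'
#' Describes the generative model behind a pair of summary-statistic tables:
#' per-variant true exposure effects drawn from a zero-mean normal mixture;
#' an outcome built from a causal effect `gamma`, correlated pleiotropy
#' acting through a shared factor (`eta` on a `q` fraction of variants),
#' uncorrelated pleiotropy (`pi_uncorr` fraction with `N(0, theta_sd^2)`
#' direct effects), and optional reverse-causation variants whose primary
#' effect is on the outcome; independent estimation error in the two samples
#' (standardized-genotype asymptotics); and optional independent LD blocks
#' for clumping and proxy exercises.
#'
#' @param L number of variants.
#' @param n_exp,n_out sample sizes of the exposure and outcome GWAS.
#' @param exposure_type,outcome_type `"continuous"` or `"binary"` (binary
#'   traits are generated on the log-OR scale with case-fraction-inflated
#'   standard errors).
#' @param case_frac_exp,case_frac_out case fractions for binary traits.
#' @param gamma true causal effect of exposure on outcome.
#' @param eta shared-factor (correlated-pleiotropy) effect.
#' @param q proportion of variants acting through the shared factor.
#' @param pi_uncorr fraction of variants with uncorrelated pleiotropy.
#' @param theta_sd effect sd of the uncorrelated pleiotropy.
#' @param effect_prior data frame (`weight`, `sd`) for true exposure
#'   effects; default a single `N(0, 0.05^2)` component, strong enough that
#'   most variants reach genome-wide significance at the default sample
#'   sizes.
#' @param maf_range uniform range of minor-allele frequencies.
#' @param ld_blocks `NULL` for independent variants, or
#'   `list(block_size =, r2 =)`: consecutive variants form blocks whose
#'   members tag the block's lead signal at the given r2 and appear in the
#'   emitted LD reference.
#' @param reverse_fraction fraction of variants whose primary effect is on
#'   the outcome (drawn `N(0, reverse_sd^2)`), back-propagated to the
#'   exposure with coefficient `reverse_coef`.
#' @param reverse_sd,reverse_coef see `reverse_fraction`.
#' @param swap_fraction fraction of outcome rows emitted with their alleles
#'   swapped (and beta negated, frequency complemented), to exercise
#'   harmonization.
#' @param palindromic_fraction fraction of variants given A/T or C/G allele
#'   pairs.
#' @param sample_overlap correlation between the two samples' estimation
#'   errors (0 = the two-sample design).
#' @param seed base seed; all randomness flows from it through per-variant
#'   counter streams keyed by variant id, so output is byte-identical across
#'   runs and invariant to row order.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(L = 100, n_exp = 1e5, n_out = 1e5,
                       exposure_type = "continuous",
                       outcome_type = "continuous",
                       case_frac_exp = 0.5, case_frac_out = 0.5,
                       gamma = 0, eta = 0, q = 0,
                       pi_uncorr = 0, theta_sd = 0.02,
                       effect_prior = data.frame(weight = 1, sd = 0.05),
                       maf_range = c(0.1, 0.5), ld_blocks = NULL,
                       reverse_fraction = 0, reverse_sd = 0.1,
                       reverse_coef = 0.5, swap_fraction = 0,
                       palindromic_fraction = 0, sample_overlap = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  if (!is_count(L) || L < 1) stop_domain("L must be a positive integer")
  if (n_exp <= 0 || n_out <= 0) stop_domain("sample sizes must be positive")
  for (p in c("q", "pi_uncorr", "reverse_fraction", "swap_fraction",
              "palindromic_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_domain(p, " must be in [0, 1]")
  }
  if (abs(sum(effect_prior$weight) - 1) > 1e-8 || any(effect_prior$sd < 0)) {
    stop_domain("effect_prior weights must sum to 1 with non-negative sds")
  }
  if (!is.null(ld_blocks)) {
    if (is.null(ld_blocks$block_size) || ld_blocks$block_size < 1 ||
        is.null(ld_blocks$r2) || ld_blocks$r2 < 0 || ld_blocks$r2 > 1) {
      stop_domain("ld_blocks needs block_size >= 1 and r2 in [0, 1]")
    }
  }
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 + 1e-12 ||
      maf_range[1] > maf_range[2]) {
    stop_domain("maf_range must lie within (0, 0.5]")
  }
  if (sample_overlap < 0 || sample_overlap > 1) {
    stop_domain("sample_overlap must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# Standard error of a per-allele effect on a standardized continuous trait
# (or log-OR scale for binary with case fraction phi).
sim_se <- function(maf, n, binary = FALSE, case_frac = 0.5) {
  base <- 1 / sqrt(2 * maf * (1 - maf) * n)
  if (binary) base / sqrt(case_frac * (1 - case_frac)) else base
}

NONPAL_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                    ncol = 2, byrow = TRUE)

#' Generate a synthetic two-sample GWAS summary-statistic pair
#'
#' @param cfg a [sim_config()].
#' @return List with `exposure` and `outcome` (`sumstats` objects), `ld`
#'   (an `ld_ref`, `NULL` without LD blocks), and `truth` (per-variant true
#'   effect decomposition and assignments).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$L
  ids <- sprintf("v%05d", seq_len(L))
  block_size <- if (is.null(cfg$ld_blocks)) 1L else cfg$ld_blocks$block_size
  block <- (seq_len(L) - 1L) %/% block_size + 1L
  lead <- !duplicated(block)
  within <- stats::ave(seq_len(L), block, FUN = seq_along)
  chrom <- rep("1", L)
  # blocks sit outside the default clumping window of one another; members
  # of a block sit a few kb apart
  pos <- (block - 1) * 2e7 + (within - 1) * 5000 + 1
  r_tag <- if (is.null(cfg$ld_blocks)) 1 else sqrt(cfg$ld_blocks$r2)

  # block-level raw effects, keyed by block id so tags share the signal
  n_block <- max(block)
  raw_block <- vapply(seq_len(n_block), function(b) {
    with_seed(variant_seed(cfg$seed + 1L, sprintf("b%05d", b)), {
      k <- sample.int(nrow(cfg$effect_prior), 1,
                      prob = cfg$effect_prior$weight)
      stats::rnorm(1, 0, cfg$effect_prior$sd[k])
    })
  }, numeric(1))

  maf <- numeric(L)
  shared <- uncorr <- reverse <- logical(L)
  theta_z <- zx <- zy <- numeric(L)
  ea <- oa <- character(L)
  swap <- logical(L)
  for (i in seq_len(L)) {
    draws <- with_seed(variant_seed(cfg$seed, ids[i]),
                       list(u = stats::runif(8), z = stats::rnorm(3)))
    u <- draws$u; z <- draws$z
    maf[i] <- cfg$maf_range[1] + u[1] * diff(cfg$maf_range)
    reverse[i] <- u[4] < cfg$reverse_fraction
    shared[i] <- !reverse[i] && u[2] < cfg$q
    uncorr[i] <- !reverse[i] && u[3] < cfg$pi_uncorr
    pal <- u[6] < cfg$palindromic_fraction
    pair <- if (pal) PAL_PAIRS[ceiling(u[5] * nrow(PAL_PAIRS)), ]
    else NONPAL_PAIRS[ceiling(u[5] * nrow(NONPAL_PAIRS)), ]
    ea[i] <- pair[1]; oa[i] <- pair[2]
    swap[i] <- u[8] < cfg$swap_fraction
    theta_z[i] <- z[3]
    zx[i] <- z[1]
    zy[i] <- cfg$sample_overlap * z[1] +
      sqrt(1 - cfg$sample_overlap^2) * z[2]
  }

  beta_x <- raw_block[block] * ifelse(lead, 1, r_tag)
  theta <- ifelse(uncorr, cfg$theta_sd * theta_z, 0)
  beta_y <- cfg$gamma * beta_x + cfg$eta * ifelse(shared, beta_x, 0) + theta
  # reverse variants: primary effect on the outcome, back-propagated
  beta_y[reverse] <- cfg$reverse_sd * theta_z[reverse]
  beta_x[reverse] <- cfg$reverse_coef * beta_y[reverse]

  bin_x <- cfg$exposure_type == "binary"
  bin_y <- cfg$outcome_type == "binary"
  se_x <- sim_se(maf, cfg$n_exp, bin_x, cfg$case_frac_exp)
  se_y <- sim_se(maf, cfg$n_out, bin_y, cfg$case_frac_out)
  b_x <- beta_x + se_x * zx
  b_y <- beta_y + se_y * zy

  mk_table <- function(beta, se, n, binary, case_frac, swap_rows, trait_id,
                       type) {
    ea_t <- ea; oa_t <- oa; eaf <- maf; b <- beta
    if (any(swap_rows)) {
      tmp <- ea_t[swap_rows]
      ea_t[swap_rows] <- oa_t[swap_rows]
      oa_t[swap_rows] <- tmp
      eaf[swap_rows] <- 1 - eaf[swap_rows]
      b[swap_rows] <- -b[swap_rows]
    }
    df <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                     effect_allele = ea_t, other_allele = oa_t,
                     eaf = eaf, beta = b, se = se,
                     pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                                 .Machine$double.xmin),
                     n = n,
                     n_case = if (binary) round(n * case_frac) else NA_real_,
                     n_control = if (binary) round(n * (1 - case_frac))
                     else NA_real_,
                     stringsAsFactors = FALSE)
    suppressMessages(sumstats_table(df, trait_id = trait_id,
                                    trait_type = type))
  }
  exposure <- mk_table(b_x, se_x, cfg$n_exp, bin_x, cfg$case_frac_exp,
                       rep(FALSE, L), "exposure", cfg$exposure_type)
  outcome <- mk_table(b_y, se_y, cfg$n_out, bin_y, cfg$case_frac_out,
                      swap, "outcome", cfg$outcome_type)

  ld <- NULL
  if (!is.null(cfg$ld_blocks) && block_size > 1) {
    pairs <- do.call(rbind, lapply(unique(block), function(b) {
      members <- ids[block == b]
      if (length(members) < 2) return(NULL)
      cmb <- utils::combn(members, 2)
      data.frame(variant_a = cmb[1, ], variant_b = cmb[2, ],
                 r2 = cfg$ld_blocks$r2, stringsAsFactors = FALSE)
    }))
    ld <- ld_reference(pairs,
                       positions = data.frame(variant_id = ids,
                                              chrom = chrom, pos = pos,
                                              stringsAsFactors = FALSE))
  }
  truth <- data.frame(variant_id = ids, block = block, maf = maf,
                      beta_X = beta_x, beta_Y = beta_y,
                      causal_component = cfg$gamma * beta_x,
                      shared_component = cfg$eta * ifelse(shared, beta_x, 0),
                      uncorr_component = theta,
                      shared = shared, uncorr_pleio = uncorr,
                      reverse = reverse, stringsAsFactors = FALSE)
  truth$causal_component[reverse] <- 0
  truth$shared_component[reverse] <- 0
  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' Per-variant binary-trait margins from liability effects
#'
#' Liability-threshold generator: a per-allele effect on the standardized
#' liability scale is converted to the expected log odds ratio by inverting
#' the same case-control-to-liability transformation used by
#' [r2_binary_liability()], so the two are round-trip consistent.
#'
#' @param liability_beta per-allele effect on the liability scale.
#' @param maf minor-allele frequency.
#' @param n total sample size.
#' @param case_frac sample case fraction.
#' @param prevalence population prevalence in (0, 1).
#' @return Data frame with columns `log_or`, `se`.
#' @export
simulate_binary_margins <- function(liability_beta, maf, n, case_frac,
                                    prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_domain("prevalence must be in (0, 1)")
  }
  r2_l <- pmin(liability_beta^2 * 2 * maf * (1 - maf), 0.999)
  k <- prevalence
  p_case <- case_frac
  x <- stats::qnorm(1 - k)
  z <- stats::dnorm(x)
  i_mean <- z / k
  cc <- k * (1 - k) / z^2 * k * (1 - k) / (p_case * (1 - p_case))
  d <- i_mean * (p_case - k) / (1 - k)
  theta <- d * (d - x)
  r2_obs <- r2_l / (cc * (1 - theta * r2_l))
  r2_obs <- pmin(pmax(r2_obs, 0), 0.999)
  vg <- r2_obs * (pi^2 / 3) / (1 - r2_obs)
  log_or <- sign(liability_beta) * sqrt(vg / (2 * maf * (1 - maf)))
  data.frame(log_or = log_or,
             se = sim_se(maf, n, binary = TRUE, case_frac = case_frac))
}

#' Write the deterministic fixture suite
#'
#' Five small scenario directories (null, causal, correlated pleiotropy,
#' reverse causation, LD blocks), each holding the exposure and outcome
#' summary-statistic tables in the default column dialect, the true effect
#' decomposition, and (for the LD scenario) the LD reference files. Running
#' twice produces identical files.
#'
#' @param out_dir output directory (created).
#' @param L variants per scenario (desk scale).
#' @param seed base seed.
#' @return Invisibly, the scenario directories.
#' @export
make_fixture_suite <- function(out_dir, L = 200, seed = 20260930) {
  scenarios <- list(
    null = sim_config(L = L, seed = seed),
    causal = sim_config(L = L, gamma = 0.3, seed = seed + 1),
    correlated_pleiotropy = sim_config(L = L, eta = 0.3, q = 0.3,
                                       seed = seed + 2),
    reverse = sim_config(L = L, gamma = 0.3, reverse_fraction = 0.3,
                         seed = seed + 3),
    ld_blocks = sim_config(L = L, gamma = 0.3,
                           ld_blocks = list(block_size = 10, r2 = 0.8),
                           seed = seed + 4)
  )
  dirs <- character(0)
  for (nm in names(scenarios)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    sim <- simulate_pair(scenarios[[nm]])
    write_tab <- function(df, f) {
      utils::write.table(df, file.path(d, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    dd <- default_dialect()
    rename <- function(tbl) {
      df <- as.data.frame(tbl)
      names(df) <- unlist(dd[names(df)])
      df
    }
    write_tab(rename(sim$exposure), "exposure.tsv")
    write_tab(rename(sim$outcome), "outcome.tsv")
    write_tab(sim$truth, "truth.tsv")
    if (!is.null(sim$ld)) {
      write_tab(sim$ld$pairs, "ld_pairs.tsv")
      write_tab(sim$ld$positions, "ld_pos.tsv")
    }
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}
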