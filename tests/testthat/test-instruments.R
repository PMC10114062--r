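make_clump_df <- function(variant_id, chrom, pos, pval) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos, pval = pval,
             stringsAsFactors = FALSE)
}

# independent transcription of the greedy clumping definition: walk the
# p-ranked candidates, accepting a variant iff every already-accepted
# variant within the window has r2 below the threshold
clump_oracle <- function(df, ld_lookup, r2_max, window_kb, p_max) {
  cand <- df[df$pval < p_max, , drop = FALSE]
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (k in kept) {
      kk <- match(k, df$variant_id)
      if (df$chrom[kk] != cand$chrom[i]) next
      if (abs(df$pos[kk] - cand$pos[i]) > window_kb * 1000) next
      if (ld_lookup(cand$variant_id[i], k) >= r2_max) conflict <- TRUE
    }
    if (!conflict) kept <- c(kept, cand$variant_id[i])
  }
  kept
}

test_that("clumping keeps the best of a correlated pair and spares distant ones", {
  df <- make_clump_df(c("a", "b"), "1", c(1e6, 1.005e6), c(1e-10, 1e-9))
  ld <- ld_reference(data.frame(variant_a = "a", variant_b = "b", r2 = 0.9))
  expect_equal(clump(df, ld), "a")
  df2 <- make_clump_df(c("a", "b"), c("1", "2"), c(1e6, 1e6), c(1e-9, 1e-9))
  expect_setequal(clump(df2, ld), c("a", "b"))
  # nothing significant -> empty
  df3 <- make_clump_df("a", "1", 1e6, 1e-3)
  expect_length(clump(df3, ld), 0)
})

test_that("block-structured candidates reduce to one lead per block", {
  sim <- simulate_pair(sim_config(L = 50, gamma = 0.3,
                                  ld_blocks = list(block_size = 10, r2 = 0.8),
                                  seed = 3))
  kept <- clump(sim$exposure, sim$ld)
  blocks <- sim$truth$block[match(kept, sim$truth$variant_id)]
  expect_false(any(duplicated(blocks)))
  # each kept variant is its block's smallest significant p
  for (b in blocks) {
    members <- sim$exposure[sim$truth$block == b, ]
    best <- members$variant_id[which.min(members$pval)]
    expect_true(best %in% kept)
  }
})

test_that("clumping matches the greedy oracle and ignores row order", {
  for (case in 1:20) {
    set.seed(case)
    n <- sample(20:60, 1)
    df <- make_clump_df(sprintf("v%03d", sample(n)),
                        chrom = sample(c("1", "2"), n, replace = TRUE),
                        pos = sample.int(3e6, n),
                        pval = 10^runif(n, -12, -4))
    pairs <- NULL
    idx <- t(combn(n, 2))
    sel <- runif(nrow(idx)) < 0.2
    if (any(sel)) {
      pairs <- data.frame(variant_a = df$variant_id[idx[sel, 1]],
                          variant_b = df$variant_id[idx[sel, 2]],
                          r2 = runif(sum(sel)))
    }
    ld <- ld_reference(pairs)
    got <- clump(df, ld, r2_max = 0.1, window_kb = 500, p_max = 1e-5)
    want <- clump_oracle(df, function(a, b) ld_r2(ld, a, b),
                         r2_max = 0.1, window_kb = 500, p_max = 1e-5)
    expect_equal(got, want)
    shuffled <- df[sample(nrow(df)), ]
    expect_equal(clump(shuffled, ld, r2_max = 0.1, window_kb = 500,
                       p_max = 1e-5), got)
  }
})

test_that("every clump exclusion is justified by a kept variant or the p gate", {
  set.seed(77)
  n <- 80
  df <- make_clump_df(sprintf("v%03d", 1:n), "1", sample.int(2e6, n),
                      10^runif(n, -12, -4))
  idx <- t(combn(n, 2))
  sel <- runif(nrow(idx)) < 0.1
  ld <- ld_reference(data.frame(variant_a = df$variant_id[idx[sel, 1]],
                                variant_b = df$variant_id[idx[sel, 2]],
                                r2 = runif(sum(sel))))
  kept <- clump(df, ld, r2_max = 0.1, window_kb = 500, p_max = 1e-5)
  for (i in seq_len(n)) {
    v <- df$variant_id[i]
    if (v %in% kept) next
    if (df$pval[i] >= 1e-5) next
    partners <- kept[vapply(kept, function(k) {
      kk <- match(k, df$variant_id)
      df$pval[kk] <= df$pval[i] &&
        abs(df$pos[kk] - df$pos[i]) <= 5e5 &&
        ld_r2(ld, v, k) >= 0.1
    }, logical(1))]
    expect_gt(length(partners), 0)
  }
})

test_that("proxy substitution picks the strongest qualifying partner", {
  outcome <- toy_sumstats(toy_records(3))  # rs1..rs3 present in outcome
  ld <- ld_reference(data.frame(
    variant_a = c("miss", "miss", "miss2"),
    variant_b = c("rs1", "rs2", "rs3"),
    r2 = c(0.85, 0.95, 0.7)))
  got <- substitute_proxies(c("miss", "miss2"), outcome, ld)
  expect_equal(got$original, "miss")
  expect_equal(got$proxy, "rs2")       # 0.95 beats 0.85
  expect_equal(nrow(substitute_proxies(character(0), outcome, ld)), 0)
})

test_that("variance explained for continuous traits follows the t conversion", {
  expect_equal(r2_continuous(0, 0.1, 100), 0)
  expect_equal(r2_continuous(1, 0.1, 10002), 100 / 10100)
  r2a <- r2_continuous(0.5, 0.05, 1000)
  r2b <- r2_continuous(0.5, 0.05, 10000)
  expect_gt(r2a, r2b)  # fixed t, larger n explains less variance
  expect_error(r2_continuous(1, 0.1, 2), "exceed 2")
})

# independent transcription of the liability conversion, kept deliberately
# step-by-step and separate from the package implementation
lee_liability_oracle <- function(lor, eaf, ncase, ncontrol, prev) {
  vg <- lor^2 * 2 * eaf * (1 - eaf)
  r2o <- vg / (vg + pi^2 / 3)
  P <- ncase / (ncase + ncontrol)
  K <- prev
  thr <- qnorm(1 - K)
  z <- dnorm(thr)
  i <- z / K
  C <- (K * (1 - K))^2 / (z^2 * P * (1 - P))
  d <- i * (P - K) / (1 - K)
  theta <- d * (d - thr)
  C * r2o / (1 + C * theta * r2o)
}

test_that("liability-scale variance explained matches an independent derivation", {
  expect_equal(r2_binary_liability(0, 0.3, 5000, 5000, 0.1), 0)
  # symmetry in the sign of the log odds ratio
  expect_equal(r2_binary_liability(0.2, 0.3, 5000, 5000, 0.1),
               r2_binary_liability(-0.2, 0.3, 5000, 5000, 0.1))
  grid <- expand.grid(lor = c(0.05, 0.2, 0.5), eaf = c(0.1, 0.45),
                      prev = c(0.01, 0.2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(r2_binary_liability(g$lor, g$eaf, 20000, 30000, g$prev),
                 lee_liability_oracle(g$lor, g$eaf, 20000, 30000, g$prev),
                 tolerance = 1e-12)
  }
  expect_error(r2_binary_liability(0.2, 0, 100, 100, 0.1), "eaf")
  expect_error(r2_binary_liability(0.2, 0.3, 100, 100, 1), "prevalence")
  expect_message(r2_binary_liability(0.2, 0.3, 100, 100), "case proportion")
})

test_that("r2 measures always land in [0, 1)", {
  set.seed(11)
  for (i in 1:50) {
    r2c <- r2_continuous(rnorm(1, 0, 0.5), runif(1, 0.001, 0.1),
                         sample(10:1e6, 1))
    expect_gte(r2c, 0); expect_lt(r2c, 1)
    r2b <- r2_binary_liability(rnorm(1, 0, 1), runif(1, 0.01, 0.99),
                               5000, 5000, runif(1, 0.01, 0.5))
    expect_gte(r2b, 0); expect_lt(r2b, 1)
  }
})

make_iset <- function(r2_exp, r2_out) {
  n <- length(r2_exp)
  structure(data.frame(
    variant_id = paste0("v", seq_len(n)),
    b_X = 0.05, se_X = 0.005, p_X = 1e-10, b_Y = 0.01, se_Y = 0.005,
    p_Y = 0.5, r2_exposure = r2_exp, r2_outcome = r2_out,
    proxy_of = NA_character_, stringsAsFactors = FALSE),
    n_exposure = 1e5, n_outcome = 1e5,
    class = c("instrument_set", "data.frame"))
}

test_that("Steiger filtering keeps forward-explaining instruments and is idempotent", {
  iset <- make_iset(c(0.010, 0.001, 0.005), c(0.001, 0.010, 0.005))
  filt <- steiger_filter(iset)
  expect_equal(filt$variant_id, "v1")   # strict inequality drops the tie
  expect_equal(attr(filt, "n_steiger_removed"), 2)
  again <- steiger_filter(filt)
  expect_equal(again$variant_id, filt$variant_id)
  expect_equal(attr(again, "n_steiger_removed"), 0)
  expect_true(all(filt$r2_exposure - filt$r2_outcome > 0))
  empty <- steiger_filter(make_iset(0.001, 0.01))
  expect_equal(nrow(empty), 0)
})

test_that("Steiger filtering removes planted reverse-causation instruments", {
  sim <- simulate_pair(sim_config(L = 150, gamma = 0.3,
                                  reverse_fraction = 0.3, seed = 8))
  pair <- harmonize(sim$exposure, sim$outcome)
  kept <- suppressWarnings(clump(sim$exposure))
  iset <- instrument_set(pair, keep = kept,
                         n_exposure = 1e5, n_outcome = 1e5)
  filt <- steiger_filter(iset)
  rev_ids <- sim$truth$variant_id[sim$truth$reverse]
  planted <- sum(iset$variant_id %in% rev_ids)
  surviving <- sum(filt$variant_id %in% rev_ids)
  expect_gt(planted, 10)
  expect_gte((planted - surviving) / planted, 0.9)
})

test_that("F statistics match their closed forms", {
  one <- make_iset(0.01, 0.001)[1, ]
  one$b_X <- 0.05; one$se_X <- 0.005  # z = 10
  attr(one, "n_exposure") <- 1e5
  fs <- f_statistics(one)
  expect_equal(fs$per_snp, 100)
  expect_equal(fs$mean_F, 100)
  expect_equal(fs$aggregate_F,
               ((1e5 - 1 - 1) / 1) * 0.01 / (1 - 0.01))
  zero <- make_iset(c(0.001, 0.001), c(0.001, 0.001))
  zero$b_X <- 0
  expect_equal(f_statistics(zero)$mean_F, 0)
  expect_error(f_statistics(make_iset(0.001, 0.01)[0, ]), "empty")
})

test_that("mean F tracks the noncentral chi-square expectation", {
  # 10 instruments with true per-SNP z of 8: E[F] = ncp + 1 = 65
  set.seed(21)
  mean_f <- replicate(500, {
    iset <- make_iset(rep(0.001, 10), rep(0.0001, 10))
    iset$b_X <- 0.04 + rnorm(10, 0, 0.005)
    iset$se_X <- 0.005
    f_statistics(iset)$mean_F
  })
  expect_equal(mean(mean_f), 65, tolerance = 0.02)
})
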