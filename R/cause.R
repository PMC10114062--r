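#' Select variants for the sharing-versus-causal model comparison
#'
#' Greedy clumping with the looser inclusion rules used for the Bayesian
#' model comparison: independent variants (`r2 < 0.01` or farther apart than
#' 250 kb) associated with the exposure at `p < 1e-3`.
#'
#' @param pair a `harmonized_pair`.
#' @param ld an `ld_ref` or `NULL` (distance-only clumping, with warning).
#' @param r2_max,window_kb,p_max selection parameters.
#' @return An object of class `cause_variant_set`: data frame with columns
#'   `variant_id`, `b_X`, `se_X`, `b_Y`, `se_Y`; selection parameters are
#'   echoed as attributes. Zero rows when nothing qualifies.
#' @export
select_cause_variants <- function(pair, ld = NULL, r2_max = 0.01,
                                  window_kb = 250, p_max = 1e-3) {
  rows <- harmonized_rows(pair)
  keep <- clump(rows, ld = ld, r2_max = r2_max, window_kb = window_kb,
                p_max = p_max)
  rows <- rows[rows$variant_id %in% keep, , drop = FALSE]
  out <- data.frame(variant_id = rows$variant_id,
                    b_X = rows$b_X, se_X = rows$se_X,
                    b_Y = rows$b_Y, se_Y = rows$se_Y,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(pair, "exposure_id"),
            outcome_id = attr(pair, "outcome_id"),
            selection = list(r2_max = r2_max, window_kb = window_kb,
                             p_max = p_max),
            class = c("cause_variant_set", "data.frame"))
}

#' Empirical mixture prior over true exposure effects
#'
#' Fits a K-component zero-mean normal mixture to the observed exposure
#' effects by EM, deconvolving the known per-variant sampling error: the
#' observed `b_j` is modelled as `N(0, tau_k^2 + se_j^2)` under component
#' `k`. For `K >= 2` the first component is pinned at `tau = 0` (a point
#' mass for null variants); the remaining scales and all weights are free.
#' The observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param b observed effect estimates.
#' @param se their standard errors.
#' @param K number of components (default 5).
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `effect_prior`: data frame with columns
#'   `weight`, `sd`, plus attributes `loglik` (trace) and `converged`.
#' @export
fit_effect_prior <- function(b, se, K = 5, max_iter = 500, tol = 1e-6) {
  stopifnot(length(b) == length(se), all(se > 0), K >= 1)
  n <- length(b)
  s2 <- se^2
  # moment-based spread of the true effects seeds the component scales
  sd0 <- sqrt(max(mean(b^2) - mean(s2), (0.1 * stats::sd(b))^2, 1e-12))
  tau <- if (K == 1) sd0 else c(0, sd0 * 2^seq(-ceiling((K - 1) / 2),
                                               length.out = K - 1))
  wgt <- rep(1 / K, K)
  fixed_zero <- K >= 2
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: responsibilities under marginal N(0, tau_k^2 + se_j^2)
    logd <- vapply(seq_len(K), function(k) {
      stats::dnorm(b, 0, sqrt(tau[k]^2 + s2), log = TRUE) + log(wgt[k])
    }, numeric(n))
    if (n == 1) logd <- matrix(logd, nrow = 1)
    mx <- apply(logd, 1, max)
    ll <- sum(mx + log(rowSums(exp(logd - mx))))
    loglik <- c(loglik, ll)
    if (iter > 1 && abs(ll - loglik[iter - 1]) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    r <- exp(logd - mx)
    r <- r / rowSums(r)
    # M-step: weights; component scales via posterior second moments of the
    # latent true effect
    wgt <- pmax(colSums(r), 1e-12)
    wgt <- wgt / sum(wgt)
    for (k in seq_len(K)) {
      if (fixed_zero && k == 1) next
      shrink <- tau[k]^2 / (tau[k]^2 + s2)
      e_beta2 <- (shrink * b)^2 + shrink * s2
      tau[k] <- sqrt(max(sum(r[, k] * e_beta2) / sum(r[, k]), 0))
    }
  }
  if (!converged) {
    warning("effect-prior EM did not converge; returning best iterate",
            call. = FALSE)
  }
  ord <- order(tau)
  structure(data.frame(weight = wgt[ord], sd = tau[ord]),
            loglik = loglik, converged = converged,
            class = c("effect_prior", "data.frame"))
}

# log marginal density of each (b_X, b_Y) pair at outcome slope m,
# integrating the true exposure effect over the mixture prior:
# returns an L x length(m) matrix.
cause_logf <- function(dat, prior, m) {
  L <- nrow(dat)
  M <- length(m)
  acc <- NULL
  for (k in seq_len(nrow(prior))) {
    tau2 <- prior$sd[k]^2
    vx <- tau2 + dat$se_X^2
    lx <- stats::dnorm(dat$b_X, 0, sqrt(vx), log = TRUE)
    mu <- dat$b_X * tau2 / vx          # posterior mean of true effect
    v <- tau2 * dat$se_X^2 / vx        # posterior variance
    mean_y <- outer(mu, m)                       # L x M
    sd_y <- sqrt(outer(v, m^2) + dat$se_Y^2)     # L x M
    term <- log(prior$weight[k]) + lx +
      stats::dnorm(matrix(dat$b_Y, L, M), mean_y, sd_y, log = TRUE)
    acc <- if (is.null(acc)) term else {
      mx <- pmax(acc, term)
      mx + log(exp(acc - mx) + exp(term - mx))
    }
  }
  acc
}

# Quantiles of a discrete grid marginal by linear interpolation of the CDF.
grid_quantile <- function(values, probs, q) {
  ord <- order(values)
  v <- values[ord]
  p <- probs[ord]
  cdf <- cumsum(p)
  if (length(v) == 1) return(rep(v, length(q)))
  stats::approx(c(0, cdf), c(v[1], v), xout = q, ties = "ordered",
                rule = 2)$y
}

# Posterior over (gamma, eta, q) on a product grid. gamma may be the single
# value 0 (sharing model). Returns grid data frame with posterior mass,
# per-variant lppd, and the marginal summaries.
cause_grid_posterior <- function(dat, prior, gamma, eta, q,
                                 gamma_sd, eta_sd, q_a, q_b) {
  L <- nrow(dat)
  ng <- length(gamma); nh <- length(eta); nq <- length(q)
  F0 <- cause_logf(dat, prior, gamma)                     # L x ng
  m1 <- as.vector(outer(gamma, eta, "+"))                 # gamma fastest
  F1 <- cause_logf(dat, prior, m1)                        # L x (ng*nh)
  F0rep <- F0[, rep(seq_len(ng), nh), drop = FALSE]
  npair <- ng * nh
  # log(q e^F1 + (1-q) e^F0) = F0 + log1p(q (e^(F1-F0) - 1)), with the
  # large-difference branch handled explicitly for stability
  D <- F1 - F0rep
  big <- D > 30
  E <- expm1(pmin(D, 30))
  base <- colSums(F0rep)
  loglik <- matrix(NA_real_, npair, nq)
  for (iq in seq_len(nq)) {
    M <- log1p(q[iq] * E)
    if (any(big)) M[big] <- log(q[iq]) + D[big]
    loglik[, iq] <- base + colSums(M)
  }
  lp_gamma <- if (ng > 1) stats::dnorm(gamma, 0, gamma_sd, log = TRUE)
  else 0
  lp <- loglik +
    rep(lp_gamma, nh) +
    rep(stats::dnorm(eta, 0, eta_sd, log = TRUE), each = ng) +
    matrix(stats::dbeta(q, q_a, q_b, log = TRUE), npair, nq, byrow = TRUE)
  mx <- max(lp)
  post <- exp(lp - mx)
  post <- post / sum(post)

  # per-variant log pointwise predictive density under the grid posterior
  shift <- apply(cbind(F1, F0), 1, max)
  wA <- rowSums(sweep(post, 2, q, "*"))          # mass on the shared branch
  wB_pair <- rowSums(sweep(post, 2, 1 - q, "*")) # mass on the direct branch
  wB <- tapply(wB_pair, rep(seq_len(ng), nh), sum)
  lppd <- shift + log(exp(F1 - shift) %*% wA +
                        exp(F0 - shift) %*% as.vector(wB))

  grid <- data.frame(gamma = rep(rep(gamma, nh), nq),
                     eta = rep(rep(eta, each = ng), nq),
                     q = rep(q, each = npair),
                     post = as.vector(post))
  list(grid = grid, lppd = as.vector(lppd), loglik_max = max(loglik))
}

marginal_summary <- function(grid, par) {
  mass <- tapply(grid$post, grid[[par]], sum)
  vals <- as.numeric(names(mass))
  qs <- grid_quantile(vals, as.vector(mass), c(0.025, 0.5, 0.975))
  list(values = vals, mass = as.vector(mass),
       median = qs[2], ci_low = qs[1], ci_high = qs[3])
}

boundary_mass <- function(summary) {
  n <- length(summary$values)
  if (n < 3) return(0)
  summary$mass[1] + summary$mass[n]
}

#' Fit the sharing and causal models on a variant set
#'
#' Both models describe each variant's pair of observed effects with a
#' mixture over a shared-factor branch (probability `q`, outcome slope
#' `gamma + eta`) and a direct branch (slope `gamma`), marginalised over the
#' empirical effect prior and the known sampling errors. The sharing model
#' pins the causal effect `gamma` at zero; the causal model leaves it free.
#' Posteriors are computed on an adaptive product grid (coarse pass over the
#' prior range, one automatic range expansion if more than 1\% of mass sits
#' on the boundary, then a refinement pass over the region holding the
#' central mass).
#'
#' @param set a `cause_variant_set` (or data frame with columns `b_X`,
#'   `se_X`, `b_Y`, `se_Y`).
#' @param prior an `effect_prior`; fitted from the set when `NULL`.
#' @param gamma_sd,eta_sd normal prior scales for the causal and shared-
#'   factor effects (default 0.6).
#' @param q_a,q_b Beta prior on the shared-variant proportion (default
#'   Beta(1, 10)).
#' @param n_gamma,n_eta,n_q grid sizes per dimension.
#' @return List with elements `sharing` and `causal`, each of class
#'   `cause_model_fit`: posterior grid, marginal summaries (`gamma`, `eta`,
#'   `q`), and the per-variant log pointwise predictive densities (`lppd`).
#' @export
fit_cause_models <- function(set, prior = NULL, gamma_sd = 0.6, eta_sd = 0.6,
                             q_a = 1, q_b = 10, n_gamma = 41, n_eta = 31,
                             n_q = 25) {
  dat <- as.data.frame(set)
  stopifnot(all(c("b_X", "se_X", "b_Y", "se_Y") %in% names(dat)))
  if (!nrow(dat)) stop_domain("empty variant set")
  prior <- prior %||% fit_effect_prior(dat$b_X, dat$se_X)
  q <- (seq_len(n_q) - 0.5) / n_q

  fit_one <- function(model) {
    free_gamma <- model == "causal"
    g_range <- c(-3, 3) * gamma_sd
    e_range <- c(-3, 3) * eta_sd
    expand_used <- FALSE
    refined <- FALSE
    for (pass in 1:4) {
      gamma <- if (free_gamma) {
        seq(g_range[1], g_range[2], length.out = n_gamma)
      } else 0
      eta <- seq(e_range[1], e_range[2], length.out = n_eta)
      res <- cause_grid_posterior(dat, prior, gamma, eta, q,
                                  gamma_sd, eta_sd, q_a, q_b)
      sg <- marginal_summary(res$grid, "gamma")
      se_ <- marginal_summary(res$grid, "eta")
      # the escape check guards the coarse, prior-spanning grid; refined
      # grids trim diffuse tails by design
      over <- !refined && ((free_gamma && boundary_mass(sg) > 0.01) ||
                             boundary_mass(se_) > 0.01)
      if (over) {
        if (expand_used) {
          stop_domain("posterior mass persists on the grid boundary after ",
                      "one automatic range expansion")
        }
        g_range <- g_range * 2
        e_range <- e_range * 2
        expand_used <- TRUE
        next
      }
      if (refined) break
      # refine: restrict each free dimension to its central mass, one grid
      # step of slack on either side
      refine <- function(s, range0) {
        keep <- s$values[cumsum(s$mass) > 1e-5 &
                           rev(cumsum(rev(s$mass))) > 1e-5]
        if (!length(keep)) keep <- s$values[which.max(s$mass)]
        step <- diff(range0) / (length(s$values) - 1)
        c(min(keep) - step, max(keep) + step)
      }
      if (free_gamma) g_range <- refine(sg, g_range)
      e_range <- refine(se_, e_range)
      refined <- TRUE
    }
    structure(list(model = model, grid = res$grid,
                   gamma = sg, eta = se_, q = marginal_summary(res$grid, "q"),
                   lppd = stats::setNames(res$lppd, dat$variant_id),
                   loglik_max = res$loglik_max,
                   prior = prior,
                   params = list(gamma_sd = gamma_sd, eta_sd = eta_sd,
                                 q_a = q_a, q_b = q_b)),
              class = "cause_model_fit")
  }
  list(sharing = fit_one("sharing"), causal = fit_one("causal"))
}

#' @export
print.cause_model_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%d variants)\n", x$model, length(x$lppd)))
  for (p in c("gamma", "eta", "q")) {
    s <- x[[p]]
    cat(sprintf("  %-5s median %.4g, 95%% CrI (%.4g, %.4g)\n",
                p, s$median, s$ci_low, s$ci_high))
  }
  invisible(x)
}

#' Compare sharing and causal fits by expected log pointwise density
#'
#' `delta_elpd = sum_j (lppd_sharing_j - lppd_causal_j)`: negative values
#' favour the causal model (the reporting convention of the source method).
#' The standard error is `sqrt(L)` times the standard deviation of the
#' per-variant differences, and the one-sided p-value
#' `pnorm(delta / se)` is the probability of seeing this much support for
#' the causal model under no real difference.
#'
#' @param sharing,causal `cause_model_fit` objects on the identical variant
#'   set.
#' @return List of class `elpd_comparison`: `delta_elpd`, `se_delta`, `z`,
#'   `p_one_sided`, `L`, and `convention` (a human-readable note).
#' @export
elpd_compare <- function(sharing, causal) {
  if (length(sharing$lppd) != length(causal$lppd) ||
      !identical(names(sharing$lppd), names(causal$lppd))) {
    stop_domain("sharing and causal fits must be on the identical variant set")
  }
  d <- sharing$lppd - causal$lppd
  L <- length(d)
  delta <- sum(d)
  se <- sqrt(L) * stats::sd(d)
  z <- if (se > 0) delta / se else 0
  structure(list(delta_elpd = delta, se_delta = se, z = z,
                 p_one_sided = stats::pnorm(z), L = L,
                 convention = "delta_elpd = elpd(sharing) - elpd(causal); negative favours the causal model"),
            class = "elpd_comparison")
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat(sprintf("delta ELPD %.4g (SE %.4g), z = %.3g, one-sided p = %.3g\n",
              x$delta_elpd, x$se_delta, x$z, x$p_one_sided))
  cat(" ", x$convention, "\n")
  invisible(x)
}

#' Sharing-versus-causal Bayesian screen for one harmonized pair
#'
#' High-level fitting function: selects independent exposure-associated
#' variants, fits the empirical effect prior, fits the sharing and causal
#' models, and scores them by the expected log pointwise posterior density
#' difference.
#'
#' @param pair a `harmonized_pair` (or a prepared `cause_variant_set`).
#' @param ld an `ld_ref` for the selection step.
#' @param r2_max,window_kb,p_max selection parameters, see
#'   [select_cause_variants()].
#' @param K effect-prior mixture components.
#' @param ... passed to [fit_cause_models()].
#' @return An object of class `cause_lite`: list with `variants`, `prior`,
#'   `sharing`, `causal`, `comparison`. `NULL` fields and an error when no
#'   variant qualifies.
#' @export
cause_lite <- function(pair, ld = NULL, r2_max = 0.01, window_kb = 250,
                       p_max = 1e-3, K = 5, ...) {
  set <- if (inherits(pair, "cause_variant_set")) pair else {
    select_cause_variants(pair, ld = ld, r2_max = r2_max,
                          window_kb = window_kb, p_max = p_max)
  }
  if (!nrow(set)) stop_domain("no variant qualifies for the model comparison")
  prior <- fit_effect_prior(set$b_X, set$se_X, K = K)
  fits <- fit_cause_models(set, prior = prior, ...)
  structure(list(variants = set, prior = prior,
                 sharing = fits$sharing, causal = fits$causal,
                 comparison = elpd_compare(fits$sharing, fits$causal)),
            class = "cause_lite")
}

#' @export
print.cause_lite <- function(x, ...) {
  cat(sprintf("Sharing-vs-causal comparison (%d variants)\n",
              nrow(x$variants)))
  print(x$causal)
  print(x$comparison)
  invisible(x)
}

#' @export
coef.cause_lite <- function(object, ...) {
  c(gamma = object$causal$gamma$median,
    eta = object$causal$eta$median,
    q = object$causal$q$median)
}

#' @export
confint.cause_lite <- function(object, parm = "gamma", level = 0.95, ...) {
  s <- object$causal[[parm]]
  matrix(c(s$ci_low, s$ci_high), 1,
         dimnames = list(parm, c("2.5 %", "97.5 %")))
}

#' @export
summary.cause_lite <- function(object, ...) {
  data.frame(
    model = c("sharing", "causal"),
    gamma_median = c(0, object$causal$gamma$median),
    eta_median = c(object$sharing$eta$median, object$causal$eta$median),
    q_median = c(object$sharing$q$median, object$causal$q$median),
    delta_elpd = c(NA, object$comparison$delta_elpd),
    se_delta = c(NA, object$comparison$se_delta),
    p_one_sided = c(NA, object$comparison$p_one_sided)
  )
}
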