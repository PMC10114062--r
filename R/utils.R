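#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded helpers never disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic 31-adic string hash into [0, 2^31 - 60). Used to key
# per-variant RNG streams by variant id so simulation output is invariant to
# row order.
hash_id <- function(x) {
  mod <- 2147483587
  vapply(as.character(x), function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% mod
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Seed for a (base seed, variant id) pair, always a valid positive integer.
# The combination is scrambled nonlinearly (Lehmer steps; exact in double
# arithmetic below 2^53) so streams for related keys are decorrelated.
variant_seed <- function(seed, id) {
  m <- 2147483647
  v <- (hash_id(id) * 69621 + (as.numeric(seed) %% m) * 40014 + 12345) %% m
  v <- (v * 48271) %% m
  v <- (v * 48271) %% m
  as.integer(v %% 2147483587 + 1)
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# Two-sided normal p-value for z = est/se; never exactly zero.
z_pvalue <- function(est, se) {
  p <- 2 * stats::pnorm(-abs(est / se))
  pmax(p, .Machine$double.xmin)
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x == as.integer(x)
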