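# Internal helpers: argument checking, seed streams, shared exact tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stopf("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         open_min = FALSE, open_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  lo_ok <- if (open_min) x > min else x >= min
  hi_ok <- if (open_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside its allowed range", name, x)
  as.numeric(x)
}

#' Derive a per-stage random seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' (simulation, permutation, read sampling, ...) draws from its own stream
#' derived deterministically from the master seed and a stage label, so
#' that adding permutations to one stage cannot perturb another.
#'
#' @param seed master seed (integer).
#' @param stage character stage label.
#' @return an integer seed in [0, 2^31 - 1].
#' @export
derive_seed <- function(seed, stage) {
  seed <- check_count(seed, "seed")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 9973 + 1) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Wilcoxon rank-sum with exact enumeration for small samples (handles
## ties exactly, unlike stats::wilcox.test), normal approximation with
## tie correction otherwise.  One-sided: alternative "less" tests whether
## x is stochastically smaller than y.
rank_sum_test <- function(x, y, alternative = c("less", "greater", "two.sided"),
                          exact_max_comb = 2e5) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(list(statistic = NA_real_, p_value = 1))
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  n <- nx + ny
  if (choose(n, nx) <= exact_max_comb) {
    combs <- utils::combn(n, nx)
    ws <- colSums(matrix(r[combs], nrow = nx))
    p_less <- mean(ws <= w_obs)
    p_greater <- mean(ws >= w_obs)
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sig <- sqrt(sig2)
    # continuity-corrected normal tail
    p_less <- stats::pnorm((w_obs - mu + 0.5) / sig)
    p_greater <- stats::pnorm((w_obs - mu - 0.5) / sig, lower.tail = FALSE)
  }
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two.sided = min(1, 2 * min(p_less, p_greater)))
  list(statistic = w_obs, p_value = min(1, p))
}

## Two-sided Fisher's exact test on a 2x2 table, probability-sum
## convention, plus the sample (cross-product) odds ratio.  `fisher.test`
## reports the conditional MLE odds ratio, which is not what the carrier
## tables use, so the OR is computed directly.
fisher_2x2 <- function(a, b, c, d, or_correction = TRUE) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != floor(tab)))
    stopf("2x2 table cells must be non-negative integers")
  p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
  zero_cell <- any(tab == 0)
  or <- if (zero_cell && or_correction) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else if (zero_cell) {
    NA_real_
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_value = p, corrected = zero_cell)
}
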