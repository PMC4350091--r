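# Independent oracles and small fixtures shared across the suite.
# Every oracle is a direct enumeration or closed form, deliberately
# written without reusing the package's own code paths.

## two-sided Fisher p by hypergeometric enumeration (probability-sum
## convention): sum P(tables at most as probable as the observed one)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
    numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## upper-tail hypergeometric P(X >= k) by direct combinatorial sum
oracle_hyper_ge <- function(N, K, n, k) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

## genotype log-likelihood triple by explicit per-read products
oracle_gl <- function(n_ref, n_alt, q) {
  e <- 10^(-q / 10)
  c(n_ref * log(1 - e) + n_alt * log(e),
    (n_ref + n_alt) * log(0.5),
    n_ref * log(e) + n_alt * log(1 - e))
}

## grid-search maximizer of the HWE marginal log-likelihood
oracle_grid_af <- function(gl, step = 1e-5) {
  ps <- seq(0, 1, by = step)
  lik <- exp(gl - apply(gl, 1, max))
  ll <- vapply(ps, function(p) {
    prior <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum(log(lik %*% prior))
  }, numeric(1))
  ps[which.max(ll)]
}

## exact permutation p over all case-label assignments:
## P(stat(perm) >= stat(observed)) under exchangeability
oracle_perm_exact <- function(stat_fn, X, case) {
  n <- length(case); k <- sum(case)
  obs <- stat_fn(X, case)
  sets <- utils::combn(n, k)
  stats <- apply(sets, 2, function(ix) {
    cs <- rep(FALSE, n); cs[ix] <- TRUE
    stat_fn(X, cs)
  })
  mean(stats >= obs - 1e-9)
}

## random genotype-likelihood set with some informative samples
random_gl_set <- function(n, seed) {
  set.seed(seed)
  depth <- rpois(n, 12)
  q <- runif(1, 0.01, 0.4)
  gl <- t(vapply(depth, function(d) {
    if (d == 0) return(c(0, 0, 0))
    g <- sample(0:2, 1, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    alt <- rbinom(1, d, c(0.01, 0.5, 0.99)[g + 1])
    oracle_gl(d - alt, alt, 20)
  }, numeric(3)))
  structure(list(gl = gl, depth = depth), class = "gl_set")
}

## hand-sized genotype fixture: 4 variants x 8 samples, 4 cases first
toy_gm <- function() {
  dosage <- rbind(
    c(1L, 0L, 2L, 0L, 0L, 1L, 0L, 0L),   # shared rare variant
    c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),   # case-unique
    c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L),   # shared
    c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L))   # control-unique
  variants <- data.frame(
    id = paste0("v", 1:4), chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "G", gene = c("GENE1", "GENE1", "GENE1", "GENE1"),
    class = "non-silent",
    maf = c(0.004, 0.001, 0.002, 0.001), stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, paste0("S", 1:8))
}

toy_cohort <- function(n_case = 4, n_ctrl = 4) {
  cohort(paste0("S", seq_len(n_case + n_ctrl)),
         rep(c("case", "control"), c(n_case, n_ctrl)),
         age = 30 + seq_len(n_case + n_ctrl))
}

## single read-summary row builder
read_row <- function(variant, sample, ref_fwd = 0, ref_rev = 0,
                     alt_fwd = 0, alt_rev = 0, qual = 20, mapq = 45) {
  data.table::data.table(variant = variant, sample = sample,
                         ref_fwd = ref_fwd, ref_rev = ref_rev,
                         alt_fwd = alt_fwd, alt_rev = alt_rev,
                         qual = qual, mapq = mapq)
}
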