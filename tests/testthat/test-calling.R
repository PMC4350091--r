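test_that("gl_triple matches the per-read product oracle", {
  expect_equal(gl_triple(0, 0), c(0, 0, 0))
  expect_equal(gl_triple(10, 0, 20, 20), oracle_gl(10, 0, 20))
  expect_equal(gl_triple(3, 7, 25, 25), oracle_gl(3, 7, 25))
  # symmetry: equal counts and qualities swap hom-ref and hom-alt
  g <- gl_triple(5, 5, 20, 20)
  expect_equal(g[1], g[3])
})

test_that("EM allele frequency estimation matches closed forms", {
  # all samples certainly hom-ref
  gl <- matrix(rep(c(0, -50, -100), 10), ncol = 3, byrow = TRUE)
  gls <- structure(list(gl = gl, depth = rep(20L, 10)), class = "gl_set")
  expect_lt(estimate_af_em(gls)$p_hat, 1e-6)

  # delta likelihoods: p_hat = minor-allele count / (2 x samples)
  counts <- c(0L, 1L, 2L, 0L, 1L)
  gl <- t(vapply(counts, function(g) {
    v <- rep(-1e4, 3); v[g + 1] <- 0; v
  }, numeric(3)))
  gls <- structure(list(gl = gl, depth = rep(20L, 5)), class = "gl_set")
  expect_equal(estimate_af_em(gls)$p_hat, sum(counts) / 10, tolerance = 1e-9)

  # no informative samples: p_hat = 0, converged
  flat <- structure(list(gl = matrix(0, 3, 3), depth = rep(0L, 3)),
                    class = "gl_set")
  est <- estimate_af_em(flat)
  expect_identical(est$p_hat, 0)
  expect_true(est$converged)
})

test_that("EM matches the grid-search ML oracle on random sites", {
  for (s in 1:50) {
    gls <- random_gl_set(n = 25, seed = 1000 + s)
    est <- estimate_af_em(gls)
    grid <- oracle_grid_af(gls$gl[gls$depth > 0, , drop = FALSE])
    expect_lt(abs(est$p_hat - grid), 1e-4)
    # the fitted frequency never beats the null by less than 0
    expect_gte(est$loglik, est$loglik0 - 1e-8)
  }
})

test_that("EM marginal log-likelihood is non-decreasing over iterations", {
  af_ll <- rvburden:::af_loglik
  for (s in 1:5) {
    gls <- random_gl_set(n = 30, seed = 2000 + s)
    gl <- gls$gl[gls$depth > 0, , drop = FALSE]
    lls <- vapply(1:12, function(k)
      af_ll(gl, estimate_af_em(gls, max_iter = k)$p_hat), numeric(1))
    expect_true(all(diff(lls) > -1e-8))
  }
})

test_that("lrt_call applies a strict threshold of 24", {
  gls <- random_gl_set(25, seed = 77)
  af <- estimate_af_em(gls)
  lrt <- lrt_call(gls, af)
  # independent evaluation of the two log-likelihoods
  gl <- gls$gl[gls$depth > 0, , drop = FALSE]
  stat_oracle <- 2 * (rvburden:::af_loglik(gl, af$p_hat) -
                        rvburden:::af_loglik(gl, 0))
  expect_equal(lrt$statistic, max(0, stat_oracle), tolerance = 1e-8)

  # boundary: a statistic of exactly 24 is NOT called
  af24 <- structure(list(p_hat = 0.1, loglik = 12, loglik0 = 0,
                         iterations = 1L, converged = TRUE),
                    class = "af_estimate")
  expect_false(lrt_call(gls, af24)$called)
  expect_true(lrt_call(gls, structure(
    list(p_hat = 0.1, loglik = 12.1, loglik0 = 0, iterations = 1L,
         converged = TRUE), class = "af_estimate"))$called)

  # p_hat = 0: statistic 0, not called
  af0 <- structure(list(p_hat = 0, loglik = -10, loglik0 = -10,
                        iterations = 1L, converged = TRUE),
                   class = "af_estimate")
  expect_equal(lrt_call(gls, af0)$statistic, 0)
  expect_false(lrt_call(gls, af0)$called)
})

test_that("call_genotypes is Bayes rule plus the 8x mask", {
  # flat likelihoods: the HWE prior decides (p = 0.1 -> hom-ref)
  flat <- structure(list(gl = matrix(0, 2, 3), depth = c(20L, 20L)),
                    class = "gl_set")
  af <- structure(list(p_hat = 0.1, loglik = 0, loglik0 = 0,
                       iterations = 1L, converged = TRUE),
                  class = "af_estimate")
  expect_equal(unname(call_genotypes(flat, af)$genotype), c(0L, 0L))

  # posteriors equal direct Bayes arithmetic on random cases
  set.seed(42)
  for (k in 1:20) {
    gls <- random_gl_set(8, seed = 3000 + k)
    p <- runif(1, 0.01, 0.5)
    af <- structure(list(p_hat = p, loglik = 0, loglik0 = 0,
                         iterations = 1L, converged = TRUE),
                    class = "af_estimate")
    cg <- call_genotypes(gls, af, min_depth = 0)
    prior <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    for (i in seq_len(8)) {
      post <- exp(gls$gl[i, ]) * prior
      post <- post / sum(post)
      expect_equal(unname(cg$posterior[i]), max(post), tolerance = 1e-10)
      expect_equal(unname(cg$genotype[i]), which.max(post) - 1L)
    }
  }

  # depth 7 is missing regardless of likelihoods
  gl <- rbind(oracle_gl(0, 7, 30), oracle_gl(0, 8, 30))
  gls <- structure(list(gl = gl, depth = c(7L, 8L)), class = "gl_set")
  cg <- call_genotypes(gls, af, min_depth = 8)
  expect_true(is.na(cg$genotype[1]))
  expect_equal(unname(cg$genotype[2]), 2L)
})

test_that("base-quality rank-sum filter matches exact enumeration", {
  # identical quality multisets: no shift, keep
  sr <- rbind(read_row("v", "s1", ref_fwd = 3, alt_fwd = 3, qual = 20),
              read_row("v", "s2", ref_fwd = 3, alt_rev = 3, qual = 20))
  f <- filter_base_quality(sr)
  expect_gte(f$p_value, 0.5)
  expect_true(f$keep)

  # small pools: p equals exhaustive rank-permutation enumeration
  sr <- rbind(read_row("v", "s1", ref_fwd = 4, qual = 31),
              read_row("v", "s2", ref_fwd = 2, qual = 28),
              read_row("v", "s3", alt_fwd = 2, qual = 12),
              read_row("v", "s4", alt_rev = 1, qual = 33))
  f <- filter_base_quality(sr)
  minor <- c(12, 12, 33); major <- c(31, 31, 31, 31, 28, 28)
  r <- rank(c(minor, major))
  w_obs <- sum(r[1:3])
  sets <- utils::combn(9, 3)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  expect_equal(f$p_value, mean(ws <= w_obs), tolerance = 1e-12)

  # strongly degraded minor qualities: removed at alpha = 1e-5
  sr <- rbind(read_row("v", "s1", ref_fwd = 150, ref_rev = 150, qual = 35),
              read_row("v", "s2", alt_fwd = 15, alt_rev = 15, qual = 4))
  f <- filter_base_quality(sr)
  expect_lt(f$p_value, 1e-5)
  expect_false(f$keep)

  # no minor-allele reads at all: keep with p = 1
  sr <- read_row("v", "s1", ref_fwd = 10, qual = 30)
  expect_equal(filter_base_quality(sr)$p_value, 1)
})

test_that("strand-bias filter is pooled two-sided Fisher", {
  # perfectly balanced table
  sr <- read_row("v", "s1", ref_fwd = 10, ref_rev = 10,
                 alt_fwd = 5, alt_rev = 5)
  f <- filter_strand_bias(sr)
  expect_equal(f$p_value, 1)
  expect_true(f$keep)

  # table (12, 2; 3, 13) against the hypergeometric-sum oracle
  sr <- read_row("v", "s1", ref_fwd = 12, ref_rev = 2,
                 alt_fwd = 3, alt_rev = 13)
  f <- filter_strand_bias(sr)
  expect_equal(f$p_value, oracle_fisher_two_sided(12, 2, 3, 13),
               tolerance = 1e-10)

  # empty minor row: degenerate margin, keep
  sr <- read_row("v", "s1", ref_fwd = 9, ref_rev = 11)
  f <- filter_strand_bias(sr)
  expect_equal(f$p_value, 1)
  expect_true(f$keep)
})

test_that("depth/MAPQ filter applies mean +/- 3 SD and MAPQ >= 20", {
  expect_true(filter_depth_mapq(100, 100, 10, mapq = 45))
  expect_false(filter_depth_mapq(140, 100, 10, mapq = 45))  # mean + 4 SD
  expect_true(filter_depth_mapq(129, 100, 10, mapq = 45))
  expect_false(filter_depth_mapq(100, 100, 10, mapq = 10))  # low MAPQ
  expect_true(filter_depth_mapq(0, 20, 10, mapq = 45))      # floor at 0
})

test_that("filter decisions are idempotent", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_genes = 3,
                    sites_per_gene = 4, maf_shape1 = 2, maf_shape2 = 8,
                    seed = 31)
  sim <- simulate_cohort(cfg, reads = TRUE)
  once <- lapply(split(sim$reads, sim$reads$variant), function(s)
    c(filter_base_quality(s)$p_value, filter_strand_bias(s)$p_value))
  twice <- lapply(split(sim$reads, sim$reads$variant), function(s)
    c(filter_base_quality(s)$p_value, filter_strand_bias(s)$p_value))
  expect_identical(once, twice)
})

test_that("calling recovers true allele frequencies and genotypes", {
  # EM consistency: n = 1000 samples, depth 20
  v <- data.frame(id = sprintf("v%02d", 1:8), chrom = "chr1",
                  pos = 1:8, ref = "A", alt = "G", gene = "G1",
                  class = "non-silent")
  q_true <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4)
  set.seed(99)
  n <- 1000
  dosage <- t(vapply(q_true, function(q)
    sample(0:2, n, TRUE, c((1 - q)^2, 2 * q * (1 - q), q^2)),
    integer(n)))
  v$maf <- q_true
  gm <- genotype_matrix(dosage, v, paste0("S", 1:n))
  rd <- simulate_reads(gm, mean_depth = 20, base_error_rate = 0.01,
                       seed = 7)
  calls <- call_variants(rd, samples = gm$samples)
  # compare p_hat to the realized sample frequency; the binomial
  # sampling bound at 2n draws covers the drawing of genotypes
  samp_af <- rowSums(dosage) / (2 * n)
  err <- calls$info$p_hat - samp_af
  expect_lt(sqrt(mean(err^2)), sqrt(mean(q_true * (1 - q_true) / (2 * n))))

  # genotype concordance >= 99% at depth ~20, error 1%
  called <- calls$dosage
  truth <- dosage[match(rownames(called), v$id), , drop = FALSE]
  ok <- !is.na(called)
  expect_gte(mean(called[ok] == truth[ok]), 0.99)
})

test_that("call_variants bookkeeping is consistent", {
  cfg <- sim_config(n_cases = 25, n_controls = 25, n_genes = 2,
                    sites_per_gene = 5, maf_shape1 = 2, maf_shape2 = 6,
                    seed = 17)
  sim <- simulate_cohort(cfg, reads = TRUE)
  calls <- call_variants(sim$reads, samples = sim$gm$samples)
  expect_equal(nrow(calls$info), 10)
  expect_identical(rownames(calls$dosage),
                   calls$info$id[calls$info$pass])
  expect_true(all(calls$info$pass == (calls$info$called &
                                        calls$info$bq_keep &
                                        calls$info$sb_keep &
                                        calls$info$dp_keep)))
  gm <- calls_to_genotype_matrix(calls, sim$gm$variants)
  expect_s3_class(gm, "genotype_matrix")
  expect_error(calls_to_genotype_matrix(
    calls, sim$gm$variants[0, ]), "annotation missing")
})
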