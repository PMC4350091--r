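test_that("classify_maf applies the 1% / 5% boundaries", {
  expect_identical(classify_maf(0.009), "rare")
  expect_identical(classify_maf(0.01), "low-frequency")
  expect_identical(classify_maf(0.049), "low-frequency")
  expect_identical(classify_maf(0.05), "common")
  expect_identical(classify_maf(0), "rare")
  expect_error(classify_maf(0.6), "maf")
  expect_error(classify_maf(-0.1), "maf")
})

## shared toy: 2 variants x 4 samples (cases first), hand countable
toy_X <- rbind(c(1L, 2L, 0L, 1L),
               c(0L, 1L, 0L, 0L))
toy_case <- c(TRUE, TRUE, FALSE, FALSE)

test_that("burden_stat is the case minor-allele count", {
  expect_equal(burden_stat(toy_X, toy_case), 1 + 2 + 0 + 1)
  expect_equal(burden_stat(matrix(0L, 2, 4), toy_case), 0)
  # all minor alleles in controls: one-sided statistic is 0
  expect_equal(burden_stat(toy_X, !toy_case), 0 + 1)
  expect_equal(burden_stat(rbind(c(0L, 0L, 2L, 1L)), toy_case), 0)
  expect_error(burden_stat(toy_X[0, , drop = FALSE], toy_case),
               "no qualifying")
})

test_that("frqwgt_stat uses pseudocounted control-frequency weights", {
  # hand arithmetic: n_ctrl = 2; variant 1 has 1 control allele,
  # q1 = 2/6, w1 = 1/sqrt(2 * 2/6 * 4/6); variant 2 has 0,
  # q2 = 1/6, w2 = 1/sqrt(2 * 1/6 * 5/6)
  w1 <- 1 / sqrt(2 * (2 / 6) * (4 / 6))
  w2 <- 1 / sqrt(2 * (1 / 6) * (5 / 6))
  expect_equal(frqwgt_stat(toy_X, toy_case), w1 * 3 + w2 * 1,
               tolerance = 1e-12)
  # control-absent variants weigh more than control-frequent ones
  expect_gt(w2, w1)
  # equal control frequencies: proportional to the plain burden
  Xeq <- rbind(c(2L, 0L, 1L, 0L), c(0L, 1L, 1L, 0L))
  w <- 1 / sqrt(2 * (2 / 6) * (4 / 6))
  expect_equal(frqwgt_stat(Xeq, toy_case), w * burden_stat(Xeq, toy_case))
})

test_that("vt_stat maximizes the standardized burden over thresholds", {
  # single observed MAF: equals the standardized burden there
  X1 <- rbind(c(1L, 1L, 0L, 0L))
  z_direct <- {
    b <- colSums(X1); n <- 4; nc <- 2
    s <- sum(b[toy_case]); mu <- nc * mean(b)
    v <- nc * (n - nc) / (n - 1) * mean((b - mean(b))^2)
    (s - mu) / sqrt(v)
  }
  expect_equal(vt_stat(X1, toy_case, maf = 0.1), z_direct)

  # two thresholds: explicit maximum of the two standardized burdens
  X2 <- rbind(c(1L, 0L, 0L, 0L), c(1L, 2L, 0L, 1L))
  maf2 <- c(0.05, 0.2)
  z_at <- vapply(list(X2[1, , drop = FALSE], X2), function(Xt) {
    b <- colSums(Xt); n <- 4; nc <- 2
    s <- sum(b[toy_case]); mu <- nc * mean(b)
    v <- nc * (n - nc) / (n - 1) * mean((b - mean(b))^2)
    if (v <= 0) 0 else (s - mu) / sqrt(v)
  }, numeric(1))
  expect_equal(vt_stat(X2, toy_case, maf2), max(z_at))
})

test_that("uniq_stat counts case alleles at control-free loci", {
  expect_equal(uniq_stat(toy_X, toy_case), 1)    # only variant 2
  # every variant seen in a control: 0
  Xc <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  expect_equal(uniq_stat(Xc, toy_case), 0)
  # four case-only loci with one carrier each: 4
  X4 <- matrix(0L, 4, 4); X4[, 1] <- 1L
  expect_equal(uniq_stat(X4, toy_case), 4)
})

test_that("statistics are invariant to sample and variant order", {
  set.seed(8)
  X <- matrix(rbinom(6 * 40, 2, 0.05), 6, 40)
  case <- rep(c(TRUE, FALSE), 20)
  maf <- runif(6, 0.001, 0.02)
  po <- sample(40); vo <- sample(6)
  expect_equal(burden_stat(X, case), burden_stat(X[vo, po], case[po]))
  expect_equal(frqwgt_stat(X, case), frqwgt_stat(X[vo, po], case[po]))
  expect_equal(uniq_stat(X, case), uniq_stat(X[vo, po], case[po]))
  expect_equal(vt_stat(X, case, maf), vt_stat(X[vo, po], case[po], maf[vo]))
})

test_that("adding a case-only minor allele never decreases the statistics", {
  set.seed(14)
  for (rep in 1:20) {
    X <- matrix(rbinom(5 * 30, 2, 0.04), 5, 30)
    case <- rep(c(TRUE, FALSE), 15)
    i <- sample(5, 1)
    j <- sample(which(case & X[i, ] < 2), 1)
    X2 <- X; X2[i, j] <- X2[i, j] + 1L
    expect_gte(burden_stat(X2, case), burden_stat(X, case))
    expect_gte(frqwgt_stat(X2, case), frqwgt_stat(X, case))
    expect_gte(uniq_stat(X2, case), uniq_stat(X, case))
  }
})

test_that("adaptive permutation stops early on null genes", {
  set.seed(33)
  X <- matrix(rbinom(4 * 60, 2, 0.08), 4, 60)
  case <- rep(c(TRUE, FALSE), 30)
  # median-ish observed statistic: early stop, p around 0.5
  out <- adaptive_permutation(burden_stat, X, case, r_stop = 10,
                              B_max = 1e5, seed = 3)
  expect_lt(out$b, 1000)
  expect_gt(out$p, 0.05)
})

test_that("adaptive permutation hits the floor when unbeatable", {
  # cases carry a private allele at every one of 10 variants
  n <- 40
  case <- rep(c(TRUE, FALSE), c(10, 30))
  X <- matrix(0L, 10, n)
  X[cbind(1:10, 1:10)] <- 2L
  out <- adaptive_permutation(burden_stat, X, case, r_stop = 10,
                              B_max = 300, seed = 6)
  expect_equal(out$p, 1 / 301)
  expect_equal(out$b, 300)
})

test_that("adaptive permutation matches exhaustive enumeration at n = 6", {
  X <- rbind(c(2L, 1L, 0L, 0L, 1L, 0L),
             c(1L, 0L, 0L, 1L, 0L, 0L))
  case <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  for (fn in list(burden_stat, frqwgt_stat, uniq_stat)) {
    exact <- oracle_perm_exact(fn, X, case)
    out <- adaptive_permutation(fn, X, case, r_stop = 5000, B_max = 5000,
                                seed = 12)
    expect_lt(abs(out$p - exact),
              3 * sqrt(exact * (1 - exact) / 5000) + 2e-3)
  }
})

test_that("adaptive and fixed-B permutation agree within Monte-Carlo error", {
  set.seed(101)
  X <- matrix(rbinom(5 * 50, 2, 0.06), 5, 50)
  case <- rep(c(TRUE, FALSE), 25)
  adapt <- adaptive_permutation(burden_stat, X, case, r_stop = 3000,
                                B_max = 3000, seed = 9)
  fixed <- adaptive_permutation(burden_stat, X, case, r_stop = 3000,
                                B_max = 3000, seed = 10)
  expect_lt(abs(adapt$p - fixed$p), 3 * sqrt(0.25 / 3000) * 2)
})

test_that("carrier Fisher columns reproduce published top-gene rows", {
  pub <- published_table("carrier_freqs")
  brwd1 <- pub[pub$label == "BRWD1", ]
  k_case <- reconstruct_count(brwd1$freq_case_pct, brwd1$n_case, 2)
  k_ctrl <- reconstruct_count(brwd1$freq_ctrl_pct, brwd1$n_ctrl, 2)
  expect_identical(c(k_case, k_ctrl), c(55L, 29L))
  cf <- carrier_fisher(k_case, 757, k_ctrl, 709)
  expect_equal(round(cf$odds_ratio, 2), 1.84)
  expect_equal(round(cf$p_value, 2), 0.01)

  usp26 <- pub[pub$label == "USP26", ]
  cf2 <- carrier_fisher(reconstruct_count(usp26$freq_case_pct, 757, 2), 757,
                        reconstruct_count(usp26$freq_ctrl_pct, 709, 2), 709)
  expect_equal(round(cf2$odds_ratio, 2), 4.25)
  expect_equal(round(cf2$p_value, 2), 0.07)

  # equal carrier frequencies: null table
  cf0 <- carrier_fisher(20, 100, 20, 100)
  expect_equal(cf0$odds_ratio, 1)
  expect_equal(cf0$p_value, 1)
})

test_that("gene_burden_scan returns Table-1-shaped rows", {
  cfg <- sim_config(n_cases = 80, n_controls = 80, n_genes = 6,
                    sites_per_gene = 6, carrier_odds_ratio = 4, seed = 44)
  sim <- simulate_cohort(cfg)
  gb <- gene_burden_scan(sim$gm, sim$cohort, r_stop = 5, B_max = 500,
                         seed = 2)
  expect_true(all(c("gene", "p_BURDEN", "p_FRQWGT", "p_VT", "p_UNIQ",
                    "carrier_freq_case", "carrier_freq_ctrl",
                    "odds_ratio", "fisher_p") %in% names(gb)))
  pcols <- as.matrix(gb[, c("p_BURDEN", "p_FRQWGT", "p_VT", "p_UNIQ")])
  expect_true(all(pcols >= 1 / 501 & pcols <= 1))
  expect_true(all(gb$carrier_freq_case >= 0 & gb$carrier_freq_case <= 100))
})

test_that("UNIQ outperforms BURDEN under case-unique enrichment", {
  # replicated genes where the signal is all case-private, diluted by
  # shared variants; sign test on paired p-values
  set.seed(55)
  n <- 60; case <- rep(c(TRUE, FALSE), c(30, 30))
  wins <- 0L; informative <- 0L
  for (r in 1:24) {
    shared <- matrix(rbinom(4 * n, 2, 0.10), 4, n)
    private <- matrix(0L, 3, n)
    private[cbind(1:3, sample(which(case), 3))] <- 1L
    X <- rbind(shared, private)
    pu <- adaptive_permutation(uniq_stat, X, case, r_stop = 5,
                               B_max = 500, seed = 100 + r)$p
    pb <- adaptive_permutation(burden_stat, X, case, r_stop = 5,
                               B_max = 500, seed = 200 + r)$p
    if (pu != pb) {
      informative <- informative + 1L
      if (pu < pb) wins <- wins + 1L
    }
  }
  expect_gt(stats::pbinom(wins - 1, informative, 0.5,
                          lower.tail = FALSE), 0)  # guard: defined
  expect_gt(wins, informative / 2)
})
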