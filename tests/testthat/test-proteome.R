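test_that("report filtering applies all four predicates with printed boundary semantics", {
  rep_tab <- data.frame(
    q_value =          c(0.02, 0.01, 0.001, 0.001),
    protein_q_value =  c(0.001, 0.01, 0.001, 0.001),
    mass_evidence =    c(0.9, 0.51, 0.9, 0.5),
    precursor_charge = c(2, 2, 1, 2))
  kept <- filter_report(rep_tab)
  expect_equal(rownames(kept), "2")  # q<=0.01 is inclusive, ev>0.5 and z>1 strict
  expect_error(filter_report(rep_tab[, -1]), "q_value")
})

test_that("imputation fills only masked cells from the down-shifted normal", {
  set.seed(31)
  m <- matrix(rnorm(50, 25, 2), 10, 5)
  # no missing cells: identity
  out <- impute_missing(m, seed = 1)
  expect_identical(out$matrix, m)
  expect_false(any(out$imputed))

  holes <- m
  holes[sample(50, 15)] <- NA
  o1 <- impute_missing(holes, seed = 2)
  o2 <- impute_missing(holes, seed = 2)
  expect_identical(o1$matrix, o2$matrix)
  expect_identical(o1$matrix[!is.na(holes)], holes[!is.na(holes)])
  o3 <- impute_missing(holes, seed = 3)
  expect_false(identical(o1$matrix[is.na(holes)], o3$matrix[is.na(holes)]))
  expect_error(impute_missing(matrix(NA_real_, 3, 3), seed = 1), "observed")
})

test_that("imputed values recover the down-shifted mean and shrunken SD", {
  set.seed(77)
  n_obs <- 2000L; n_miss <- 10000L
  obs <- rnorm(n_obs, 25, 2)
  m <- matrix(c(obs, rep(NA_real_, n_miss)), ncol = 1)
  out <- impute_missing(m, seed = 5, per_column = TRUE)
  imp <- out$matrix[out$imputed]
  mu <- mean(obs); s <- sd(obs)
  target_mean <- mu - 1.8 * s
  target_sd <- 0.25 * s
  se_mean <- target_sd / sqrt(n_miss)
  se_sd <- target_sd / sqrt(2 * (n_miss - 1))
  expect_lt(abs(mean(imp) - target_mean), 3 * se_mean)
  expect_lt(abs(sd(imp) - target_sd), 3 * se_sd)
})

test_that("differential test handles identical groups and degenerate rows", {
  m <- rbind(c(1, 2, 3, 1, 2, 3), c(5, 5, 5, 5, 5, 5))
  groups <- rep(c("A", "B"), each = 3)
  res <- differential_test(m, groups)
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  expect_true(res$degenerate[2])
  expect_false(res$degenerate[1])
})

test_that("BH adjustment equals the closed-form step-up on enumerated vectors", {
  cases <- list(
    c(0.01, 0.02, 0.03, 0.04),
    c(0.04, 0.01, 0.03, 0.02),
    c(0.001, 0.5, 0.9),
    c(0.2, 0.2, 0.2, 0.2, 0.2),
    c(0.03, 0.001, 0.8, 0.047, 0.1, 0.25),
    runif(6))
  for (p in cases) {
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # adjusted p from the pipeline matches the oracle on real test output
  set.seed(8)
  mm <- matrix(rnorm(60, 20, 1), 10, 6)
  res <- differential_test(mm, rep(c("A", "B"), each = 3))
  expect_equal(res$adjusted_p, oracle_bh(res$p_value), tolerance = 1e-12)
  # monotone in raw-p rank and capped at 1
  ord <- order(res$p_value)
  expect_true(all(diff(res$adjusted_p[ord]) >= -1e-15))
  expect_true(all(res$adjusted_p <= 1))
})

test_that("null proteome t tests are calibrated at the nominal level", {
  pvals <- c()
  for (s in 1:5) {
    sim <- simulate_proteome(n_proteins = 400, n_per_group = 3,
                             effect_size = 0, mnar_max = 0, seed = 600 + s)
    # Student variant: exact under the simulation's equal-variance null
    # (Welch, the robust default, is mildly conservative at n = 3)
    res <- differential_test(sim$matrix, sim$groups, var_equal = TRUE)
    pvals <- c(pvals, res$p_value)
  }
  rate <- mean(pvals < 0.05)
  n <- length(pvals)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("volcano classification follows the printed cuts and ignores row order", {
  res <- data.frame(protein = paste0("p", 1:4),
                    log2fc = c(2.5, 1.9, -3, 0.1),
                    p_value = c(0.01, 0.001, 0.3, 0.9),
                    adjusted_p = c(0.01, 0.001, 0.4, 0.95))
  cls <- classify_volcano(res)
  expect_equal(cls$class, c("up_A", "not_significant", "up_B", "not_significant"))
  perm <- classify_volcano(res[c(3, 1, 4, 2), ])
  expect_equal(perm$class[perm$protein == "p3"], "up_B")
})

test_that("z-scored median profiles have mean 0 and unit population SD", {
  m <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 1)
  z <- zscore_profiles(m, rep(c("c1", "c2", "c3"), each = 3))
  expect_equal(as.numeric(z$profiles),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  # constant row convention
  mc <- matrix(5, 1, 6)
  zc <- zscore_profiles(mc, rep(c("c1", "c2"), each = 3))
  expect_equal(as.numeric(zc$profiles), c(0, 0))
  expect_true(zc$constant)
  # generic normalization property
  set.seed(12)
  mm <- matrix(rnorm(40), 4, 10)
  zz <- zscore_profiles(mm, rep(paste0("c", 1:5), each = 2))
  expect_true(all(abs(rowMeans(zz$profiles)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(zz$profiles^2)) - 1) < 1e-9))
})
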