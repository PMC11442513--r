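test_that("paired permutation test handles identity, separation and degeneracy", {
  a <- rnorm(19)
  t1 <- permutation_test(a, a, paired = TRUE, n_perm = 200, seed = 1)
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1)
  # strongly separated samples reach the add-one floor
  set.seed(20)
  b <- rnorm(19)
  t2 <- permutation_test(b + 3, b, paired = TRUE, n_perm = 500, seed = 2)
  expect_equal(t2$p_value, 1 / 501)
  expect_warning(t3 <- permutation_test(rep(2, 5), rep(2, 5), n_perm = 100),
                 "degenerate")
  expect_equal(t3$p_value, 1)
  expect_error(permutation_test(1:5, 1:5, n_perm = 10), "n_perm")
  expect_error(permutation_test(1:5, 1:4, paired = TRUE), "equal lengths")
})

test_that("permutation p-values are seeded and valid under the null", {
  a <- rnorm(19); b <- rnorm(19)
  p1 <- permutation_test(a, b, paired = TRUE, n_perm = 300, seed = 7)$p_value
  p2 <- permutation_test(a, b, paired = TRUE, n_perm = 300, seed = 7)$p_value
  expect_identical(p1, p2)
  # type-I error near the nominal level (coarse check; the acceptance
  # suite runs the full calibration)
  set.seed(21)
  rej <- mean(replicate(150, {
    permutation_test(rnorm(19), rnorm(19), paired = TRUE, n_perm = 200,
                     seed = sample.int(1e6, 1))$p_value <= 0.05
  }))
  expect_lt(rej, 0.11)
  # unpaired variant distinguishes separated groups
  expect_lt(permutation_test(rnorm(15) + 2, rnorm(15), paired = FALSE,
                             n_perm = 300, seed = 3)$p_value, 0.01)
})

test_that("BH correction matches worked examples and reference implementations", {
  r <- fdr_correct(c(0.01, 0.02, 0.03), alpha = 0.05)
  expect_true(all(r$rejected))
  r2 <- fdr_correct(0.5)
  expect_false(r2$rejected)
  expect_equal(r2$adjusted, 0.5)
  expect_equal(fdr_correct(numeric(0))$adjusted, numeric(0))
  set.seed(22)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_correct(p)$adjusted, bh_brute(p), tolerance = 1e-12)
  }
  # order invariance and monotonicity
  p <- runif(20)
  o <- sample(20)
  expect_equal(fdr_correct(p)$adjusted[o], fdr_correct(p[o])$adjusted)
  adj <- fdr_correct(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("cluster permutation finds a banded effect and ignores none", {
  freqs <- seq(1, 45, 0.5)
  set.seed(23)
  base <- matrix(rnorm(12 * length(freqs)), 12)
  expect_length(cluster_permutation(base, base, freqs, n_perm = 200, seed = 1), 0)
  eff <- base
  sel <- freqs >= 3 & freqs <= 12
  eff[, sel] <- eff[, sel] + 1.2
  cl <- cluster_permutation(eff, base, freqs, n_perm = 300, seed = 2)
  expect_gt(length(cl), 0)
  main <- cl[[which.max(vapply(cl, function(c) abs(c$mass), numeric(1)))]]
  expect_lte(main$p_value, 0.05)
  expect_true(all(main$freqs >= 2.5 & main$freqs <= 12.5))
  # a single noisy bin rarely forms a surviving cluster
  one <- base
  one[, 40] <- one[, 40] + 0.5
  cl1 <- cluster_permutation(one, base, freqs, n_perm = 300, seed = 3)
  sig <- vapply(cl1, function(c) c$p_value <= 0.05, logical(1))
  expect_equal(sum(sig), 0)
  expect_error(cluster_permutation(base[1, , drop = FALSE],
                                   base[1, , drop = FALSE], freqs), ">= 2 units")
})

test_that("Monte Carlo Lilliefors agrees with the reference statistic and discriminates", {
  set.seed(24)
  x <- rnorm(19)
  lt <- lilliefors_test(x, n_mc = 500, seed = 1)
  expect_equal(lt$statistic, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-12)
  expect_gt(lt$p_value, 0.05)
  y <- rexp(40)
  expect_lt(lilliefors_test(y, n_mc = 500, seed = 2)$p_value, 0.05)
  expect_error(lilliefors_test(rnorm(3)), "n >= 4")
})

test_that("hemisphere aggregation averages within subject and keeps unilateral subjects", {
  df <- data.frame(subject_id = c("s1", "s1", "s2"),
                   est = c(0.2, 0.4, 0.9))
  agg <- aggregate_hemispheres(df)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$est, c(0.3, 0.9))
  # 19 hemispheres from 10 subjects collapse to 10 rows
  df19 <- data.frame(subject_id = rep(sprintf("s%02d", 1:10), each = 2)[-13],
                     est = rnorm(19))
  expect_equal(nrow(aggregate_hemispheres(df19)), 10)
})

test_that("severity correlation reports exact affine relations and errors on degeneracy", {
  tab <- data.frame(subject_id = 1:10, est = seq(0.1, 1, 0.1))
  tab$severity <- 5 + 3 * tab$est
  ct <- correlate_with_severity(tab, "est", seed = 1)
  expect_equal(ct$statistic, 1, tolerance = 1e-9)
  expect_lt(ct$p_value, 1e-6)
  tab$flat <- 1
  expect_error(correlate_with_severity(tab, "flat"), "variance")
  expect_error(correlate_with_severity(tab[1:2, ], "est"), "3 subjects")
  expect_error(correlate_with_severity(tab, "missing_col"), "not found")
})

test_that("null severity correlations are centered with near-nominal rejection", {
  set.seed(25)
  out <- replicate(120, {
    tab <- data.frame(subject_id = 1:10, est = rnorm(10),
                      severity = rnorm(10))
    ct <- correlate_with_severity(tab, "est", n_mc = 100, seed = 1)
    c(ct$statistic, ct$p_value <= 0.05)
  })
  expect_lt(abs(mean(out[1, ])), 0.12)
  expect_lt(mean(out[2, ]), 0.13)
})
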