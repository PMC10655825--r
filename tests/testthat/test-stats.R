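test_that("paired_t_d reproduces textbook values on [1,2,3,4]", {
  r <- paired_t_d(c(1, 2, 3, 4))
  expect_equal(r$mean, 2.5)
  expect_equal(r$t, 3.8730, tolerance = 1e-4)
  expect_equal(r$d, 1.9365, tolerance = 1e-4)
  expect_equal(r$p, 2 * pt(-sqrt(15), df = 3))  # t = sqrt(15) exactly
  expect_equal(r$p, 0.0305, tolerance = 5e-3)
  # independent oracle: stats::t.test
  tt <- t.test(c(1, 2, 3, 4))
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
})

test_that("paired_t_d is antisymmetric and rejects degenerate input", {
  x <- c(0.3, -0.1, 0.5, 0.2, 0.4)
  a <- paired_t_d(x); b <- paired_t_d(-x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(paired_t_d(rep(0, 5)), "degenerate")
  expect_error(paired_t_d(1), "at least 2")
})

test_that("t = d * sqrt(n) for any group test", {
  set.seed(21)
  for (n in c(4, 9, 16)) {
    r <- paired_t_d(rnorm(n, 0.2))
    expect_equal(r$t, r$d * sqrt(n), tolerance = 1e-9)
  }
})

test_that("unit_t_map reduces to paired_t_d at a single unit", {
  set.seed(5)
  x <- rnorm(12, 0.3)
  m <- unit_t_map(matrix(x, ncol = 1))
  r <- paired_t_d(x)
  expect_equal(m$t[1], r$t)
  expect_equal(m$p[1], r$p)
  # zero-variance units masked; injected sign recovered
  dat <- cbind(x, 0.5, -x)
  m2 <- unit_t_map(dat)
  expect_true(m2$masked[2] && is.na(m2$t[2]))
  expect_equal(m2$t[3], -m2$t[1])
})

test_that("an injected effect attains the maximum |t| in most replicates", {
  set.seed(99)
  hits <- replicate(200, {
    d <- matrix(rnorm(20 * 10), 20)
    d[, 7] <- d[, 7] + 1                   # SNR 1 injection at unit 7
    m <- unit_t_map(d)
    (which.max(abs(m$t)) == 7) && (m$t[7] > 0)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("permutation max-T respects its bounds and reductions", {
  set.seed(2)
  d <- matrix(rnorm(10 * 6), 10)
  out <- permutation_maxT(d, n_permutations = 200, rng_seed = 3)
  expect_true(all(out$p_corrected >= 1 / 201))
  # corrected p never below uncorrected p
  unc <- unit_t_map(d)$p
  expect_true(all(out$p_corrected >= unc - 1e-12))
  # single-unit map: corrected p equals the sign-flip p of the paired test
  x <- c(0.9, 0.4, 1.1, 0.2, 0.8, -0.1, 0.5, 0.7)
  o1 <- permutation_maxT(matrix(x, ncol = 1), 4000, rng_seed = 11)
  t0 <- abs(paired_t_d(x)$t)
  # exact sign-flip p by full enumeration of 2^8 assignments
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  tperm <- apply(signs, 1, function(s) abs(paired_t_d(s * x)$t))
  p_exact <- mean(tperm >= t0 - 1e-12)
  expect_equal(o1$p_corrected[1], p_exact, tolerance = 0.02)
  expect_error(permutation_maxT(d, 0), "n_permutations")
  # deterministic given the seed
  o2 <- permutation_maxT(d, 200, rng_seed = 3)
  expect_identical(out$p_corrected, o2$p_corrected)
})

test_that("matrix comparison is symmetric and recovers injected block shifts", {
  spec <- fast_spec(n_subjects = 8, frames_per_run = 200,
                    shift_mean = c("SAL-TMS" = 0, "DN-TMS" = 0.5),
                    shift_sd = 1e-6)
  atl <- spec$atlas
  pre <- lapply(1:8, function(s)
    fc_matrix(generate_bold_run(spec, s, "DN-TMS", "pre", 1), atl))
  post <- lapply(1:8, function(s)
    fc_matrix(generate_bold_run(spec, s, "DN-TMS", "post", 1), atl))
  mc <- matrix_comparison(pre, post)
  expect_identical(unclass(mc$delta_z), t(unclass(mc$delta_z)))
  expect_gt(fc_block_mean(mc$delta_z, "default", "salience"), 0)
  # identical inputs: zero deltas, masked p
  mc0 <- matrix_comparison(pre, pre)
  expect_true(all(abs(mc0$delta_z) < 1e-12, na.rm = TRUE))
  expect_true(all(is.na(mc0$p)))
  # ordering mismatch rejected
  bad <- pre
  rownames(bad[[1]]) <- rev(rownames(bad[[1]]))
  expect_error(matrix_comparison(bad, post), "ordering")
})

test_that("coupling correlation satisfies R^2 = r^2 with n-2 df p values", {
  x <- c(1, 2, 3, 4, 5)
  r <- coupling_correlation(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)
  set.seed(4)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  cc <- coupling_correlation(a, b)
  expect_equal(cc$r_squared, cc$r^2, tolerance = 1e-12)
  ct <- cor.test(a, b)                     # independent oracle
  expect_equal(cc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cc$p, ct$p.value, tolerance = 1e-12)
  expect_error(coupling_correlation(a, rep(1, 30)), "variance")
})

test_that("the published r values square to the published R^2 at 2 d.p.", {
  printed <- data.frame(r = c(0.71, 0.67, -0.48),
                        r2 = c(0.50, 0.45, 0.23))
  expect_equal(round(printed$r^2, 2), printed$r2)
})

test_that("subgroup divergence selects deterministic top/bottom sets", {
  d <- 1:16
  sg <- subgroup_divergence(d, fc_delta = d, k = 5)
  expect_equal(sg$bottom$ids, 1:5)
  expect_equal(sg$top$ids, 12:16)
  expect_gt(sg$top$fc_mean, sg$bottom$fc_mean)   # monotone coupling
  # ties broken by subject id
  sg2 <- subgroup_divergence(rep(1, 10), fc_delta = 1:10, k = 5,
                             ids = 1:10)
  expect_equal(sg2$bottom$ids, 1:5)
  expect_error(subgroup_divergence(1:8, 1:8, k = 5), "2k")
})

test_that("paired t type-I error is nominal under a Gaussian null", {
  set.seed(31)
  rej <- replicate(4000, paired_t_d(rnorm(16))$p < 0.05)
  expect_gt(mean(rej), 0.04)
  expect_lt(mean(rej), 0.06)
})
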