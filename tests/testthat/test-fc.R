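test_that("fisher_z matches closed-form atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  z1 <- fisher_z(1)
  expect_true(is.finite(z1))
  expect_equal(z1, atanh(1 - 1e-7))
  expect_equal(z1, 8.406, tolerance = 1e-3)
  expect_equal(fisher_z(-1), -z1)
  expect_error(fisher_z(1.2), "outside")
  expect_equal(inv_fisher_z(fisher_z(0.3)), 0.3, tolerance = 1e-12)
})

test_that("nuisance regression builds 19 columns and orthogonal residuals", {
  atl <- nuisance_atlas()
  set.seed(7)
  n <- 50
  run <- bold_run(matrix(rnorm(n * n_units(atl)), n), tr_seconds = 1,
                  motion = as.data.frame(matrix(rnorm(n * 6, sd = 0.05), n, 6,
                    dimnames = list(NULL, names(zero_motion(1))))))
  res <- regress_nuisance(run, atl)
  # intercept + 9 base regressors + 9 temporal derivatives
  expect_length(attr(res, "design_columns"), 19L)
  # residuals orthogonal to every regressor
  wb <- rowMeans(run$data)
  dwb <- c(0, diff(wb))
  for (v in list(rep(1, n), wb, dwb, run$motion$trans_x,
                 rowMeans(run$data[, region_units(atl, "white_matter")])))
    expect_lt(abs(sum(res$data[, 1] * v)),
              1e-8 * sqrt(sum(res$data[, 1]^2) * sum(v^2)) + 1e-10)
})

test_that("a unit equal to the whole-brain mean is residualised to zero", {
  atl <- nuisance_atlas()
  set.seed(5)
  N <- n_units(atl)
  dat <- matrix(rnorm(40 * N), 40)
  # construct unit 1 so that it equals the whole-brain mean after insertion
  dat[, 1] <- rowSums(dat[, -1]) / (N - 1)
  run <- bold_run(dat, tr_seconds = 1,
                  motion = as.data.frame(matrix(rnorm(240, sd = 0.05), 40, 6,
                    dimnames = list(NULL, names(zero_motion(1))))))
  expect_equal(dat[, 1], rowMeans(dat))     # the construction holds
  res <- regress_nuisance(run, atl)
  expect_lt(max(abs(res$data[, 1])), 1e-8)
})

test_that("rank-deficient nuisance designs are rejected with column names", {
  atl <- nuisance_atlas()
  n <- 30
  m <- zero_motion(n)                      # all-zero motion: collinear
  run <- bold_run(matrix(rnorm(n * n_units(atl)), n), 1, motion = m)
  expect_error(regress_nuisance(run, atl), "collinear")
})

test_that("low-pass filter has the specified spectral behaviour", {
  n <- 400; t <- seq_len(n)
  mk <- function(f) sin(2 * pi * f * t)    # TR 1 s
  run <- bold_run(cbind(mk(0.2), mk(0.01), rep(3.7, n)), tr_seconds = 1)
  out <- lowpass_filter(run, 0.08)
  # 0.2 Hz (2.5x cutoff): attenuated below 10% of input amplitude
  expect_lt(sd(out$data[, 1]), 0.1 * sd(run$data[, 1]))
  # 0.01 Hz (0.125x cutoff): preserved within 5%
  expect_equal(sd(out$data[, 2]), sd(run$data[, 2]), tolerance = 0.05)
  # constant series unchanged exactly (DC preserved)
  expect_equal(out$data[, 3], run$data[, 3])
  expect_error(lowpass_filter(bold_run(cbind(mk(0.1), mk(0.1)), 3), 0.2),
               "Nyquist")
})

test_that("extract_timecourse handles unit sets and weights", {
  run <- bold_run(matrix(1:20, 5, 4), tr_seconds = 1)
  expect_equal(extract_timecourse(run, seed_spec("sphere", units = 2)),
               run$data[, 2])
  # two identical units: same series
  run2 <- bold_run(cbind(run$data[, 1], run$data[, 1]), 1)
  expect_equal(extract_timecourse(run2, seed_spec("region_set", units = 1:2)),
               run2$data[, 1])
  # weights (2, 0) on units (A, B) -> series A
  expect_equal(extract_timecourse(run, seed_spec("map_weighted",
                                                 weights = c(2, 0, 0, 0))),
               run$data[, 1])
  expect_error(seed_spec("sphere", units = integer(0)), "empty")
  expect_error(extract_timecourse(run, seed_spec("sphere", units = 9)),
               "outside")
})

test_that("seed_fc_map reports clipped z at the seed and masks flat units", {
  set.seed(11)
  x <- matrix(rnorm(300), 100, 3)
  x[, 3] <- 0                                 # zero-variance unit
  run <- bold_run(x, tr_seconds = 1)
  expect_warning(m <- seed_fc_map(run, seed_spec("sphere", units = 1)),
                 "zero-variance")
  expect_equal(unclass(m)[1], fisher_z(1))
  expect_true(is.na(unclass(m)[3]))
  expect_equal(attr(m, "in_seed"), 1L)
})

test_that("seed maps reflect the designed covariance signs", {
  spec <- fast_spec(frames_per_run = 2000, global_sd = 0)
  atl <- spec$atlas
  run <- generate_bold_run(spec, 1, "none", "pre", 1)
  pt <- parcel_table(atl)
  # seed on a DN region: positive z over DN parcels, negative over SAL
  dn_idx <- which(pt$network == "default" & pt$region != "DN_dlPFC")
  sal_idx <- which(pt$network == "salience" & pt$region != "SAL_dlPFC")
  m <- seed_fc_map(run, seed_spec("region_set", units = dn_idx[1]))
  expect_true(all(unclass(m)[dn_idx[-1]] > 0))
  expect_true(all(unclass(m)[sal_idx] < 0))
})

test_that("fc_matrix is symmetric, network-ordered and null-calibrated", {
  spec <- fast_spec(frames_per_run = 5000, region_loading = 0, global_sd = 0,
                    sgacc_coloading = 0,
                    target_loading = c(dn = 0, sal = 0))
  atl <- spec$atlas
  run <- generate_bold_run(spec, 1, "none", "pre", 1)
  m <- fc_matrix(run, atl)
  expect_identical(unclass(m), t(unclass(m)))
  expect_true(all(is.na(diag(m))))
  expect_equal(dim(m), c(51L, 51L))
  # independent signals: single pairs within 3 s.e., whole matrix within
  # 4.5 s.e. (1275 pairs)
  se <- 1 / sqrt(5000 - 3)
  expect_lt(abs(m[1, 2]), 3 * se)
  expect_lt(abs(m[10, 40]), 3 * se)
  expect_lt(max(abs(m), na.rm = TRUE), 4.5 * se)
  expect_error(fc_matrix(list(), atl))
})

test_that("regions with identical signals hit the clipped maximum z", {
  atl <- nuisance_atlas()
  s <- series_mean_sd(60, 0, 1, seed = 8)
  dat <- matrix(rnorm(60 * n_units(atl)), 60)
  dat[, region_units(atl, "R1")] <- s
  dat[, region_units(atl, "R2")] <- s
  m <- fc_matrix(bold_run(dat, 1), atl)
  expect_equal(m["R1", "R2"], fisher_z(1))
})

test_that("single-region seed map equals the fc_matrix row in parcel space", {
  spec <- fast_spec(frames_per_run = 80)
  atl <- spec$atlas
  run <- generate_bold_run(spec, 2, "none", "pre", 1)
  m <- fc_matrix(run, atl)
  pt_full <- parcel_table(atl)
  ptc <- parcel_table(atl, cortical_only = TRUE)
  k <- 5
  seed_idx <- match(ptc$region[k], pt_full$region)
  sm <- seed_fc_map(run, seed_spec("region_set", units = seed_idx))
  row <- unclass(m)[k, -k]
  mapped <- unclass(sm)[match(ptc$region[-k], pt_full$region)]
  expect_equal(unname(mapped), unname(row), tolerance = 1e-12)
})

test_that("correlations are invariant to affine rescaling of a unit", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4)
  runA <- bold_run(x, 1)
  xb <- x; xb[, 2] <- 5 * xb[, 2] + 100
  runB <- bold_run(xb, 1)
  sA <- seed_fc_map(runA, seed_spec("sphere", units = 1))
  sB <- seed_fc_map(runB, seed_spec("sphere", units = 1))
  expect_equal(unclass(sA), unclass(sB), tolerance = 1e-12)
})

test_that("group FC averaging in z space is linear", {
  set.seed(9)
  maps <- lapply(1:4, function(i) rnorm(10))
  g <- average_fc(maps)
  h <- average_fc(list(average_fc(maps[1:2]), average_fc(maps[3:4])))
  expect_equal(g, h, tolerance = 1e-12)
})

test_that("voxel-space smoothing preserves means and flattens structure", {
  a <- tiny_atlas(11, 11, 1)
  v <- rep(0, n_units(a)); v[61] <- 1       # central impulse
  sm <- smooth_units(v, a, fwhm_mm = 3)
  expect_gt(sum(sm > 1e-6), 1)              # spread out
  expect_lt(max(sm), 1)
  expect_equal(smooth_units(v, a, fwhm_mm = 0), v)  # disabled = identity
  # constant field is unchanged (mask-normalised kernel)
  expect_equal(smooth_units(rep(2, n_units(a)), a, 6),
               rep(2, n_units(a)), tolerance = 1e-9)
})
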