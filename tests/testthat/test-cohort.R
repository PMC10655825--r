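test_that("cohort spec validates its inputs", {
  expect_error(fast_spec(n_subjects = 0), "n_subjects")
  expect_error(fast_spec(frames_per_run = 1), "frames_per_run")
  expect_error(fast_spec(base_corr_dn_sal = -1), "positive definite")
})

test_that("generated runs have the designed dimensions and determinism", {
  spec <- fast_spec(frames_per_run = 120, tr_seconds = 3)
  run <- generate_bold_run(spec, 1, "none", "pre", 1)
  expect_equal(nrow(run$data), 120L)
  expect_equal(run$tr_seconds, 3)
  run2 <- generate_bold_run(spec, 1, "none", "pre", 1)
  expect_identical(run$data, run2$data)
  # different run index, subject or phase changes the draw
  expect_false(identical(run$data,
                         generate_bold_run(spec, 1, "none", "pre", 2)$data))
  expect_false(identical(run$data,
                         generate_bold_run(spec, 2, "none", "pre", 1)$data))
})

test_that("empirical latent correlations converge to the design covariance", {
  spec <- fast_spec(frames_per_run = 10000, noise_sd = 0, global_sd = 0,
                    suv_noise_sd = 0)
  atl <- spec$atlas
  run <- generate_bold_run(spec, 1, "none", "pre", 1)
  pt <- parcel_table(atl)
  dn <- which(pt$network == "default" & pt$region != "DN_dlPFC")
  sal <- which(pt$network == "salience" & pt$region != "SAL_dlPFC")
  r <- cor(rowMeans(run$data[, dn]), rowMeans(run$data[, sal]))
  expect_lt(abs(r - (-0.4)), 0.03)
  # post-TMS covariance shift is realised
  prof <- netstim:::subject_profile(spec, 1)
  post <- generate_bold_run(spec, 1, "DN-TMS", "post", 1)
  r2 <- cor(rowMeans(post$data[, dn]), rowMeans(post$data[, sal]))
  expect_lt(abs(r2 - (-0.4 + prof$shift[["DN-TMS"]])), 0.03)
})

test_that("zero loading yields null pairwise correlations", {
  spec <- fast_spec(frames_per_run = 3000, region_loading = 0, global_sd = 0,
                    sgacc_coloading = 0, target_loading = c(dn = 0, sal = 0))
  run <- generate_bold_run(spec, 1, "none", "pre", 1)
  z <- fisher_z(cor(run$data[, c(1, 10, 25, 40)]))
  offd <- z[upper.tri(z)]
  expect_true(all(abs(offd) < 4 / sqrt(3000 - 3)))  # 6 pairs jointly
})

test_that("cohort generation is reproducible and counter-balanced", {
  spec <- fast_spec(n_subjects = 5, frames_per_run = 20)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$subjects[[3]]$`DN-TMS`$post[[2]]$data,
                   c2$subjects[[3]]$`DN-TMS`$post[[2]]$data)
  tab <- table(c1$ground_truth$first_condition)
  expect_lte(abs(tab[["SAL-TMS"]] - tab[["DN-TMS"]]), 1)
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
})

test_that("written cohorts are byte-identical across identical seeds", {
  spec <- fast_spec(n_subjects = 1, frames_per_run = 8, runs_per_session = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  sums1 <- unname(tools::md5sum(file.path(d1, f1)))
  sums2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(sums1, sums2)
  # and a voxel-space BOLD run survives the disk round trip
  vspec <- fast_spec(n_subjects = 1, frames_per_run = 8,
                     runs_per_session = 1, space = "voxel")
  run <- generate_bold_run(vspec, 1, "none", "pre", 1)
  stem <- file.path(d1, "roundtrip")
  write_bold_run(run, vspec$atlas, stem)
  back <- load_bold_run(stem, vspec$atlas)
  expect_equal(back$data, unname(run$data), tolerance = 1e-6)
  expect_equal(back$tr_seconds, run$tr_seconds)
})

test_that("ground truth predicts injected metabolic deltas", {
  spec <- fast_spec(n_subjects = 4, suv_noise_sd = 0)
  gt <- generate_cohort(spec)$ground_truth
  for (s in 1:4) {
    tg <- subject_targets(spec, s)
    d <- roi_mean_excluding(normalize_wbn(generate_suv_session(spec, s, "SAL-TMS")),
                            tg$sal) -
      roi_mean_excluding(normalize_wbn(generate_suv_session(spec, s, "none")),
                         tg$sal)
    expect_equal(d, gt$delta_sal[s], tolerance = 1e-9)
  }
})

test_that("disabled coupling gives independent metabolic and FC deltas", {
  spec <- fast_spec(n_subjects = 50)
  expect_true(all(spec$design$w == 0))
  gt <- generate_cohort(spec)$ground_truth
  # with w = 0 the injected deltas and shifts share no factor
  expect_lt(abs(cor(gt$delta_sal, gt$shift_sal)), 3 / sqrt(50))
})

test_that("the coupling design solves the measured-correlation closed form", {
  spec <- cohort_spec(n_subjects = 2, space = "parcel")
  des <- spec$design
  for (cc in c("SAL-TMS", "DN-TMS")) {
    expect_equal(des$realized_rho[[cc]],
                 min(1, des$w[[cc]]) * des$Dx * des$Dy[[cc]],
                 tolerance = 1e-9)
    expect_lte(des$w[[cc]], 1)
  }
  # the realized measured coupling never exceeds the designed value and
  # attains it exactly whenever the reliability budget allows (w < 1)
  expect_true(all(des$realized_rho <= spec$coupling_rho + 1e-9))
  for (cc in c("SAL-TMS", "DN-TMS"))
    if (des$w[[cc]] < 1)
      expect_equal(des$realized_rho[[cc]], spec$coupling_rho)
  # at a high-reliability acquisition the designed value is attainable
  spec_hi <- cohort_spec(n_subjects = 2, space = "parcel",
                         frames_per_run = 1000)
  expect_equal(unname(spec_hi$design$realized_rho), c(0.7, 0.7),
               tolerance = 1e-9)
  # the population model matches the analytic raw correlation when no
  # nuisance structure is present
  expect_equal(des$base_pair_z < 0, TRUE)
})
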