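test_that("tSNR matches closed form on constructed runs", {
  # single slice with slice-mean series of mean 100 and sd 10 -> tSNR 10
  s <- series_mean_sd(50, 100, 10)
  run <- bold_run(cbind(s, s), tr_seconds = 3, slice = c(1, 1))
  expect_equal(as.numeric(compute_tsnr(run)), 10, tolerance = 1e-12)

  # two slices with slice tSNR 8 and 12 -> run tSNR 10
  a <- series_mean_sd(50, 80, 10, seed = 2)   # tSNR 8
  b <- series_mean_sd(50, 120, 10, seed = 3)  # tSNR 12
  run2 <- bold_run(cbind(a, b), tr_seconds = 3, slice = c(1, 2))
  expect_equal(as.numeric(compute_tsnr(run2)), 10, tolerance = 1e-12)

  # analytic construction with arbitrary per-slice mean/sd
  ms <- c(90, 110, 130); sds <- c(5, 10, 20)
  dat <- sapply(1:3, function(i) series_mean_sd(80, ms[i], sds[i], seed = i))
  run3 <- bold_run(dat, tr_seconds = 3, slice = 1:3)
  expect_equal(as.numeric(compute_tsnr(run3)), mean(ms / sds),
               tolerance = 1e-12)

  # constant slice contributes +Inf; all-constant run errors
  run4 <- bold_run(cbind(a, rep(5, 50)), tr_seconds = 3, slice = c(1, 2))
  expect_true(is.infinite(compute_tsnr(run4)))
  expect_equal(attr(compute_tsnr(run4), "degenerate_slices"), "2")
  run5 <- bold_run(cbind(rep(1, 10), rep(2, 10)), tr_seconds = 3)
  expect_error(compute_tsnr(run5), "degenerate")
})

test_that("relative motion converts rotations on a 50 mm sphere", {
  m <- zero_motion(3)
  m$trans_x <- c(0, 3, 3); m$rot_y <- c(0, 0, 4 / 50)
  expect_equal(relative_motion(m), c(3, 4))
})

test_that("qc_run applies the tSNR and strict motion thresholds", {
  mk_run <- function(tsnr, n_big_moves, n = 60) {
    s <- series_mean_sd(n, tsnr, 1)
    m <- zero_motion(n)
    if (n_big_moves > 0) {                 # n_big_moves persistent 0.6 mm steps
      step <- rep(0, n)
      step[seq_len(n_big_moves) * 3] <- 0.6
      m$trans_x <- cumsum(step)
    }
    bold_run(cbind(s, s), tr_seconds = 3, motion = m)
  }
  # tSNR 89 with group mean 100 sd 5 -> threshold 90 -> excluded
  r <- qc_run(mk_run(89, 0), 100, 5)
  expect_true(r$excluded)
  expect_match(r$reasons, "tSNR", all = FALSE)
  # exactly five movements > 0.5 mm is retained ("more than five" is strict)
  expect_false(qc_run(mk_run(100, 5), 100, 5)$excluded)
  # six movements > 0.5 mm is excluded
  r6 <- qc_run(mk_run(100, 6), 100, 5)
  expect_true(r6$excluded)
  expect_equal(r6$n_moves_gt_0p5mm, 6L)
  expect_gte(r6$n_moves_gt_0p1mm, 6L)
  # motion table length mismatch errors at construction
  expect_error(bold_run(matrix(rnorm(20), 10), 3, motion = zero_motion(9)),
               "frame count")
})

test_that("qc decisions depend only on the run and fixed group statistics", {
  runs <- lapply(1:5, function(i) {
    s <- series_mean_sd(40, 90 + 5 * i, 1, seed = i)
    bold_run(cbind(s, s), tr_seconds = 3, motion = zero_motion(40))
  })
  dec1 <- vapply(runs, function(r) qc_run(r, 100, 5)$excluded, logical(1))
  dec2 <- vapply(rev(runs), function(r) qc_run(r, 100, 5)$excluded, logical(1))
  expect_equal(dec1, rev(dec2))
})

test_that("stimulation protocol totals reproduce the study arithmetic", {
  # 20 Hz, 40 pulses/train, 28 s ITI, 45 trains -> 1800 pulses, 22.5 min
  tot <- protocol_totals(stim_protocol(20, 40, 28, 45))
  expect_identical(tot$total_pulses, 1800L)
  expect_equal(tot$total_seconds, 1350)       # 22.5 min
  expect_equal(protocol_totals(stim_protocol(20, 40, 28, 1)),
               list(total_pulses = 40L, total_seconds = 30))
  expect_equal(protocol_totals(stim_protocol(10, 30, 20, 10)),
               list(total_pulses = 300L, total_seconds = 230))
  expect_error(stim_protocol(0, 40, 28, 45), "positive")
})

test_that("protocol totals are linear in the number of trains", {
  base <- protocol_totals(stim_protocol(20, 40, 28, 1))
  for (k in c(2, 7, 45)) {
    tot <- protocol_totals(stim_protocol(20, 40, 28, k))
    expect_equal(tot$total_pulses, base$total_pulses * k)
    expect_equal(tot$total_seconds, base$total_seconds * k)
  }
})
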