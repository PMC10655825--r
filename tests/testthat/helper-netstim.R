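# Shared fixtures, built in code.

# single-region atlas on an isotropic grid (label 1 everywhere)
tiny_atlas <- function(nx = 5, ny = 5, nz = 5, voxel = 1, origin = c(0, 0, 0)) {
  vol <- array(1L, c(nx, ny, nz))
  atlas(vol, voxel_size_mm = rep(voxel, 3), origin_mm = origin,
        region_table = data.frame(label = 1L, region = "R1", network = "A"),
        networks = "A")
}

# two cortical regions + white matter + ventricles, for nuisance regression
nuisance_atlas <- function() {
  vol <- array(0L, c(9, 3, 3))
  vol[1:2, , ] <- 1L; vol[3:4, , ] <- 2L; vol[5:6, , ] <- 3L; vol[7:8, , ] <- 4L
  atlas(vol, voxel_size_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
        region_table = data.frame(
          label = 1:4,
          region = c("R1", "R2", "white_matter", "ventricles"),
          network = c("A", "B", "white_matter", "ventricles")),
        networks = c("A", "B"))
}

zero_motion <- function(n) {
  as.data.frame(matrix(0, n, 6, dimnames = list(
    NULL, c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z"))))
}

# series with exact sample mean and sd
series_mean_sd <- function(n, mean, sd, seed = 1) {
  x <- withr::with_seed(seed, stats::rnorm(n))
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}

# small, fast cohort spec (no coupling calibration)
fast_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 3, frames_per_run = 60, space = "parcel",
                   coupling_rho = 0, rng_seed = 42)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}
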