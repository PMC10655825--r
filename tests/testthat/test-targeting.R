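test_that("node grids tile a mask at the requested spacing", {
  a <- tiny_atlas(11, 11, 1, voxel = 1)
  g <- build_node_grid(a, seq_len(n_units(a)), spacing_mm = 5,
                       node_radius_mm = 2)
  expect_equal(nrow(g$centers), 9L)            # 3 x 3 lattice on 11x11x1 mm
  expect_true(all(lengths(g$units) >= 1L))
  expect_error(build_node_grid(a, integer(0), 5), "empty")
  # default geometry: 4 mm diameter nodes
  expect_equal(formals(build_node_grid)$node_radius_mm, 2)
  g2 <- build_node_grid(synthetic_atlas(), dlpfc_mask(synthetic_atlas()))
  expect_equal(g2$radius_mm, 2)
  expect_equal(g2$spacing_mm, 4)
})

# five-node line atlas with a separate seed region, for engineered runs
line_fixture <- function() {
  vol <- array(0L, c(9, 1, 1))
  vol[1:5, 1, 1] <- 1L            # dlPFC strip
  vol[8, 1, 1] <- 2L              # seed voxel
  atl <- atlas(vol, c(1, 1, 1), c(0, 0, 0),
               data.frame(label = 1:2, region = c("strip", "seedreg"),
                          network = c("A", "B")),
               networks = c("A", "B"))
  grid <- build_node_grid(atl, region_units(atl, "strip"), spacing_mm = 1,
                          node_radius_mm = 0.4)
  list(atl = atl, grid = grid)
}

test_that("derive_targets takes the extrema with lowest-id tie-breaks", {
  fx <- line_fixture()
  set.seed(13)
  s <- rnorm(100)
  mk_run <- function(node_series) {
    dat <- matrix(rnorm(600, sd = 1), 100, 6)
    dat[, 1:5] <- node_series
    dat[, 6] <- s
    bold_run(dat, tr_seconds = 1)
  }
  w <- c(rep(0, 5), 1)                         # map-weighted seed off-mask
  seed <- seed_spec("map_weighted", weights = w)
  # node values ~ (0.5, -0.3, 0.1, noise, noise)
  run <- mk_run(cbind(0.6 * s + rnorm(100, sd = 0.9),
                      -0.4 * s + rnorm(100, sd = 0.9),
                      0.1 * s + rnorm(100),
                      rnorm(100), rnorm(100)))
  tp <- derive_targets(run, seed, fx$grid)
  expect_equal(tp$dn_target$node_id, 1L)
  expect_equal(tp$sal_target$node_id, 2L)
  expect_gt(tp$dn_target$fc_value, tp$sal_target$fc_value)
  expect_equal(tp$separation_mm,
               target_distance(fx$grid$centers[1, ], fx$grid$centers[2, ]))
  # exact tie between nodes 1 and 3: lowest node id wins
  run2 <- mk_run(cbind(s, -s, s, -s, rnorm(100)))
  tp2 <- derive_targets(run2, seed, fx$grid)
  expect_equal(tp2$dn_target$node_id, 1L)
  expect_equal(tp2$sal_target$node_id, 2L)
  # seed weights inside the grid mask are rejected
  expect_error(derive_targets(run, seed_spec("map_weighted",
                                             weights = c(1, rep(0, 4), 1)),
                              fx$grid), "exclude")
  # constant node values are ambiguous
  run3 <- mk_run(matrix(rep(s, 5), 100))
  expect_error(derive_targets(run3, seed, fx$grid), "ambiguous")
})

test_that("derive_targets recovers ground-truth nodes on synthetic subjects", {
  spec <- fast_spec(n_subjects = 2, space = "voxel", frames_per_run = 120)
  atl <- spec$atlas
  grid <- spec$grid
  for (s in 1:2) {
    prof <- netstim:::subject_profile(spec, s)
    runs <- lapply(1:3, function(r)
      denoise_run(generate_bold_run(spec, s, "none", "pre", r), atl))
    sg <- seed_spec("region_set", units = region_units(atl, "sgACC"))
    w <- unclass(average_fc(lapply(runs, seed_fc_map, seed = sg)))
    w[dlpfc_mask(atl)] <- 0
    tp <- derive_targets(runs, seed_spec("map_weighted", weights = w), grid)
    expect_equal(tp$dn_target$node_id, prof$dn_node)
    expect_equal(tp$sal_target$node_id, prof$sal_node)
    expect_gt(tp$dn_target$fc_value, 0)
    expect_lt(tp$sal_target$fc_value, 0)
  }
})

test_that("network identity is confirmed from whole-network time courses", {
  spec <- fast_spec(n_subjects = 1, space = "voxel", frames_per_run = 120)
  atl <- spec$atlas
  prof <- netstim:::subject_profile(spec, 1)
  runs <- lapply(1:3, function(r)
    denoise_run(generate_bold_run(spec, 1, "none", "pre", r), atl))
  id_dn <- confirm_network_identity(runs, spec$grid$centers[prof$dn_node, ],
                                    atl)
  expect_equal(id_dn$network, "default")
  id_sal <- confirm_network_identity(runs, spec$grid$centers[prof$sal_node, ],
                                     atl)
  expect_equal(id_sal$network, "salience")
  expect_named(id_dn$z, atl$networks)
  # a pure-noise site has near-null z everywhere and is flagged ambiguous
  # (long runs so the null s.e. is well below the 0.05 ambiguity margin)
  spec0 <- fast_spec(n_subjects = 1, space = "voxel", frames_per_run = 2000,
                     target_loading = c(dn = 0, sal = 0))
  runs0 <- lapply(1:3, function(r)
    denoise_run(generate_bold_run(spec0, 1, "none", "pre", r), spec0$atlas)
  )
  id0 <- confirm_network_identity(runs0, spec0$grid$centers[1, ], spec0$atlas)
  expect_true(id0$ambiguous)
  expect_lt(max(abs(id0$z)), 0.1)
  suppressWarnings(
    expect_error(confirm_network_identity(runs, c(999, 999, 999), atl)))
})

test_that("reverse seed maps recapitulate the stimulated network", {
  spec <- fast_spec(n_subjects = 1, space = "voxel", frames_per_run = 120)
  atl <- spec$atlas
  prof <- netstim:::subject_profile(spec, 1)
  run <- denoise_run(generate_bold_run(spec, 1, "none", "pre", 1), atl)
  m <- reverse_seed_map(run, spec$grid$centers[prof$dn_node, ], atl)
  dn_units <- network_units(atl, "default", exclude_regions = "DN_dlPFC")
  sal_units <- network_units(atl, "salience", exclude_regions = "SAL_dlPFC")
  expect_gt(mean(unclass(m)[dn_units]), 0)
  expect_lt(mean(unclass(m)[sal_units]), 0)
  # single-unit target equals the unit-seeded map
  u1 <- sphere_units(atl, unit_coords(atl)[1, ], 0.1)
  m1 <- reverse_seed_map(run, unit_coords(atl)[1, ], atl, radius_mm = 0.1)
  m2 <- seed_fc_map(run, seed_spec("sphere", units = u1))
  expect_equal(as.numeric(m1), as.numeric(m2))
})
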