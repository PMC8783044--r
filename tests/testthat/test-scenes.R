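# a compact spec whose whole protrusion solid fits well inside the grid,
# at the fine isotropic-lateral voxel size used for membership oracles
membership_spec <- function(radius = 0.5, length = 2.0) {
  scene_spec(grid_shape = c(30L, 70L, 60L), voxel_size = c(0.1, 0.1, 0.1),
             ac_center = c(ap = 3.0, dv = 1.2, z = 1.5),
             ac_radii = c(ap = 1.0, dv = 0.8, z = 0.8),
             bm_y = 2.4, bm_gap = list(center = 3.0, width = 1.2),
             protrusion = list(present = TRUE, radius = radius, length = length),
             landmarks = list(vulA1 = c(0.5, 2.6), vulA2 = c(5.5, 2.6),
                              ac_edge_1 = c(2.2, 1.4), ac_edge_2 = c(3.8, 1.4),
                              vulF_mid = c(3.0, 2.2)))
}

test_that("ground-truth protrusion volume equals brute-force voxel-centre counting", {
  spec <- membership_spec(radius = 0.5, length = 2.0)
  b <- build_scene(spec)
  expect_equal(b$truth$true_volume_trace$volume_um3,
               brute_protrusion_voxels(spec) * 0.001)
  # and for a second geometry
  spec2 <- membership_spec(radius = 0.3, length = 1.2)
  expect_equal(build_scene(spec2)$truth$true_volume_trace$volume_um3,
               brute_protrusion_voxels(spec2) * 0.001)
})

test_that("a scene without protrusion has zero true volume", {
  spec <- preset_scene("default", protrusion = list(present = FALSE))
  b <- build_scene(spec)
  expect_equal(b$truth$true_volume_trace$volume_um3, 0)
})

test_that("inconsistent and invalid specs are rejected with informative errors", {
  expect_error(preset_scene("default",
                            bm_gap = list(center = 6, width = 0)),
               "cannot cross an intact BM")
  expect_error(preset_scene("default",
                            landmarks = list(vulA1 = c(1.5, 4.6),
                                             vulA2 = c(1e4, 4.6),
                                             ac_edge_1 = c(4.8, 3.0),
                                             ac_edge_2 = c(7.2, 3.0),
                                             vulF_mid = c(6.0, 4.2))),
               "vulA2")
  expect_error(scene_spec(n_frames = 0), "n_frames")
  expect_error(scene_spec(ac_radii = c(ap = -1, dv = 1, z = 1)), "semi-axes")
})

test_that("rendering is deterministic for a fixed spec and seed", {
  spec <- preset_scene("dynamics", seed = 7)
  b <- build_scene(spec)
  o1 <- render_stack(b, spec)
  o2 <- render_stack(b, spec)
  expect_identical(o1$ac$values, o2$ac$values)
  expect_identical(o1$bm$values, o2$bm$values)
  o3 <- render_stack(b, preset_scene("dynamics", seed = 8))
  expect_false(identical(o1$ac$values, o3$ac$values))
})

test_that("zero noise and a near-delta PSF reproduce the scene up to quantization", {
  spec <- preset_scene("dynamics",
                       noise = list(photon_scale = 0, gain = 16000, read_sd = 0),
                       psf_sigma = c(lateral = 1e-4, axial = 1e-4))
  b <- build_scene(spec)
  obs <- render_stack(b, spec)
  expect_lt(max(abs(obs$ac$values / 16000 - b$scene$ac$values)), 1 / 16000)
})

test_that("camera noise follows the gain * mean + read variance law and Poisson scaling", {
  # a big uniform AC interior provides the uniform patch
  patch_stats <- function(photon_scale) {
    # z semi-axis far beyond the grid: a through-depth slab whose interior is
    # uniform within every z-slice even after axial blur
    spec <- preset_scene("dynamics",
                         ac_radii = c(ap = 2.2, dv = 1.9, z = 50),
                         protrusion = list(present = FALSE),
                         ac_focus = list(present = FALSE),
                         noise = list(photon_scale = photon_scale, gain = 2,
                                      read_sd = 3))
    obs <- render_stack(build_scene(spec), spec)
    patch <- obs$ac$values[4, 14:34, 22:42]  # interior, away from edges
    c(m = mean(patch), v = var(as.numeric(patch)))
  }
  s1 <- patch_stats(2000)
  expect_equal(s1[["v"]], 2 * s1[["m"]] + 9, tolerance = 0.1)
  s4 <- patch_stats(8000)
  rel1 <- sqrt(s1[["v"]]) / s1[["m"]]
  rel4 <- sqrt(s4[["v"]]) / s4[["m"]]
  expect_equal(rel1 / rel4, 2, tolerance = 0.15)
})

test_that("a static series yields identical frames and linear growth a rising trace", {
  quiet <- list(photon_scale = 0, gain = 16000, read_sd = 0)
  spec <- preset_scene("dynamics", n_frames = 3, noise = quiet)
  sim <- simulate_timeseries(spec)
  expect_identical(sim$frames[[1]]$ac$values, sim$frames[[3]]$ac$values)
  expect_true(all(diff(sim$truth$true_volume_trace$volume_um3) == 0))

  grow <- preset_scene("protrusion", n_frames = 4, noise = quiet,
                       protrusion = list(length = 0.4, growth = 0.02))
  simg <- simulate_timeseries(grow)
  expect_true(all(diff(simg$truth$true_volume_trace$volume_um3) > 0))
})

test_that("fixtures round-trip exactly through TIFF + JSON sidecar", {
  spec <- preset_scene("dynamics", seed = 3)
  b <- build_scene(spec)
  obs <- render_stack(b, spec)
  path <- withr::local_tempdir()
  write_fixture(obs, b$truth, path, spec = spec)
  back <- read_fixture(path)
  expect_identical(back$frames[[1]]$ac$values, obs$ac$values)
  expect_identical(back$frames[[1]]$bm$values, obs$bm$values)
  expect_equal(back$spec$bm_gap$width, spec$bm_gap$width)
  expect_equal(back$spec$seed, spec$seed)
  expect_equal(back$truth$true_R_A, b$truth$true_R_A)

  # multi-frame round trip
  sim <- simulate_timeseries(preset_scene("dynamics", n_frames = 3, seed = 4))
  path2 <- withr::local_tempdir()
  write_fixture(sim$frames, sim$truth, path2)
  back2 <- read_fixture(path2)
  expect_identical(back2$frames[[3]]$ac$values, sim$frames[[3]]$ac$values)

  # missing sidecar is a stated no-ground-truth condition, not a failure
  file.remove(file.path(path2, "truth.json"))
  expect_message(nogt <- read_fixture(path2), "no ground truth")
  expect_null(nogt$truth)
})
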