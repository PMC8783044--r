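# a bare ridge grid: sheet at height h(x) on a (nz, ny, nx) grid, no optics
ridge_grid <- function(hfun, d = c(3, 40, 50), vs = c(0.5, 0.1, 0.1),
                       intensity = rep(1, d[3])) {
  a <- array(0, d)
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  for (j in seq_len(d[3])) {
    x <- (j - 0.5) * vs[3]
    a[, which.min(abs(yc - hfun(x))), j] <- intensity[j]
  }
  voxel_grid(a, vs)
}

test_that("BM surface extraction recovers flat and tilted sheets", {
  flat <- ridge_grid(function(x) 2.0)
  surf <- extract_bm_surface(flat)
  expect_true(all(surf$height_um == surf$height_um[1]))
  expect_equal(surf$height_um[1], 1.95)  # voxel centre nearest 2.0 um

  tilt <- ridge_grid(function(x) 1.0 + 0.4 * x)
  st <- extract_bm_surface(tilt)
  expect_lte(max(abs(st$height_um - (1.0 + 0.4 * st$ap_um))), 0.05 + 1e-9)

  expect_error(extract_bm_surface(voxel_grid(array(0, c(2, 4, 4)), c(1, 1, 1))),
               "no BM signal")
})

test_that("breach detection finds rendered gaps at their true extent and ignores sub-threshold ones", {
  intact <- detect_breach(extract_bm_surface(ridge_grid(function(x) 2.0)))
  expect_false(intact$breached)
  expect_equal(nrow(intact$gaps), 0)

  gap3 <- function(x) as.numeric(abs(x - 4.0) >= 1.5)  # 3 um zero-intensity gap
  g <- ridge_grid(function(x) 2.0, d = c(3, 40, 80),
                  intensity = gap3((seq_len(80) - 0.5) * 0.1))
  res <- detect_breach(extract_bm_surface(g))
  expect_true(res$breached)
  expect_lte(abs(res$gap_extent_um - 3.0), 0.1)  # within one column

  half <- function(x) as.numeric(abs(x - 2.5) >= 0.25)  # 0.5 um gap
  h <- ridge_grid(function(x) 2.0,
                  intensity = half((seq_len(50) - 0.5) * 0.1))
  expect_false(detect_breach(extract_bm_surface(h), min_gap_um = 1.0)$breached)
})

test_that("protrusion volume is the voxel count times the voxel volume", {
  surf <- extract_bm_surface(ridge_grid(function(x) 2.0,
                                        d = c(12, 40, 50),
                                        vs = c(0.25, 0.1, 0.1)))
  mask <- array(FALSE, c(12, 40, 50))
  mask[2:11, 25:34, 11:20] <- TRUE  # 1000 voxels, all ventral of y = 2.0
  out <- protrusion_volume(mask, surf, voxel_size = c(0.25, 0.1, 0.1))
  expect_equal(out$n_voxels, 1000L)
  expect_equal(out$volume_um3, 2.5)

  none <- protrusion_volume(array(FALSE, c(12, 40, 50)), surf,
                            voxel_size = c(0.25, 0.1, 0.1))
  expect_equal(none$volume_um3, 0)
  expect_match(none$note, "no candidate")

  # voxels dorsal of the surface never count
  dorsal_only <- array(FALSE, c(12, 40, 50)); dorsal_only[5, 1:15, 20] <- TRUE
  expect_equal(protrusion_volume(dorsal_only, surf,
                                 voxel_size = c(0.25, 0.1, 0.1))$volume_um3, 0)
})

test_that("component selection honours seeds and 26-connectivity", {
  surf <- extract_bm_surface(ridge_grid(function(x) 1.0))
  mask <- array(FALSE, c(3, 40, 50))
  mask[2, 20:29, 5:9] <- TRUE     # 50-voxel component
  mask[2, 20:24, 40:42] <- TRUE   # 15-voxel component
  big <- protrusion_volume(mask, surf, voxel_size = c(0.5, 0.1, 0.1))
  expect_equal(big$n_voxels, 50L)
  small <- protrusion_volume(mask, surf, seed = c(2, 22, 41),
                             voxel_size = c(0.5, 0.1, 0.1))
  expect_equal(small$n_voxels, 15L)
  expect_error(protrusion_volume(mask, surf, seed = c(1, 1, 1),
                                 voxel_size = c(0.5, 0.1, 0.1)),
               "not in any")
  # a diagonal-only bridge keeps a component connected under 26-connectivity
  diagm <- array(FALSE, c(4, 30, 30))
  diagm[2, 20, 10] <- TRUE; diagm[3, 21, 11] <- TRUE; diagm[2, 22, 12] <- TRUE
  dres <- protrusion_volume(diagm, surf, voxel_size = c(0.5, 0.1, 0.1))
  expect_equal(dres$n_voxels, 3L)
})

test_that("volume is monotone under mask inclusion", {
  surf <- extract_bm_surface(ridge_grid(function(x) 1.0))
  set.seed(99)
  for (i in 1:10) {
    a <- array(runif(3 * 40 * 50) < 0.05, c(3, 40, 50))
    extra <- array(runif(3 * 40 * 50) < 0.05, c(3, 40, 50))
    b <- a | extra
    va <- protrusion_volume(a, surf, voxel_size = c(0.5, 0.1, 0.1))$volume_um3
    vb <- protrusion_volume(b, surf, voxel_size = c(0.5, 0.1, 0.1))$volume_um3
    expect_lte(va, vb)
  }
})

test_that("volume estimates are invariant under AP translation of the scene", {
  shift_um <- 0.5
  base <- preset_scene("protrusion", seed = 5,
                       noise = list(photon_scale = 0, gain = 16000, read_sd = 0))
  lm_sh <- lapply(base$landmarks, function(p) p + c(shift_um, 0))
  shifted <- preset_scene("protrusion", seed = 5,
                          noise = list(photon_scale = 0, gain = 16000,
                                       read_sd = 0),
                          ac_center = base$ac_center + c(ap = shift_um, dv = 0, z = 0),
                          bm_gap = list(center = base$bm_gap$center + shift_um),
                          landmarks = lm_sh)
  psf <- psf_model(0.15, 0.4)
  v1 <- measure_protrusion(render_stack(build_scene(base), base), psf,
                           bm_search_band(base))$volume_um3
  v2 <- measure_protrusion(render_stack(build_scene(shifted), shifted), psf,
                           bm_search_band(shifted))$volume_um3
  expect_equal(v1, v2)
})

test_that("protrusion traces recover growth rates and flag short windows", {
  tm <- seq(0, 90, by = 5)
  flat <- protrusion_trace(rep(2, length(tm)) + rnorm(length(tm), 0, 1e-3),
                           tm, 0, 90)
  expect_equal(flat$growth_rate_um3_min, 0, tolerance = 1e-3)

  lin <- protrusion_trace(1 + 0.05 * tm, tm, 0, 90)
  expect_equal(lin$growth_rate_um3_min, 0.05)

  short <- protrusion_trace(c(1, 2, 3), c(0, 50, 100), 0, 90)
  expect_true(is.na(short$growth_rate_um3_min))
  expect_match(short$flag, "fewer than 3")

  expect_error(protrusion_trace(c(1, 2), c(5, 5), 0), "increasing")
  expect_error(protrusion_trace(c(1, 2), c(0, 5), 100), "outside")
  agg <- aggregate_traces(list(lin, lin))
  expect_equal(agg$mean_um3, 1 + 0.05 * tm)
  expect_true(all(agg$sd_um3 == 0))
})
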