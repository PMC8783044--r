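#' Canonical desk-scale scene presets
#'
#' Ready-made [scene_spec()]s for the standard simulation studies shipped with
#' the package. All presets use desk-scale grids so that whole cohorts can be
#' simulated in seconds on one CPU:
#'
#' * `"default"` — the full two-channel L4.0 vulval-region scene
#'   (16 x 64 x 120 voxels at 0.25/0.1/0.1 um) with AC, protrusion, BM gap and
#'   all five junction landmarks; used for landmark detection and alignment
#'   recovery.
#' * `"protrusion"` — protrusion-volumetry geometry at the coarser 0.5 um z
#'   spacing used for protrusion time-lapse stacks (8 x 64 x 96 voxels); its
#'   second channel is a pure laminin reporter (no junction punctae).
#' * `"dynamics"` — compact AC-shape series geometry at 0.25 um z spacing
#'   (8 x 48 x 64 voxels) for correlation-index studies.
#' * `"bm-sheet"` — pure laminin-reporter sheet (no punctae, no protrusion)
#'   for breach-detection studies; set `gap_width` to 0 for an intact sheet.
#'
#' @param type preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [scene_spec()] (e.g. `deform_amplitude`,
#'   `n_frames`, `protrusion`).
#' @param gap_width BM gap width for the `"bm-sheet"` preset, um.
#' @return a [scene_spec()].
#' @export
preset_scene <- function(type = c("default", "protrusion", "dynamics",
                                  "bm-sheet"),
                         seed = 1L, ..., gap_width = 2.0) {
  type <- match.arg(type)
  args <- switch(type,
    "default" = list(),
    "protrusion" = list(
      grid_shape = c(8L, 64L, 96L), voxel_size = c(0.5, 0.1, 0.1),
      ac_center = c(ap = 4.8, dv = 2.8, z = 2.0),
      bm_gap = list(center = 4.8, width = 2.0),
      intensity = list(punctae = 0),  # laminin reporter only in channel 2
      landmarks = list(vulA1 = c(1.0, 4.6), vulA2 = c(8.6, 4.6),
                       ac_edge_1 = c(3.6, 3.0), ac_edge_2 = c(6.0, 3.0),
                       vulF_mid = c(4.8, 4.2)),
      frame_interval = 300),
    "dynamics" = list(
      grid_shape = c(8L, 48L, 64L), voxel_size = c(0.25, 0.1, 0.1),
      ac_center = c(ap = 3.2, dv = 2.4, z = 1.0),
      ac_radii = c(ap = 1.2, dv = 1.0, z = 0.8),
      bm_y = 3.8, bm_gap = list(center = 3.2, width = 1.6),
      landmarks = list(vulA1 = c(0.8, 4.0), vulA2 = c(5.6, 4.0),
                       ac_edge_1 = c(2.4, 2.6), ac_edge_2 = c(4.0, 2.6),
                       vulF_mid = c(3.2, 3.6)),
      frame_interval = 30),
    "bm-sheet" = list(
      grid_shape = c(8L, 48L, 80L), voxel_size = c(0.5, 0.1, 0.1),
      ac_center = c(ap = 4.0, dv = 2.4, z = 2.0),
      ac_radii = c(ap = 1.2, dv = 1.0, z = 0.8),
      bm_y = 3.8, bm_gap = list(center = 4.0, width = gap_width),
      protrusion = list(present = FALSE),
      intensity = list(punctae = 0),
      landmarks = list(vulA1 = c(1.0, 4.0), vulA2 = c(7.0, 4.0),
                       ac_edge_1 = c(3.2, 2.6), ac_edge_2 = c(4.8, 2.6),
                       vulF_mid = c(4.0, 3.6))))
  args <- utils::modifyList(args, list(seed = seed, ...))
  do.call(scene_spec, args)
}

#' DV search band for BM surface extraction of a preset scene
#'
#' The band brackets the sheet position, excluding the AC body dorsally and
#' the image border ventrally.
#'
#' @param spec a [scene_spec()].
#' @param half_width band half-width, um.
#' @return `(min, max)` DV band in um.
#' @export
bm_search_band <- function(spec, half_width = 0.4) {
  c(spec$bm_y - half_width, spec$bm_y + half_width)
}
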