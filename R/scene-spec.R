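#' Specify a synthetic two-channel imaging scene
#'
#' A `scene_spec` describes the ground-truth geometry and acquisition model of
#' a synthetic vulval-region stack: an ellipsoidal anchor-cell (AC) body with
#' an optional ventral invasive protrusion in channel 1, and a thin
#' basement-membrane (BM) sheet with a gap plus punctate junction landmarks in
#' channel 2, blurred by a Gaussian PSF and corrupted by photon and read
#' noise.
#'
#' Geometry follows the package-wide convention: arrays are `(z, y, x)`, the
#' AP axis is `x` (anterior at low `x`) and the DV axis is `y` with ventral at
#' high `y`. All positions and sizes are in micrometres.
#'
#' Defaults emulate a mid-L4.0 vulval region imaged at 60x: a ~12 um AP field,
#' 0.1 um lateral pixels, 0.25 um z spacing, an AC of ~1.2-1.5 um semi-axes
#' sitting dorsal of a BM sheet with a 2 um breach, and five junction
#' landmarks (vulA1/vulA2 at the outer vulval corners, the two AC-edge
#' punctae, and the mid-vulF point).
#'
#' @param grid_shape integer `(nz, ny, nx)` voxels.
#' @param voxel_size `(dz, dy, dx)` um.
#' @param ac_center AC centre as `(ap, dv, z)` um.
#' @param ac_radii AC ellipsoid semi-axes `(ap, dv, z)` um.
#' @param protrusion list: `present`, `radius` (stalk radius, um), `length`
#'   (stalk length ventral of the BM, um), `growth` (um/min elongation for
#'   time series).
#' @param bm_y DV position of the BM sheet, um.
#' @param bm_gap list: `center` (AP um), `width` (um, `>= 0`).
#' @param landmarks named list of `(ap, dv)` um positions for roles
#'   `vulA1`, `vulA2`, `ac_edge_1`, `ac_edge_2`, `vulF_mid`.
#' @param ac_focus list describing the bright ventral actin focus the AC
#'   reporter concentrates into (`present`, `amplitude` relative to the AC
#'   body, `sigma` um, `offset` um dorsal of the ventral pole). The
#'   brightest-point centring of the dynamics chain relies on such a focus
#'   existing, as it does in the real reporter signal.
#' @param deform_amplitude relative amplitude of smooth AC boundary
#'   fluctuations (0 = static shape).
#' @param deform_tau correlation time of the boundary fluctuations, s.
#' @param intensity list of per-channel intensity scales: `ac`, `bm`,
#'   `punctae` (puncta peak relative to the BM sheet).
#' @param noise list: `photon_scale` (mean photoelectrons per unit intensity),
#'   `gain` (counts per photoelectron), `read_sd` (read noise s.d., counts).
#' @param psf_sigma `(lateral, axial)` um.
#' @param frame_interval frame interval, s.
#' @param n_frames number of frames (`>= 1`).
#' @param jitter_sd s.d. (voxels) of per-frame integer `(y, x)` stage jitter;
#'   0 disables jitter.
#' @param seed integer seed; the fixture's single pseudo-random stream and its
#'   per-frame sub-streams derive from it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(grid_shape = c(16L, 64L, 120L),
                       voxel_size = c(0.25, 0.1, 0.1),
                       ac_center = c(ap = 6.0, dv = 2.8, z = 2.0),
                       ac_radii = c(ap = 1.5, dv = 1.2, z = 1.2),
                       protrusion = list(present = TRUE, radius = 0.5,
                                         length = 1.0, growth = 0),
                       bm_y = 4.4,
                       bm_gap = list(center = 6.0, width = 2.0),
                       landmarks = list(
                         vulA1 = c(1.5, 4.6), vulA2 = c(10.5, 4.6),
                         ac_edge_1 = c(4.8, 3.0), ac_edge_2 = c(7.2, 3.0),
                         vulF_mid = c(6.0, 4.2)),
                       ac_focus = list(present = TRUE, amplitude = 1.5,
                                       sigma = 0.25, offset = 0.5),
                       deform_amplitude = 0,
                       deform_tau = 60,
                       intensity = list(ac = 1, bm = 1, punctae = 2),
                       noise = list(photon_scale = 8000, gain = 2, read_sd = 3),
                       psf_sigma = c(lateral = 0.15, axial = 0.4),
                       frame_interval = 30,
                       n_frames = 1L,
                       jitter_sd = 0,
                       seed = 1L) {
  # partial lists are completed from the defaults
  protrusion <- utils::modifyList(
    list(present = TRUE, radius = 0.5, length = 1.0, growth = 0), protrusion)
  bm_gap <- utils::modifyList(list(center = 6.0, width = 2.0), bm_gap)
  intensity <- utils::modifyList(list(ac = 1, bm = 1, punctae = 2), intensity)
  noise <- utils::modifyList(list(photon_scale = 8000, gain = 2, read_sd = 3),
                             noise)
  ac_focus <- utils::modifyList(
    list(present = TRUE, amplitude = 1.5, sigma = 0.25, offset = 0.5), ac_focus)
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
         ac_center = ac_center, ac_radii = ac_radii, protrusion = protrusion,
         bm_y = bm_y, bm_gap = bm_gap, landmarks = landmarks,
         ac_focus = ac_focus,
         deform_amplitude = deform_amplitude, deform_tau = deform_tau,
         intensity = intensity, noise = noise, psf_sigma = as.numeric(psf_sigma),
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("grid_shape must be three positive voxel counts (nz, ny, nx)")
    if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
    if (any(ac_radii <= 0)) stop("AC semi-axes must be strictly positive")
    if (bm_gap$width < 0) stop("bm_gap width must be >= 0")
    if (n_frames < 1L) stop("n_frames must be >= 1")
    if (deform_amplitude < 0 || deform_tau <= 0)
      stop("deformation parameters must be non-negative (tau > 0)")
    if (isTRUE(protrusion$present) && bm_gap$width <= 0)
      stop("inconsistent spec: protrusion present but the BM gap has zero ",
           "width (a protrusion cannot cross an intact BM)")
    extent <- c(ap = grid_shape[3] * voxel_size[3],
                dv = grid_shape[2] * voxel_size[2])
    for (role in names(landmarks)) {
      p <- landmarks[[role]]
      if (length(p) != 2L || any(p < 0) || p[1] > extent["ap"] ||
          p[2] > extent["dv"])
        stop(sprintf("landmark '%s' lies outside the grid", role))
    }
  })
  invisible(spec)
}

# per-frame sub-stream seed, kept below 2^31
frame_seed <- function(seed, frame) {
  (as.numeric(seed) * 48271 + frame * 1009) %% 2147483647
}
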