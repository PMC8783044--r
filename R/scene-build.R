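# coordinate arrays (um) for a (z,y,x) grid
coord_arrays <- function(grid_shape, voxel_size) {
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  zc <- axis_centers(nz, voxel_size[1])
  yc <- axis_centers(ny, voxel_size[2])
  xc <- axis_centers(nx, voxel_size[3])
  d <- c(nz, ny, nx)
  list(Z = array(rep(zc, times = ny * nx), d),
       Y = array(rep(rep(yc, each = nz), times = nx), d),
       X = array(rep(xc, each = nz * ny), d))
}

# AC ellipsoid membership with an optional smooth boundary perturbation;
# coefs: 7 mode coefficients of a low-order angular field (zero = sphere-true)
ac_membership <- function(co, spec, coefs = rep(0, 7)) {
  cx <- spec$ac_center[["ap"]]; cy <- spec$ac_center[["dv"]]
  cz <- spec$ac_center[["z"]]
  rx <- spec$ac_radii[["ap"]]; ry <- spec$ac_radii[["dv"]]
  rz <- spec$ac_radii[["z"]]
  ux <- (co$X - cx) / rx; uy <- (co$Y - cy) / ry; uz <- (co$Z - cz) / rz
  rho <- sqrt(ux^2 + uy^2 + uz^2)
  safe <- pmax(rho, 1e-9)
  ex <- ux / safe; ey <- uy / safe; ez <- uz / safe
  g <- coefs[1] * ex + coefs[2] * ey + coefs[3] * ez +
    coefs[4] * ex * ey + coefs[5] * ey * ez + coefs[6] * ex * ez +
    coefs[7] * (ex^2 - ey^2)
  rho <= 1 + g
}

# below-BM protrusion solid (stalk of length L ventral of bm_y + spherical cap);
# this solid defines the ground-truth protrusion volume
protrusion_membership <- function(co, spec, L) {
  x0 <- spec$bm_gap$center
  z0 <- spec$ac_center[["z"]]
  r <- spec$protrusion$radius
  tip <- spec$bm_y + L
  in_stalk <- co$Y >= spec$bm_y & co$Y <= tip &
    (co$X - x0)^2 + (co$Z - z0)^2 <= r^2
  in_cap <- co$Y > tip &
    (co$X - x0)^2 + (co$Y - tip)^2 + (co$Z - z0)^2 <= r^2
  in_stalk | in_cap
}

# connector between the AC body and the BM plane (same stalk radius); keeps the
# rendered protrusion attached to the cell but is dorsal of the BM, so it is
# not part of the ground-truth volume
connector_membership <- function(co, spec) {
  x0 <- spec$bm_gap$center
  z0 <- spec$ac_center[["z"]]
  r <- spec$protrusion$radius
  co$Y < spec$bm_y & co$Y >= spec$ac_center[["dv"]] &
    (co$X - x0)^2 + (co$Z - z0)^2 <= r^2
}

# BM channel: 1-voxel-thick sheet at the DV row nearest bm_y, interrupted by
# the gap, plus Gaussian junction punctae at the landmark positions
bm_channel <- function(co, spec) {
  d <- spec$grid_shape
  vals <- array(0, d)
  yc <- axis_centers(d[2], spec$voxel_size[2])
  row <- which.min(abs(yc - spec$bm_y))
  in_gap <- abs(axis_centers(d[3], spec$voxel_size[3]) - spec$bm_gap$center) <
    spec$bm_gap$width / 2
  vals[, row, !in_gap] <- spec$intensity$bm
  sig_p <- 0.15; sig_pz <- 0.3
  pz <- spec$ac_center[["z"]]
  for (p in spec$landmarks) {
    vals <- vals + spec$intensity$punctae * spec$intensity$bm *
      exp(-((co$X - p[1])^2 + (co$Y - p[2])^2) / (2 * sig_p^2) -
            (co$Z - pz)^2 / (2 * sig_pz^2))
  }
  vals
}

# alignment metrics from a set of true landmark positions (defining formulas)
truth_alignment <- function(lm) {
  mid_ac <- (lm$ac_edge_1[1] + lm$ac_edge_2[1]) / 2
  y <- abs(lm$vulA2[1] - lm$vulA1[1])
  x <- min(abs(mid_ac - lm$vulA1[1]), abs(mid_ac - lm$vulA2[1]))
  list(R_A = x / y, Delta = abs(mid_ac - lm$vulF_mid[1]))
}

#' Render the noise-free scene and its ground truth
#'
#' Builds the two-channel, noise-free intensity scene described by a
#' [scene_spec()]: channel `ac` holds the AC ellipsoid plus (when configured)
#' the ventral invasive protrusion crossing the BM through its gap; channel
#' `bm` holds the basement-membrane sheet with the gap and Gaussian punctae at
#' the junction landmark positions. The ground-truth sidecar records the true
#' below-BM protrusion volume (voxel-centre membership count times voxel
#' volume), the true landmarks and the alignment metrics they imply.
#'
#' @param spec a [scene_spec()].
#' @param deform_coefs optional 7-vector of boundary-perturbation mode
#'   coefficients (used by [simulate_timeseries()]); default zero.
#' @param protrusion_length override of the below-BM stalk length, um.
#' @return list with elements `scene` (list of two [voxel_grid()]s, `ac` and
#'   `bm`) and `truth` (list: `true_volume_trace`, `true_landmarks`,
#'   `true_R_A`, `true_Delta`, `true_breached`, `applied_shifts`).
#' @export
build_scene <- function(spec, deform_coefs = rep(0, 7),
                        protrusion_length = NULL) {
  validate_scene_spec(spec)
  co <- coord_arrays(spec$grid_shape, spec$voxel_size)
  ac_vals <- spec$intensity$ac * ac_membership(co, spec, deform_coefs)
  n_prot <- 0L
  if (isTRUE(spec$protrusion$present)) {
    if (spec$protrusion$radius > spec$bm_gap$width / 2)
      stop("inconsistent spec: protrusion stalk wider than the BM gap ",
           "(a protrusion cannot cross an intact BM)")
    L <- if (is.null(protrusion_length)) spec$protrusion$length
         else protrusion_length
    below <- protrusion_membership(co, spec, L)
    n_prot <- sum(below)
    ac_vals <- pmax(ac_vals,
                    spec$intensity$ac * (below | connector_membership(co, spec)))
  }
  storage.mode(ac_vals) <- "double"
  if (isTRUE(spec$ac_focus$present)) {
    # bright actin focus at the ventral AC pole, pointing at the vulval midline
    fx <- spec$bm_gap$center
    fy <- spec$ac_center[["dv"]] + spec$ac_radii[["dv"]] - spec$ac_focus$offset
    fz <- spec$ac_center[["z"]]
    s2 <- 2 * spec$ac_focus$sigma^2
    ac_vals <- ac_vals + spec$intensity$ac * spec$ac_focus$amplitude *
      exp(-((co$X - fx)^2 + (co$Y - fy)^2 + (co$Z - fz)^2) / s2)
  }
  truth <- list(
    true_volume_trace = data.frame(time_s = 0,
                                   volume_um3 = n_prot * voxel_volume(spec$voxel_size)),
    true_landmarks = spec$landmarks,
    true_breached = spec$bm_gap$width > 0,
    applied_shifts = NULL)
  al <- truth_alignment(spec$landmarks)
  truth$true_R_A <- al$R_A
  truth$true_Delta <- al$Delta
  list(scene = list(ac = voxel_grid(ac_vals, spec$voxel_size, channel = "ac"),
                    bm = voxel_grid(bm_channel(co, spec), spec$voxel_size,
                                    channel = "bm")),
       truth = truth)
}

# blur + camera model for one channel; returns 16-bit-quantized counts.
# counts = gain * Poisson(photon_scale * blurred) + N(0, read_sd), so the
# count variance over a uniform patch is gain * mean + read_sd^2.
render_channel <- function(grid, spec) {
  psf <- psf_model(spec$psf_sigma[1], spec$psf_sigma[2])
  blurred <- blur_psf(grid$values, psf, spec$voxel_size)
  ns <- spec$noise
  counts <- blurred
  n <- length(blurred)
  if (ns$photon_scale > 0)
    counts <- ns$gain * rpois(n, pmax(blurred, 0) * ns$photon_scale)
  else
    counts <- ns$gain * blurred  # photon noise disabled: deterministic mapping
  if (ns$read_sd > 0) counts <- counts + rnorm(n, 0, ns$read_sd)
  q <- round(pmin(pmax(counts, 0), 65535))
  sat <- mean(counts > 65535)
  out <- voxel_grid(array(q, dim = dim(grid$values)), spec$voxel_size,
                    channel = grid$channel, time = grid$time)
  attr(out, "saturation_fraction") <- sat
  out
}

#' Render an observed stack from a noise-free scene
#'
#' Applies the forward acquisition model: separable Gaussian PSF blur, Poisson
#' photon noise, Gaussian read noise, and quantization to 16-bit unsigned
#' counts with clipping (the saturated fraction is attached as attribute
#' `saturation_fraction`). The same `spec` (including its seed) always yields
#' bit-identical output.
#'
#' @param scene output of [build_scene()] (or its `scene` element).
#' @param spec the [scene_spec()] used to build it.
#' @param frame frame number used to derive the per-frame noise sub-stream.
#' @return list of observed [voxel_grid()]s (`ac`, `bm`).
#' @export
render_stack <- function(scene, spec, frame = 0L) {
  if (!is.null(scene$scene)) scene <- scene$scene
  set.seed(frame_seed(spec$seed, frame))
  lapply(scene, render_channel, spec = spec)
}

#' Simulate an observed two-channel time series with ground truth
#'
#' The AC boundary is perturbed by a smooth random angular field whose mode
#' coefficients follow a stationary AR(1) process with standard deviation
#' `deform_amplitude` and correlation time `deform_tau`; the protrusion
#' elongates linearly when `protrusion$growth` is non-zero; optional integer
#' stage jitter in `(y, x)` is applied to the observed frames and recorded in
#' `applied_shifts`.
#'
#' @param spec a [scene_spec()] with `n_frames >= 2`.
#' @return list with `frames` (per-frame lists of observed `ac`/`bm`
#'   [voxel_grid()]s) and `truth` (as in [build_scene()], with the full
#'   `true_volume_trace` and `applied_shifts`).
#' @export
simulate_timeseries <- function(spec) {
  validate_scene_spec(spec)
  if (spec$n_frames < 2L) stop("a time series needs n_frames >= 2")
  nt <- spec$n_frames
  phi <- exp(-spec$frame_interval / spec$deform_tau)
  set.seed(frame_seed(spec$seed, -1))
  a <- spec$deform_amplitude
  coefs <- rnorm(7, 0, a)
  shifts <- matrix(0L, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  if (spec$jitter_sd > 0)
    shifts[-1, ] <- matrix(as.integer(round(rnorm(2 * (nt - 1), 0, spec$jitter_sd))),
                           ncol = 2)
  frames <- vector("list", nt)
  vols <- numeric(nt)
  times <- (seq_len(nt) - 1L) * spec$frame_interval
  truth <- NULL
  for (t in seq_len(nt)) {
    L <- spec$protrusion$length + spec$protrusion$growth * times[t] / 60
    built <- build_scene(spec, deform_coefs = coefs, protrusion_length = L)
    if (t == 1L) truth <- built$truth
    vols[t] <- built$truth$true_volume_trace$volume_um3[1]
    obs <- render_stack(built$scene, spec, frame = t)
    if (any(shifts[t, ] != 0)) {
      obs <- lapply(obs, function(g) {
        v <- g$values
        for (z in seq_len(dim(v)[1]))
          v[z, , ] <- shift_image(v[z, , ], shifts[t, 1], shifts[t, 2])
        voxel_grid(v, g$voxel_size, channel = g$channel)
      })
    }
    obs$ac$time <- obs$bm$time <- times[t]
    frames[[t]] <- obs
    coefs <- phi * coefs + sqrt(1 - phi^2) * rnorm(7, 0, a)
  }
  truth$true_volume_trace <- data.frame(time_s = times, volume_um3 = vols)
  truth$applied_shifts <- shifts
  list(frames = frames, truth = truth)
}
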