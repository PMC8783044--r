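#' Extract the ventral basement-membrane surface
#'
#' For each AP column of the (mid-sagittally projected) BM channel, the BM
#' height is the DV position of maximum intensity within a configured DV
#' search band, and the ridge intensity is that maximum. The search band
#' excludes bright off-membrane structures (e.g. junction punctae dorsal of
#' the sheet).
#'
#' @param bm_grid single-channel [voxel_grid()].
#' @param dv_band optional `(min, max)` DV search band, um; default the full
#'   DV range.
#' @param z_window half-width (slices) of the z-window projected around the
#'   central slice.
#' @return object of class `bm_surface`: data.frame with `ap_um`, `height_um`,
#'   `ridge`, plus attributes `voxel_size` and `gaps` (filled by
#'   [detect_breach()]).
#' @export
extract_bm_surface <- function(bm_grid, dv_band = NULL, z_window = 2L) {
  stopifnot(is_voxel_grid(bm_grid))
  if (all(bm_grid$values == 0)) stop("no BM signal")
  d <- dim(bm_grid$values)
  vs <- bm_grid$voxel_size
  zc <- round(d[1] / 2)
  zsel <- max(1, zc - z_window):min(d[1], zc + z_window)
  img <- max_project(bm_grid$values[zsel, , , drop = FALSE], axis = "z") # (y,x)
  yc <- axis_centers(d[2], vs[2])
  if (is.null(dv_band)) dv_band <- range(yc)
  rows <- which(yc >= dv_band[1] & yc <= dv_band[2])
  if (length(rows) == 0) stop("empty DV search band")
  band <- img[rows, , drop = FALSE]
  peak_row <- apply(band, 2, which.max)
  ridge <- band[cbind(peak_row, seq_len(ncol(band)))]
  surf <- data.frame(ap_um = axis_centers(d[3], vs[3]),
                     height_um = yc[rows[peak_row]],
                     ridge = ridge)
  structure(surf, class = c("bm_surface", "data.frame"),
            voxel_size = vs)
}

#' Detect a basement-membrane breach
#'
#' Columns whose ridge intensity falls below `drop_fraction` times the median
#' ridge intensity of the flanking (non-low) columns are grouped into runs;
#' the surface is called breached when the longest run spans at least
#' `min_gap_um` micrometres.
#'
#' @param surface a `bm_surface` from [extract_bm_surface()].
#' @param drop_fraction ridge-intensity drop defining a gap column.
#' @param min_gap_um minimum gap extent to call a breach, um.
#' @return list with `breached` (flag), `gap_extent_um` (longest gap, 0 when
#'   none) and `gaps` (data.frame of `start_um`, `end_um` per gap interval).
#' @export
detect_breach <- function(surface, drop_fraction = 0.2, min_gap_um = 1.0) {
  stopifnot(inherits(surface, "bm_surface"))
  ridge <- surface$ridge
  med <- median(ridge)
  low <- ridge < drop_fraction * med
  if (any(low) && !all(low)) {
    med <- median(ridge[!low])          # flanking (intact) columns
    low <- ridge < drop_fraction * med
  }
  dx <- attr(surface, "voxel_size")[3]
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gap_idx <- which(runs$values)
  gaps <- data.frame(start_um = (starts[gap_idx] - 1) * dx,
                     end_um = ends[gap_idx] * dx)
  extent <- if (nrow(gaps)) max(gaps$end_um - gaps$start_um) else 0
  list(breached = extent >= min_gap_um, gap_extent_um = extent, gaps = gaps)
}

# 26-connectivity component labelling of a 3D logical mask
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  pd <- d + 2L
  padded <- array(FALSE, pd)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin_offs <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  labels <- array(0L, pd)
  unvisited <- which(padded)
  next_label <- 0L
  for (start in unvisited) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    frontier <- start
    labels[start] <- next_label
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, lin_offs, `+`)))
      nb <- nb[padded[nb] & labels[nb] == 0L]
      labels[nb] <- next_label
      frontier <- nb
    }
  }
  labels[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

#' Protrusion volume by voxel counting
#'
#' Candidate voxels are the AC-mask voxels lying ventral of the BM height at
#' their AP column ("below the BM barrier"); they are grouped into
#' 26-connected components, the protrusion component is selected (the
#' component containing `seed`, or the largest component intersecting a
#' detected gap interval, or simply the largest when no gaps are supplied),
#' and the volume is the voxel count times the voxel volume.
#'
#' @param ac_mask logical 3D `(z,y,x)` mask (e.g. from [binarize()]).
#' @param surface a `bm_surface` from [extract_bm_surface()].
#' @param seed either `"largest"` or a voxel index `(z, y, x)` inside the
#'   protrusion.
#' @param gaps optional gaps data.frame from [detect_breach()] used to pick
#'   the component when `seed = "largest"`.
#' @param voxel_size `(dz, dy, dx)` um; defaults to the surface's.
#' @return list with `volume_um3`, `n_voxels` and the selected component mask.
#' @export
protrusion_volume <- function(ac_mask, surface, seed = "largest",
                              gaps = NULL, voxel_size = NULL) {
  stopifnot(inherits(surface, "bm_surface"))
  if (is.null(voxel_size)) voxel_size <- attr(surface, "voxel_size")
  d <- dim(ac_mask)
  yc <- axis_centers(d[2], voxel_size[2])
  below <- ac_mask
  for (j in seq_len(d[3])) {
    h <- surface$height_um[j]
    below[, yc <= h, j] <- FALSE
  }
  if (!any(below))
    return(list(volume_um3 = 0, n_voxels = 0L, component = below,
                note = "no candidate voxels below the BM"))
  labels <- label_components_3d(below)
  if (identical(seed, "largest")) {
    sizes <- tabulate(labels[labels > 0L])
    keep <- seq_along(sizes)
    if (!is.null(gaps) && nrow(gaps)) {
      xc <- axis_centers(d[3], voxel_size[3])
      in_gap_col <- Reduce(`|`, lapply(seq_len(nrow(gaps)), function(i)
        xc > gaps$start_um[i] & xc < gaps$end_um[i]))
      in_gap <- vapply(keep, function(l) {
        cols <- unique(((which(labels == l) - 1L) %/% (d[1] * d[2])) + 1L)
        any(in_gap_col[cols])
      }, logical(1))
      if (any(in_gap)) keep <- keep[in_gap]
    }
    lab <- keep[which.max(sizes[keep])]
  } else {
    seed <- as.integer(seed)
    lab <- labels[seed[1], seed[2], seed[3]]
    if (lab == 0L) stop("seed voxel is not in any below-BM component")
  }
  comp <- labels == lab
  list(volume_um3 = sum(comp) * prod(voxel_size), n_voxels = sum(comp),
       component = comp)
}

#' One-stop protrusion volumetry for an observed two-channel stack
#'
#' Runs the full volumetry chain on one observed time point: Richardson-Lucy
#' deconvolution of the AC channel, binarization at the constant threshold
#' (`level` as a fraction of the 16-bit dynamic range), BM surface extraction
#' from the laminin channel, breach detection, and protrusion voxel counting.
#'
#' @param obs named list of observed [voxel_grid()]s (`ac`, `bm`), e.g. one
#'   frame of [simulate_timeseries()] or [render_stack()].
#' @param psf a [psf_model()].
#' @param dv_band DV search band for [extract_bm_surface()], um.
#' @param n_iter Richardson-Lucy iterations.
#' @param level constant threshold as a fraction of full scale (65535 counts).
#' @param seed passed to [protrusion_volume()].
#' @return list with `volume_um3`, `breach` (the [detect_breach()] result) and
#'   `surface`.
#' @export
measure_protrusion <- function(obs, psf, dv_band, n_iter = 15L, level = 0.05,
                               seed = "largest") {
  surf <- extract_bm_surface(obs$bm, dv_band = dv_band)
  br <- detect_breach(surf)
  dec <- richardson_lucy(obs$ac, psf, n_iter)
  mask <- binarize(dec$values, level = level, reference = 65535)
  pv <- protrusion_volume(mask, surf, seed = seed, gaps = br$gaps)
  list(volume_um3 = pv$volume_um3, breach = br, surface = surf)
}

#' Protrusion volume trace and post-breach growth rate
#'
#' Computes the per-frame protrusion volume of a time series and the
#' least-squares growth rate (um^3/min) of volume against time over the first
#' `window_min` minutes after the breach (the field-standard window is 90 min
#' at 5 min frame intervals).
#'
#' @param volumes numeric per-frame volumes, um^3 (e.g. from repeated
#'   [protrusion_volume()] calls).
#' @param times_min frame times in minutes.
#' @param breach_time_min time of first breach, min.
#' @param window_min regression window length after the breach, min.
#' @return object of class `protrusion_trace`: list with `samples`
#'   (data.frame `time_min`, `volume_um3`) and `growth_rate_um3_min` (`NA`
#'   with a flag when fewer than 3 frames fall inside the window).
#' @export
protrusion_trace <- function(volumes, times_min, breach_time_min = 0,
                             window_min = 90) {
  stopifnot(length(volumes) == length(times_min))
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (any(volumes < 0)) stop("volumes must be non-negative")
  if (breach_time_min < min(times_min) - 1e-9 ||
      breach_time_min > max(times_min) + 1e-9)
    stop("breach_time_min outside the series")
  sel <- times_min >= breach_time_min &
    times_min <= breach_time_min + window_min
  out <- list(samples = data.frame(time_min = times_min,
                                   volume_um3 = volumes))
  if (sum(sel) < 3L) {
    out$growth_rate_um3_min <- NA_real_
    out$flag <- "fewer than 3 frames in the post-breach window"
  } else {
    fit <- lm(volume_um3 ~ time_min, data = out$samples[sel, ])
    out$growth_rate_um3_min <- unname(coef(fit)[2])
  }
  class(out) <- "protrusion_trace"
  out
}

#' Aggregate volume traces across animals
#'
#' @param traces list of `protrusion_trace` objects sampled on a common time
#'   grid.
#' @return data.frame `time_min`, `mean_um3`, `sd_um3`, `n`.
#' @export
aggregate_traces <- function(traces) {
  times <- traces[[1]]$samples$time_min
  mat <- vapply(traces, function(tr) tr$samples$volume_um3,
                numeric(length(times)))
  data.frame(time_min = times,
             mean_um3 = rowMeans(mat),
             sd_um3 = apply(mat, 1, sd),
             n = length(traces))
}
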