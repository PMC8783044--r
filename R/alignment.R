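#' Create a landmark set
#'
#' Named mid-sagittal landmark positions used for the AC alignment metrics:
#' the outer vulA junctions (`vulA1`, `vulA2`), the two adherens-junction
#' punctae delimiting the AC (`ac_edge_1`, `ac_edge_2`) and the mid-vulF point
#' (`vulF_mid`). Coordinates are `(ap, dv)` in micrometres; `vulA1`/`vulA2`
#' are reordered so that `vulA1` is the anterior (lower AP) junction.
#'
#' @param points named list of `(ap, dv)` positions.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  roles <- c("vulA1", "vulA2", "ac_edge_1", "ac_edge_2", "vulF_mid")
  missing <- setdiff(roles, names(points))
  if (length(missing))
    stop("missing landmark role(s): ", paste(missing, collapse = ", "))
  if (points$vulA1[1] > points$vulA2[1]) {
    tmp <- points$vulA1; points$vulA1 <- points$vulA2; points$vulA2 <- tmp
  }
  structure(points[roles], class = "landmark_set")
}

#' AC alignment metrics from junction landmarks
#'
#' Computes the alignment ratio `R_A` and the absolute AC-to-mid-vulF distance
#' `Delta`, both along the AP axis. The AC mid-point `mid_AC` is the AP
#' midpoint of the two AC-edge punctae; `x` is the AP distance from `mid_AC`
#' to the nearer vulA junction (ties broken towards `vulA1`); `y` is the AP
#' distance between the vulA junctions; `R_A = x / y`, with 0.5 indicating
#' perfect centering between the junctions; `Delta = |mid_AC - vulF_mid|` in
#' micrometres.
#'
#' @param landmarks a [landmark_set()] (or a named list accepted by it).
#' @return data.frame with columns `mid_AC`, `x`, `y`, `R_A`, `Delta`.
#' @export
compute_alignment <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set")) landmarks <- landmark_set(landmarks)
  ap <- vapply(landmarks, `[`, numeric(1), 1)
  y <- ap[["vulA2"]] - ap[["vulA1"]]
  if (y == 0) stop("coincident vulA junctions: alignment undefined")
  mid_ac <- (ap[["ac_edge_1"]] + ap[["ac_edge_2"]]) / 2
  d1 <- abs(mid_ac - ap[["vulA1"]])
  d2 <- abs(mid_ac - ap[["vulA2"]])
  x <- if (d1 <= d2) d1 else d2  # tie towards vulA1
  data.frame(mid_AC = mid_ac, x = x, y = y, R_A = x / y,
             Delta = abs(mid_ac - ap[["vulF_mid"]]))
}

#' Dorsoventral polarity index from a summed z-projection
#'
#' The AC mask is split at its intensity-weighted DV centroid row (ventral =
#' rows below the centroid, i.e. larger row index); `I_DV` is the ratio of the
#' ventral-half to the dorsal-half intensity sum. Rows lying exactly at the
#' centroid count as dorsal.
#'
#' @param projection 2D summed-intensity image `(y, x)` with ventral at high
#'   row index.
#' @param ac_mask logical mask of the AC in the same shape.
#' @return scalar `I_DV`.
#' @export
compute_polarity_index <- function(projection, ac_mask) {
  stopifnot(identical(dim(projection), dim(ac_mask)))
  if (!any(ac_mask)) stop("empty AC mask")
  w <- projection * ac_mask
  rows <- row(projection)
  total <- sum(w)
  if (total <= 0) stop("no intensity inside the AC mask")
  centroid <- sum(rows * w) / total
  ventral <- sum(w[rows > centroid])
  dorsal <- sum(w[rows <= centroid])
  if (dorsal == 0) stop("zero dorsal intensity: polarity index undefined")
  ventral / dorsal
}

# local maxima of a 2D image (8-neighbourhood), ordered by intensity
local_maxima_2d <- function(img, min_value = 0) {
  d <- dim(img)
  pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- img
  ismax <- matrix(TRUE, d[1], d[2])
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[2:(d[1] + 1) + dy, 2:(d[2] + 1) + dx]
    ismax <- ismax & (img >= nb)
  }
  ismax <- ismax & img > min_value
  idx <- which(ismax, arr.ind = TRUE)
  idx[order(img[idx], decreasing = TRUE), , drop = FALSE]
}

#' Detect junction landmarks in the junction/BM channel
#'
#' Semi-automated stand-in for manual landmark picking: the five brightest,
#' well-separated local maxima of the mid-sagittal slice (maximum projection
#' over a thin z-window around the given slice) are taken as punctae, and
#' roles are assigned by AP order: `vulA1 < ac_edge_1 < vulF_mid < ac_edge_2 <
#' vulA2`. Manually supplied landmarks (e.g. from a CSV) are authoritative
#' whenever available.
#'
#' @param bm_grid junction-channel [voxel_grid()].
#' @param n number of punctae to detect (5 for the standard role set).
#' @param min_sep_um minimum separation between accepted punctae, um.
#' @param z_window half-width (in slices) of the z-window projected around the
#'   central slice.
#' @return a [landmark_set()] with positions in micrometres.
#' @export
detect_landmarks <- function(bm_grid, n = 5L, min_sep_um = 0.8, z_window = 2L) {
  stopifnot(is_voxel_grid(bm_grid))
  d <- dim(bm_grid$values)
  zc <- round(d[1] / 2)
  zsel <- max(1, zc - z_window):min(d[1], zc + z_window)
  img <- max_project(bm_grid$values[zsel, , , drop = FALSE], axis = "z")
  cand <- local_maxima_2d(img, min_value = max(img) * 0.1)
  vs <- bm_grid$voxel_size
  picked <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    p <- (cand[i, ] - 0.5) * c(vs[2], vs[3])  # (dv, ap) um
    if (nrow(picked) == 0 ||
        all(sqrt(rowSums(sweep(picked, 2, p)^2)) >= min_sep_um))
      picked <- rbind(picked, p)
    if (nrow(picked) == n) break
  }
  if (nrow(picked) < n)
    stop("found only ", nrow(picked), " of ", n, " punctae")
  ord <- order(picked[, 2])  # by AP
  pts <- lapply(seq_len(n), function(i) {
    c(picked[ord[i], 2], picked[ord[i], 1])  # (ap, dv)
  })
  names(pts) <- c("vulA1", "ac_edge_1", "vulF_mid", "ac_edge_2", "vulA2")
  landmark_set(pts)
}

#' Read / write landmark tables
#'
#' Landmark CSVs have columns `animal_id`, `role`, `ap_um`, `dv_um`; one
#' [landmark_set()] is returned per animal.
#'
#' @param file path to a CSV file.
#' @return named list of [landmark_set()]s keyed by `animal_id`.
#' @export
read_landmark_csv <- function(file) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("animal_id", "role", "ap_um", "dv_um")
  if (!all(need %in% names(tab)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$animal_id), function(a) {
    landmark_set(setNames(
      lapply(seq_len(nrow(a)), function(i) c(a$ap_um[i], a$dv_um[i])),
      a$role))
  })
  out
}

#' Alignment metrics for a cohort of landmark sets
#'
#' @param landmark_list named list of [landmark_set()]s (e.g. from
#'   [read_landmark_csv()]).
#' @return data.frame with one row per animal: `animal_id`, `mid_AC`, `x`,
#'   `y`, `R_A`, `Delta`.
#' @export
alignment_table <- function(landmark_list) {
  rows <- lapply(names(landmark_list), function(id) {
    cbind(animal_id = id, compute_alignment(landmark_list[[id]]))
  })
  do.call(rbind, rows)
}
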