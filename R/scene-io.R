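#' Write a synthetic fixture to disk
#'
#' Writes one multi-page 16-bit TIFF per channel (pages ordered frame-major,
#' then z) plus a JSON sidecar (`truth.json`) holding the scene specification,
#' the voxel sizes and the ground truth. Reading the directory back with
#' [read_fixture()] reproduces the voxel values exactly.
#'
#' @param stacks either a single stack (named list of [voxel_grid()]s, e.g.
#'   `ac`/`bm`) or the `frames` element of [simulate_timeseries()].
#' @param truth ground-truth list as produced by [build_scene()] /
#'   [simulate_timeseries()]; may be `NULL`.
#' @param path directory to write into (created if needed).
#' @param spec the [scene_spec()], stored in the sidecar for round-tripping.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(stacks, truth, path, spec = NULL) {
  multi_frame <- !is_voxel_grid(stacks[[1]])
  frames <- if (multi_frame) stacks else list(stacks)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create fixture directory: ", path)
  channels <- names(frames[[1]])
  for (ch in channels) {
    pages <- list()
    for (fr in frames) {
      v <- fr[[ch]]$values
      for (z in seq_len(dim(v)[1]))
        pages[[length(pages) + 1L]] <- v[z, , ] / 65535
    }
    tiff::writeTIFF(pages, file.path(path, paste0(ch, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  }
  g1 <- frames[[1]][[1]]
  sidecar <- list(
    channels = channels,
    n_frames = length(frames),
    grid_shape = dim(g1$values),
    voxel_size = g1$voxel_size,
    spec = if (is.null(spec)) NULL else unclass(spec),
    truth = truth)
  jsonlite::write_json(sidecar, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param path fixture directory.
#' @return list with `frames` (list of per-frame channel lists of
#'   [voxel_grid()]s), `spec` (a [scene_spec()] or `NULL`) and `truth`
#'   (`NULL`, with a message, when the sidecar is absent).
#' @export
read_fixture <- function(path) {
  sidecar_file <- file.path(path, "truth.json")
  tifs <- list.files(path, pattern = "\\.tif$", full.names = TRUE)
  if (length(tifs) == 0) stop("no TIFF channels found in ", path)
  if (file.exists(sidecar_file)) {
    side <- jsonlite::read_json(sidecar_file, simplifyVector = TRUE)
    voxel_size <- side$voxel_size
    nz <- side$grid_shape[1]
    n_frames <- side$n_frames
    truth <- side$truth
    spec <- if (is.null(side$spec)) NULL else {
      s <- side$spec
      s$landmarks <- lapply(s$landmarks, as.numeric)
      do.call(scene_spec, s)
    }
  } else {
    message("no ground truth sidecar found in ", path)
    side <- NULL; truth <- NULL; spec <- NULL
    voxel_size <- c(1, 1, 1)
    n_frames <- 1L
    nz <- NULL
  }
  frames <- NULL
  for (f in tifs) {
    ch <- sub("\\.tif$", "", basename(f))
    pages <- tiff::readTIFF(f, all = TRUE)
    if (is.null(nz)) nz <- length(pages)
    per_frame <- length(pages) / n_frames
    if (is.null(frames)) frames <- rep(list(list()), n_frames)
    for (t in seq_len(n_frames)) {
      sl <- pages[(t - 1L) * per_frame + seq_len(per_frame)]
      v <- array(0, c(per_frame, dim(sl[[1]])))
      for (z in seq_len(per_frame)) v[z, , ] <- round(sl[[z]] * 65535)
      frames[[t]][[ch]] <- voxel_grid(v, voxel_size, channel = ch)
    }
  }
  list(frames = frames, spec = spec, truth = truth)
}
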