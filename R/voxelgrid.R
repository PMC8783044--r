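#' Construct a voxel grid
#'
#' A `voxel_grid` is the unit every image operation consumes and produces: one
#' channel's 3D intensity array on `(z, y, x)` together with its physical voxel
#' sizes in micrometres.
#'
#' @param values numeric 3D array `(z, y, x)` of non-negative intensities.
#' @param voxel_size numeric length-3, micrometres per voxel as `(dz, dy, dx)`.
#' @param channel optional channel label.
#' @param time optional acquisition time in seconds.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size, channel = NULL, time = NULL) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array ordered (z, y, x)")
  if (any(values < 0))
    stop("voxel intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive values (dz, dy, dx)")
  structure(
    list(values = values, voxel_size = voxel_size,
         channel = channel, time = time),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), voxel %s um%s\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size, digits = 3), collapse = " x "),
              if (is.null(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' Voxel volume of a grid in cubic micrometres
#' @param grid a `voxel_grid` or a voxel-size vector `(dz, dy, dx)`.
#' @return scalar volume of one voxel in um^3.
#' @export
voxel_volume <- function(grid) {
  vs <- if (inherits(grid, "voxel_grid")) grid$voxel_size else as.numeric(grid)
  prod(vs)
}

# voxel-centre coordinates (um) along one axis, 1-based indices
axis_centers <- function(n, d) (seq_len(n) - 0.5) * d

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

as_grid_values <- function(x) {
  if (is_voxel_grid(x)) x$values else x
}
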