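#' Construct a BOLD run
#'
#' A single fMRI run: a 4D array of signal values on a fixed voxel grid
#' plus its acquisition geometry.
#'
#' @param data 4D numeric array, dimensions (x, y, z, time).
#' @param tr_s Repetition time in seconds (> 0).
#' @param voxel_size_mm Voxel edge lengths in mm, length-3 vector.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, voxel_size_mm = c(3, 3, 3)) {
  d <- dim(data)
  if (length(d) != 4L) stop("'data' must be a 4D array (x, y, z, time)")
  if (d[4] < 2L) stop("time dimension must have >= 2 volumes")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("'tr_s' must be positive")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  structure(
    list(data = data, tr_s = as.numeric(tr_s),
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %d x %d x %d voxels (%g x %g x %g mm), %d volumes, TR %g s\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              d[4], x$tr_s))
  invisible(x)
}

n_vols <- function(run) dim(run$data)[4]

grid_dim <- function(run) dim(run$data)[1:3]

# time x voxel matrix view of a run (voxels in array order)
run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, nrow = prod(d[1:3]), ncol = d[4]))
}

# rebuild a run from a time x voxel matrix, reusing geometry from `like`
matrix_to_run <- function(Y, like) {
  d <- dim(like$data)
  bold_run(array(t(Y), dim = d), tr_s = like$tr_s,
           voxel_size_mm = like$voxel_size_mm)
}
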