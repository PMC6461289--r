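#' Acquisition grid specification
#'
#' Describes the Cartesian reconstruction grid: field of view, in-plane
#' (x, y) voxel size, and a slice-thickness factor multiplying the in-plane
#' size along z. Matrix dimensions are `fov / voxel_dims` and must be whole
#' numbers (to within 1e-6): the study design chooses a 36 mm FoV precisely
#' so every resolution fits without interpolation.
#'
#' @param in_plane voxel size along x and y (mm).
#' @param thickness_factor slice thickness as a multiple of `in_plane`
#'   (1 = isotropic).
#' @param fov field of view per axis (mm); a scalar is recycled to 3 axes.
#' @return An object of class `grid_spec` with elements `fov`, `in_plane`,
#'   `thickness_factor`, `voxel_dims`, `matrix_dims`.
#' @examples
#' g <- grid_spec(2.0, 1.2) # 18 x 18 x 15 matrix, 2.0 x 2.0 x 2.4 mm voxels
#' voxel_volume(g)
#' @export
grid_spec <- function(in_plane, thickness_factor = 1, fov = c(36, 36, 36)) {
  if (length(fov) == 1) fov <- rep(fov, 3)
  stopifnot(length(fov) == 3, all(is.finite(fov)), all(fov > 0),
            length(in_plane) == 1, is.finite(in_plane),
            length(thickness_factor) == 1, is.finite(thickness_factor))
  if (in_plane <= 0 || thickness_factor <= 0)
    stop("voxel dimensions must be positive")
  voxel <- c(in_plane, in_plane, in_plane * thickness_factor)
  exact <- fov / voxel
  dims <- as.integer(round(exact))
  if (any(abs(exact - dims) > 1e-6))
    stop(sprintf(
      "FoV is not an integer multiple of the voxel size (matrix %s): %s",
      paste(signif(exact, 8), collapse = " x "),
      "choose sizes that tile the FoV exactly"))
  if (any(dims < 1)) stop("matrix dimensions must all be >= 1")
  structure(list(fov = as.numeric(fov), in_plane = as.numeric(in_plane),
                 thickness_factor = as.numeric(thickness_factor),
                 voxel_dims = voxel, matrix_dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid> FoV %g x %g x %g mm, voxels %g x %g x %g mm, matrix %d x %d x %d\n",
    x$fov[1], x$fov[2], x$fov[3], x$voxel_dims[1], x$voxel_dims[2],
    x$voxel_dims[3], x$matrix_dims[1], x$matrix_dims[2], x$matrix_dims[3]))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid a [grid_spec()].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  prod(grid$voxel_dims)
}

#' Is a grid isotropic?
#'
#' @param grid a [grid_spec()].
#' @return `TRUE` iff the thickness factor is 1.
#' @export
is_isotropic <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$thickness_factor == 1.0
}

# Centered frequency samples (cycles/mm) per axis: n / FoV with
# n = -floor(N/2) .. ceil(N/2)-1, DC at index floor(N/2)+1.
.k_frequencies <- function(grid) {
  lapply(1:3, function(d) {
    N <- grid$matrix_dims[d]
    ((seq_len(N) - 1) - N %/% 2) / grid$fov[d]
  })
}

#' Voxel-centre world coordinates
#'
#' Coordinates (mm) of voxel centres along each axis, in the convention
#' consistent with the discrete Fourier reconstruction: index
#' `floor(N/2) + 1` sits at the FoV centre (0 mm).
#'
#' @param grid a [grid_spec()].
#' @return List of 3 numeric vectors.
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lapply(1:3, function(d) {
    N <- grid$matrix_dims[d]
    ((seq_len(N) - 1) - N %/% 2) * grid$voxel_dims[d]
  })
}

.same_grid <- function(a, b, tol = 1e-9) {
  all(abs(a$fov - b$fov) < tol) &&
    all(a$matrix_dims == b$matrix_dims) &&
    all(abs(a$voxel_dims - b$voxel_dims) < tol)
}

# index permutations moving DC between centered and DFT layouts
.fftshift_idx <- function(N) c((N - N %/% 2 + 1):N, seq_len(N - N %/% 2))
.ifftshift_idx <- function(N) c((N %/% 2 + 1):N, seq_len(N %/% 2))
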