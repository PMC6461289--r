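#' Ellipsoid ground-truth object
#'
#' Defines an analytic ellipsoid in world space (mm). The default corresponds
#' to the study phantom: semi-axes of 2.7 x 2.7 x 5.4 mm, i.e. a structure of
#' 164.9 mm^3, in the size range of deep-brain-stimulation targets such as the
#' subthalamic nucleus and internal globus pallidus.
#'
#' @param semi_axes length-3 numeric, semi-axis lengths (mm), all positive.
#'   The third component is the "long" axis, aligned with the slice (z) axis
#'   before any orientation is applied.
#' @param center length-3 numeric, offset of the ellipsoid centre from the
#'   field-of-view centre (mm).
#' @param rotation length-3 numeric, intrinsic Euler angles (degrees) about
#'   the x, y and z axes; applied as `Rz %*% Ry %*% Rx`.
#' @param intensity positive scalar signal amplitude (arbitrary units).
#' @return An object of class `ellipsoid`.
#' @examples
#' e <- ellipsoid()
#' ellipsoid_volume(e) # 164.9 mm^3
#' @export
ellipsoid <- function(semi_axes = c(2.7, 2.7, 5.4), center = c(0, 0, 0),
                      rotation = c(0, 0, 0), intensity = 1) {
  stopifnot(length(semi_axes) == 3, all(is.finite(semi_axes)),
            length(center) == 3, all(is.finite(center)),
            length(rotation) == 3, all(is.finite(rotation)),
            length(intensity) == 1, is.finite(intensity))
  if (any(semi_axes <= 0)) stop("all semi-axes must be positive")
  if (intensity <= 0) stop("intensity must be positive")
  structure(list(semi_axes = as.numeric(semi_axes),
                 center = as.numeric(center),
                 rotation = as.numeric(rotation),
                 intensity = as.numeric(intensity)),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid> semi-axes (%.2f, %.2f, %.2f) mm, volume %.1f mm^3\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              ellipsoid_volume(x)))
  cat(sprintf("  centre (%g, %g, %g) mm, rotation (%g, %g, %g) deg, intensity %g\n",
              x$center[1], x$center[2], x$center[3],
              x$rotation[1], x$rotation[2], x$rotation[3], x$intensity))
  invisible(x)
}

#' Exact ellipsoid volume
#'
#' @param e an [ellipsoid()].
#' @return Volume in mm^3, `(4/3) * pi * a * b * c`.
#' @export
ellipsoid_volume <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  (4 / 3) * pi * prod(e$semi_axes)
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations about the x, then y, then z axis:
#' `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)`, angles in degrees.
#'
#' @param angles length-3 numeric, degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_matrix <- function(angles) {
  a <- angles * pi / 180
  ca <- cos(a); sa <- sin(a)
  rx <- matrix(c(1, 0, 0, 0, ca[1], sa[1], 0, -sa[1], ca[1]), 3, 3)
  ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3, 3)
  rz <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Rigid-body transform
#'
#' @param translation length-3 numeric translation (mm).
#' @param rotation length-3 numeric Euler angles (degrees), see
#'   [euler_matrix()].
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, all(is.finite(translation)),
            length(rotation) == 3, all(is.finite(rotation)))
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid transform> t = (%g, %g, %g) mm, r = (%g, %g, %g) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

#' Base orientation of the ellipsoid long axis
#'
#' Returns the pure rotation placing the long (third) semi-axis parallel to
#' the slice (z) axis, at 45 degrees to it (diagonal), or in the imaging
#' plane (orthogonal). These emulate how an elongated nucleus may lie
#' relative to the slice stack in the scanner.
#'
#' @param tag one of `"parallel"`, `"diagonal"`, `"orthogonal"`.
#' @return A [rigid_transform()] with zero translation.
#' @export
base_orientation <- function(tag = c("parallel", "diagonal", "orthogonal")) {
  tag <- match.arg(tag)
  ang <- switch(tag, parallel = 0, diagonal = 45, orthogonal = 90)
  rigid_transform(rotation = c(ang, 0, 0))
}

#' Default rigid-body sampling bounds
#'
#' The study draws small between-subject pose variations uniformly within
#' +/- 4 mm translation and +/- 8 degrees rotation per axis.
#'
#' @param translation length-2 numeric `c(min, max)` in mm.
#' @param rotation length-2 numeric `c(min, max)` in degrees.
#' @return A list with elements `translation` and `rotation`.
#' @export
rigid_bounds <- function(translation = c(-4, 4), rotation = c(-8, 8)) {
  stopifnot(length(translation) == 2, length(rotation) == 2)
  if (translation[1] > translation[2] || rotation[1] > rotation[2])
    stop("invalid bounds: min > max")
  list(translation = as.numeric(translation), rotation = as.numeric(rotation))
}

#' Sample a random rigid-body transform
#'
#' Independent uniform draws per axis within `bounds`; reproducible for a
#' fixed `seed`. Zero-width bounds yield the corresponding fixed value.
#'
#' @param seed optional integer seed; when given the draw is made in a local
#'   RNG scope and the global RNG state is untouched.
#' @param bounds see [rigid_bounds()].
#' @return A [rigid_transform()].
#' @export
sample_rigid_transform <- function(seed = NULL, bounds = rigid_bounds()) {
  draw <- function() {
    rigid_transform(
      translation = stats::runif(3, bounds$translation[1], bounds$translation[2]),
      rotation = stats::runif(3, bounds$rotation[1], bounds$rotation[2])
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Compose an object's own pose with a chain of rigid transforms (applied in
# list order, each about the FoV centre). Returns list(R = 3x3, center = 3).
.world_pose <- function(e, pose = NULL) {
  R <- euler_matrix(e$rotation)
  cen <- e$center
  if (!is.null(pose)) {
    if (inherits(pose, "rigid_transform")) pose <- list(pose)
    for (tr in pose) {
      stopifnot(inherits(tr, "rigid_transform"))
      Rt <- euler_matrix(tr$rotation)
      R <- Rt %*% R
      cen <- as.numeric(Rt %*% cen) + tr$translation
    }
  }
  list(R = R, center = cen)
}

# Normalize an object argument to a list of ellipsoids.
.as_object_list <- function(objects) {
  if (inherits(objects, "ellipsoid")) objects <- list(objects)
  if (!length(objects) || !all(vapply(objects, inherits, TRUE, "ellipsoid")))
    stop("`objects` must be an ellipsoid or a non-empty list of ellipsoids")
  objects
}
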