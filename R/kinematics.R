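# Rotation algebra and error-signal computation for the neck controllers.
#
# Frame convention (fixed for the whole package, repeated in every I/O
# header): x = vehicle forward, y = lateral (positive to the occupant's
# right), z = vertical DOWNWARD; right-handed. Under this convention a
# positive rotation about +y is extension (nose up), about -y flexion,
# about +x right lateral bending, and about +z right axial rotation.
# All angles inside the package are radians; degrees appear only at I/O
# boundaries.

.AXIS_DEFAULT <- c(0, 0, 1)   # documented default axis for zero rotation
.ANGLE_EPS <- 1e-9            # below this the rotation is degenerate

#' Axis-angle rotation
#'
#' Constructs an axis-angle representation of a 3-D rotation: a unit axis
#' `v` and an angle `theta >= 0` (radians). For rotations smaller than
#' 1e-9 rad the axis is undefined; the documented default `(0, 0, 1)` is
#' returned with `degenerate = TRUE`, and downstream load sharing must emit
#' zero directional drive for degenerate errors.
#'
#' @param axis numeric length-3 axis (normalized internally).
#' @param angle rotation angle in radians, in `[0, pi]`.
#' @param degenerate logical flag marking an undefined axis.
#' @return an object of class `axis_angle` with fields `axis`, `angle`,
#'   `degenerate`.
#' @export
axis_angle <- function(axis, angle, degenerate = FALSE) {
  stopifnot(length(axis) == 3, is.finite(angle), angle >= 0)
  if (!degenerate) {
    n <- sqrt(sum(axis^2))
    if (n < .ANGLE_EPS) stop("axis has zero length for a non-degenerate rotation")
    axis <- axis / n
  }
  structure(list(axis = as.numeric(axis), angle = as.numeric(angle),
                 degenerate = isTRUE(degenerate)),
            class = "axis_angle")
}

#' @export
print.axis_angle <- function(x, ...) {
  cat(sprintf("<axis_angle> theta = %.6g rad (%.3f deg), axis = [%.4f, %.4f, %.4f]%s\n",
              x$angle, x$angle * 180 / pi, x$axis[1], x$axis[2], x$axis[3],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

.elem_rot <- function(axis = c("x", "y", "z"), angle) {
  c1 <- cos(angle); s1 <- sin(angle)
  switch(match.arg(axis),
    x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3),
    y = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3),
    z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3))
}

#' Validate a proper rotation matrix
#'
#' @param R candidate 3x3 matrix.
#' @param tol orthonormality / determinant tolerance.
#' @return `R`, invisibly; signals an error when invalid.
#' @export
check_orientation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || !all(is.finite(R)))
    stop("orientation must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("orientation matrix is not orthonormal within tolerance")
  if (abs(det(R) - 1) > tol)
    stop("orientation matrix determinant is not +1 within tolerance")
  invisible(R)
}

#' Rotation matrix from successive z, y, x rotations
#'
#' Composes elemental rotations applied in the order z, then y, then x.
#' The default reading is intrinsic z-y'-x'' (body-fixed axes), for which
#' the matrix product is `Rz(rz) %*% Ry(ry) %*% Rx(rx)`. The extrinsic
#' reading (fixed axes z, y, x in turn) gives `Rx %*% Ry %*% Rz` and is
#' selectable because the two conventions coincide only to first order in
#' the angles; the maneuvers of interest involve small combined angles, so
#' both are supported and the choice is recorded in run configs.
#'
#' @param rx,ry,rz rotation angles about x, y, z in radians.
#' @param convention `"intrinsic"` (default) or `"extrinsic"`.
#' @return a proper orthogonal 3x3 matrix.
#' @export
rotation_matrix_zyx <- function(rx, ry, rz,
                                convention = c("intrinsic", "extrinsic")) {
  if (!all(is.finite(c(rx, ry, rz)))) stop("angles must be finite")
  convention <- match.arg(convention)
  Rx <- .elem_rot("x", rx); Ry <- .elem_rot("y", ry); Rz <- .elem_rot("z", rz)
  if (convention == "intrinsic") Rz %*% Ry %*% Rx else Rx %*% Ry %*% Rz
}

#' Rodrigues rotation matrix from axis-angle
#'
#' @param aa an [axis_angle()] object (or list with `axis`, `angle`).
#' @return 3x3 rotation matrix.
#' @export
rodrigues <- function(aa) {
  v <- aa$axis; th <- aa$angle
  if (isTRUE(aa$degenerate) || th < .ANGLE_EPS) return(diag(3))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Internal fast extraction, no validation. Near theta = pi the sine-based
# axis formula degenerates; the axis is then taken from the dominant
# column of (R + I)/2, sign-matched to the skew part when available.
.axis_angle_core <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  th <- acos(min(1, max(-1, (tr - 1) / 2)))
  if (th < .ANGLE_EPS)
    return(list(axis = .AXIS_DEFAULT, angle = th, degenerate = TRUE))
  s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (pi - th > 1e-4) {
    v <- s / (2 * sin(th))
  } else {
    B <- (R + diag(3)) / 2
    j <- which.max(diag(B))
    v <- B[, j] / sqrt(max(B[j, j], .Machine$double.eps))
    if (sum(v * s) < 0) v <- -v
  }
  v <- v / sqrt(sum(v^2))
  list(axis = v, angle = th, degenerate = FALSE)
}

#' Axis-angle representation of a rotation matrix
#'
#' Extracts the unit axis and angle (in `[0, pi]`) of a proper rotation
#' matrix, such that [rodrigues()] reconstructs the input. The identity
#' rotation returns angle 0 with the documented default axis `(0, 0, 1)`
#' and `degenerate = TRUE`.
#'
#' @param R 3x3 proper rotation matrix.
#' @param tol orthonormality tolerance for validation.
#' @return an [axis_angle()] object.
#' @export
axis_angle_from_matrix <- function(R, tol = 1e-6) {
  check_orientation(R, tol)
  out <- .axis_angle_core(R)
  axis_angle(out$axis, out$angle, degenerate = out$degenerate)
}

#' Rotational error between two head orientations
#'
#' Axis-angle of the relative rotation taking the reference orientation to
#' the current orientation, `Rrel = t(reference) %*% current`; the axis is
#' expressed in the reference frame. The angle `theta` is the scalar error
#' fed to the PID controller and the axis drives intermuscular load
#' sharing. Swapping the arguments leaves `theta` unchanged and negates
#' the axis.
#'
#' @param current,reference 3x3 proper rotation matrices; the reference is
#'   the head orientation captured at the reference time in a globally
#'   fixed frame initially aligned with the head.
#' @return an [axis_angle()] object.
#' @export
rotational_error <- function(current, reference) {
  check_orientation(current)
  check_orientation(reference)
  out <- .axis_angle_core(crossprod(reference, current))
  axis_angle(out$axis, out$angle, degenerate = out$degenerate)
}

#' Translational (link-deviation) error
#'
#' Error signal of the translational controller: the angular deviation of
#' the T1-to-head-CoG link from its reference, both expressed in a frame
#' that follows T1 in yaw (rotation about global z), plus the horizontal
#' azimuth of the head displacement used for load sharing. Azimuth 0 is
#' forward (+x) and +pi/2 is rightward (+y); leftward displacement gives
#' -pi/2.
#'
#' @param head_cog current head centre-of-gravity position (m, global frame).
#' @param t1_pos current T1 position (m, global frame).
#' @param t1_yaw current T1 yaw angle about global z (radians).
#' @param reference_link T1-to-head link captured before the maneuver,
#'   expressed in the (then-aligned) T1-local frame; must be non-zero.
#' @return list of class `translational_error` with `deviation_angle`
#'   (radians, >= 0), `azimuth` (radians in `(-pi, pi]`) and `degenerate`
#'   (TRUE when the horizontal displacement is numerically zero).
#' @export
translational_error <- function(head_cog, t1_pos, t1_yaw, reference_link) {
  stopifnot(length(head_cog) == 3, length(t1_pos) == 3,
            length(reference_link) == 3, is.finite(t1_yaw))
  nref <- sqrt(sum(reference_link^2))
  if (nref <= 0) stop("reference link must have positive length")
  link <- as.numeric(head_cog) - as.numeric(t1_pos)
  local <- as.numeric(crossprod(.elem_rot("z", t1_yaw), link))
  ncur <- sqrt(sum(local^2))
  if (ncur < 1e-12) stop("degenerate geometry: current T1-to-head link has zero length")
  cosang <- sum(local * reference_link) / (ncur * nref)
  dev <- acos(min(1, max(-1, cosang)))
  delta <- local - as.numeric(reference_link)
  horiz <- sqrt(delta[1]^2 + delta[2]^2)
  if (horiz < 1e-12) {
    list_out <- structure(list(deviation_angle = dev, azimuth = 0,
                               degenerate = TRUE),
                          class = "translational_error")
    return(list_out)
  }
  structure(list(deviation_angle = dev,
                 azimuth = atan2(delta[2], delta[1]),
                 degenerate = FALSE),
            class = "translational_error")
}

#' Map a rotation axis to an STP query direction
#'
#' Converts the rotational controller's unit axis `v` into the direction
#' coordinates used by spatial tuning patterns. Under the package frame
#' (x forward, y right, z down):
#'
#' | head deviation            | rotation axis | bend azimuth |
#' |---------------------------|---------------|--------------|
#' | forward flexion           | (0, -1, 0)    | 0            |
#' | right lateral bend        | (+1, 0, 0)    | +pi/2        |
#' | extension (rearward)      | (0, +1, 0)    | pi           |
#' | left lateral bend         | (-1, 0, 0)    | -pi/2        |
#' | right axial rotation      | (0, 0, +1)    | axial +1     |
#'
#' so `bend_azimuth = atan2(vx, -vy)` and `axial_component = vz`.
#'
#' @param axis unit 3-vector rotation axis.
#' @return list with `bend_azimuth` (radians) and `axial_component`
#'   (in `[-1, 1]`, positive = right axial rotation).
#' @export
axis_to_direction <- function(axis) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  list(bend_azimuth = atan2(axis[1], -axis[2]),
       axial_component = min(1, max(-1, axis[3])))
}
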