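# Independent oracles used by the tests. These deliberately avoid the
# package's own rotation code paths.

# quaternion [w, x, y, z] for a rotation about a coordinate axis
quat_axis <- function(axis, angle) {
  v <- c(x = 1, y = 2, z = 3)[[axis]]
  q <- c(cos(angle / 2), 0, 0, 0)
  q[1 + v] <- sin(angle / 2)
  q
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# intrinsic z-y'-x'' composition via quaternions
quat_zyx_matrix <- function(rx, ry, rz) {
  q <- quat_mult(quat_mult(quat_axis("z", rz), quat_axis("y", ry)),
                 quat_axis("x", rx))
  quat_to_matrix(q)
}

# axis-angle via eigen-decomposition: the rotation axis is the (real)
# eigenvector of R with unit eigenvalue; the angle comes from the trace
eigen_axis_angle <- function(R) {
  ev <- eigen(R)
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v / sqrt(sum(v^2))
  th <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
  # orient the eigenvector to match the rotation sense
  s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sum(v * s) < 0) v <- -v
  list(axis = v, angle = th)
}

random_rotation <- function() {
  neckcontrol::rotation_matrix_zyx(stats::runif(1, -pi, pi),
                                   stats::runif(1, -pi / 2, pi / 2),
                                   stats::runif(1, -pi, pi))
}
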