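# Quaternion utilities (scalar-first convention: q = (w, x, y, z)).
# All functions are vectorized over rows of n x 4 matrices.

quat_normalize <- function(q) {
  q <- rbind(q)
  q / sqrt(rowSums(q^2))
}

quat_norm_error <- function(q) {
  max(abs(sqrt(rowSums(rbind(q)^2)) - 1))
}

#' @noRd
quat_multiply <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

# Rotation about a fixed unit axis by angles theta (vectorized).
quat_from_axis_angle <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  h <- theta / 2
  cbind(cos(h), sin(h) * axis[1], sin(h) * axis[2], sin(h) * axis[3])
}

# n x 4 quaternions -> n x 9 row-major rotation matrices
# (columns r11 r12 r13 r21 r22 r23 r31 r32 r33).
quat_to_rotmat9 <- function(q) {
  q <- rbind(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  )
}

# Apply n x 9 row-major rotation matrices to a single body-frame vector.
rotmat9_apply <- function(R9, v) {
  cbind(
    R9[, 1] * v[1] + R9[, 2] * v[2] + R9[, 3] * v[3],
    R9[, 4] * v[1] + R9[, 5] * v[2] + R9[, 6] * v[3],
    R9[, 7] * v[1] + R9[, 8] * v[2] + R9[, 9] * v[3]
  )
}

# Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

rowdot <- function(a, b) rowSums(rbind(a) * rbind(b))
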