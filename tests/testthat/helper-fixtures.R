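# shared fixtures: everything is generated in code at test time

# uniformly random unit vector
random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random proper rotation with angle in [lo, hi] degrees
random_rotation <- function(lo = 10, hi = 170) {
  rotation_from_attitude(stats::runif(1, lo, hi), random_unit())
}

# random non-degenerate pose parameter vector around the knee reference pose
random_pose_params <- function() {
  c(theta = stats::runif(1, 5, 120),
    kx = stats::runif(1, -0.3, 0.3), ky = stats::runif(1, -0.3, 0.3),
    e1x = stats::runif(1, -0.3, 0.3), e1y = stats::runif(1, -0.3, 0.3),
    e3x = stats::runif(1, -0.5, 0.5), e3z = stats::runif(1, -0.5, 0.5))
}

# independently coded Rodrigues construction via the quaternion formula,
# used as a dual-implementation oracle
quaternion_rotation <- function(theta_deg, k) {
  a <- theta_deg * pi / 360 # half angle, radians
  w <- cos(a); x <- sin(a) * k[1]; y <- sin(a) * k[2]; z <- sin(a) * k[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rz_deg <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
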