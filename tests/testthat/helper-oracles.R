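# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: elementary rotations are built directly, random
# rotations come from Rodrigues' formula, and spherical membership from a
# winding-number sum on the sphere.

Rz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
Ry <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
Rx <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# Rodrigues rotation about a random axis — independent of the Euler path.
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

random_unit <- function(n = 1) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

cross_v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Brute-force spherical winding number: sum of signed turning angles of the
# boundary as seen from p. |sum| ~ 2*pi inside, ~ 0 outside.
winding_inside <- function(p, boundary) {
  n <- nrow(boundary)
  tang <- boundary - outer(as.numeric(boundary %*% p), p)
  nrm <- sqrt(rowSums(tang^2))
  if (any(nrm < 1e-12)) return(TRUE)     # query point on a vertex
  tang <- tang / nrm
  i2 <- c(2:n, 1)
  tot <- 0
  for (i in seq_len(n)) {
    a <- tang[i, ]; b <- tang[i2[i], ]
    tot <- tot + atan2(sum(p * cross_v(a, b)), sum(a * b))
  }
  abs(tot) > pi
}

# Sample points on the surface of a joint-limit model's zero-torque
# ellipsoid (gauge = 1) in Euler space.
sample_model_boundary <- function(model, n = 200) {
  u <- random_unit(n)                        # directions in scaled space
  m <- solve(model$coupling) %*% diag(model$semi_axes)
  sweep(u %*% t(m), 2, model$center, "+")
}
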