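# Tolerances used throughout the rotation layer.
.ROT_TOL <- 1e-9          # orthonormality / determinant tolerance
.GIMBAL_TOL <- 1e-8       # |cos(abad)| below this counts as gimbal lock

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Validate a rotation matrix
#'
#' A valid rotation is a 3x3 real matrix with `t(R) %*% R = I` and
#' `det(R) = +1`, both within `tol`.
#'
#' @param m A 3x3 numeric matrix.
#' @param tol Numeric tolerance on orthonormality and determinant residuals.
#' @return `TRUE` invisibly; errors if `m` is not a proper rotation.
#' @export
check_rotation <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || !is.numeric(m) ||
      anyNA(m) || any(!is.finite(m))) {
    stop("invalid-rotation: expected a finite 3x3 numeric matrix", call. = FALSE)
  }
  ortho <- max(abs(crossprod(m) - diag(3)))
  if (ortho > tol) {
    stop(sprintf("invalid-rotation: orthonormality residual %.3g exceeds %.3g",
                 ortho, tol), call. = FALSE)
  }
  d <- det(m)
  if (abs(d - 1) > max(tol, 1e-6)) {
    stop(sprintf("invalid-rotation: det = %.6f, expected +1 (improper rotation?)",
                 d), call. = FALSE)
  }
  invisible(TRUE)
}

is_rotation <- function(m, tol = 1e-6) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && is.numeric(m) &&
    !anyNA(m) && all(is.finite(m)) &&
    max(abs(crossprod(m) - diag(3))) <= tol && abs(det(m) - 1) <= max(tol, 1e-6)
}

#' Euler triple (Z-Y-X) to rotation matrix
#'
#' Converts an intrinsic Z-then-Y-then-X Euler triple, in degrees, to the
#' rotation matrix `Rz(fe) %*% Ry(abad) %*% Rx(lar)` (column-vector
#' convention, right-hand rule). In the joint convention used here Z is
#' flexion/extension (FE), Y abduction/adduction (ABAD) and X long-axis
#' rotation (LAR); FE is applied first.
#'
#' @param fe_z,abad_y,lar_x Rotation angles in degrees about Z, Y and X.
#'   Alternatively `fe_z` may be a length-3 numeric vector `c(fe, abad, lar)`.
#' @return A 3x3 rotation matrix.
#' @examples
#' euler_to_matrix(90, 0, 0)[, 1]   # unit-x maps to unit-y
#' @export
euler_to_matrix <- function(fe_z, abad_y = NULL, lar_x = NULL) {
  if (is.null(abad_y) && length(fe_z) == 3L) {
    abad_y <- fe_z[[2L]]; lar_x <- fe_z[[3L]]; fe_z <- fe_z[[1L]]
  }
  e <- c(fe_z, abad_y, lar_x)
  if (length(e) != 3L || !is.numeric(e) || anyNA(e) || any(!is.finite(e))) {
    stop("invalid-angle: Euler angles must be three finite numbers", call. = FALSE)
  }
  euler_to_matrix_many(matrix(e, nrow = 1L))[, , 1L]
}

# Vectorized form: `e` is an n x 3 matrix of (fe_z, abad_y, lar_x) in degrees;
# returns a 3 x 3 x n array. Used by the bulk pose-sequence paths.
euler_to_matrix_many <- function(e) {
  stopifnot(is.matrix(e), ncol(e) == 3L)
  a <- deg2rad(e[, 1L]); b <- deg2rad(e[, 2L]); c_ <- deg2rad(e[, 3L])
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c_); sc <- sin(c_)
  n <- nrow(e)
  r <- array(0, dim = c(3L, 3L, n))
  r[1L, 1L, ] <- ca * cb
  r[1L, 2L, ] <- ca * sb * sc - sa * cc
  r[1L, 3L, ] <- ca * sb * cc + sa * sc
  r[2L, 1L, ] <- sa * cb
  r[2L, 2L, ] <- sa * sb * sc + ca * cc
  r[2L, 3L, ] <- sa * sb * cc - ca * sc
  r[3L, 1L, ] <- -sb
  r[3L, 2L, ] <- cb * sc
  r[3L, 3L, ] <- cb * cc
  r
}

#' Rotation matrix to Euler triple (Z-Y-X)
#'
#' Inverse of [euler_to_matrix()]. Returns the unique triple with
#' `abad_y` in \[-90, 90\] degrees. At gimbal lock (`|abad_y| = 90` within
#' tolerance) the X and Z rotations are not separable; the convention here
#' forces `lar_x = 0` and folds the residual rotation into `fe_z`.
#'
#' @param r A 3x3 proper rotation matrix.
#' @param tol Orthonormality tolerance for input validation.
#' @return Named numeric vector `c(fe_z, abad_y, lar_x)` in degrees.
#' @export
matrix_to_euler <- function(r, tol = 1e-6) {
  check_rotation(r, tol = tol)
  e <- matrix_to_euler_many(array(r, dim = c(3L, 3L, 1L)))
  c(fe_z = unname(e[1L, 1L]), abad_y = unname(e[1L, 2L]),
    lar_x = unname(e[1L, 3L]))
}

# Vectorized inverse: 3 x 3 x n array -> n x 3 matrix of degrees.
matrix_to_euler_many <- function(r) {
  stopifnot(length(dim(r)) == 3L)
  r31 <- pmin(1, pmax(-1, r[3L, 1L, ]))
  b <- asin(-r31)
  locked <- abs(cos(b)) < .GIMBAL_TOL
  a <- atan2(r[2L, 1L, ], r[1L, 1L, ])
  c_ <- atan2(r[3L, 2L, ], r[3L, 3L, ])
  if (any(locked)) {
    # fe and lar act about the same world axis: put everything in fe
    a[locked] <- atan2(-r[1L, 2L, locked], r[2L, 2L, locked])
    c_[locked] <- 0
  }
  out <- cbind(fe_z = rad2deg(a), abad_y = rad2deg(b), lar_x = rad2deg(c_))
  # canonical ranges: fe, lar in (-180, 180], ties at -180 mapped to +180
  out[, c(1L, 3L)][out[, c(1L, 3L)] <= -180] <- 180
  out
}

#' Relative rotation of a distal frame in a proximal frame
#'
#' Joint rotation is measured as the orientation of the distal bone's
#' anatomical coordinate system expressed in the proximal bone's system:
#' `t(r_prox) %*% r_dist`. The result is the identity exactly when the two
#' frames are aligned — the null (reference) pose.
#'
#' @param r_prox,r_dist World orientations (3x3 rotations) of the proximal
#'   and distal anatomical coordinate systems.
#' @return A 3x3 rotation matrix.
#' @export
relative_rotation <- function(r_prox, r_dist) {
  check_rotation(r_prox); check_rotation(r_dist)
  crossprod(r_prox, r_dist)
}

#' Mirror a pose across the proximal X-Z plane
#'
#' Left-side joint data are transformed to the right-side convention by
#' conjugating each relative rotation with the reflection
#' `M = diag(1, -1, 1)` (the plane perpendicular to the mediolateral Y
#' axis): `M %*% r %*% M`. In Euler terms this maps
#' `(fe, abad, lar) -> (-fe, abad, -lar)`.
#'
#' @param r A 3x3 proper rotation (relative pose in the proximal frame).
#' @return The mirrored rotation, again a proper rotation.
#' @export
mirror_pose <- function(r) {
  check_rotation(r)
  m <- diag(c(1, -1, 1))
  m %*% r %*% m
}

mirror_pose_many <- function(r) {
  out <- r
  # conjugation by diag(1,-1,1) flips sign of elements with exactly one
  # index equal to 2
  out[1L, 2L, ] <- -r[1L, 2L, ]
  out[2L, 1L, ] <- -r[2L, 1L, ]
  out[2L, 3L, ] <- -r[2L, 3L, ]
  out[3L, 2L, ] <- -r[3L, 2L, ]
  out
}

#' Geodesic angle between two rotations or two unit vectors
#'
#' For rotations, the rotation angle of `t(a) %*% b` from the trace formula;
#' for unit vectors, the arc `acos(a . b)`. Both in degrees in \[0, 180\].
#'
#' @param a,b Two 3x3 rotation matrices, or two numeric 3-vectors.
#' @return Angle in degrees.
#' @export
geodesic_angle <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    check_rotation(a); check_rotation(b)
    tr <- sum(diag(crossprod(a, b)))
    return(rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2)))))
  }
  if (is.numeric(a) && is.numeric(b) && length(a) == 3L && length(b) == 3L &&
      !is.matrix(a) && !is.matrix(b)) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) {
      stop("invalid-input: zero vector has no direction", call. = FALSE)
    }
    return(rad2deg(acos(pmin(1, pmax(-1, sum(a * b) / (na * nb))))))
  }
  stop("invalid-input: arguments must both be rotations or both unit vectors",
       call. = FALSE)
}

#' Construct a pose sequence
#'
#' A pose sequence is an ordered set of relative rotations (distal ACS in the
#' proximal ACS) with frame times and acquisition metadata — the common
#' currency between the simulators, the file readers and the RoM analysis.
#'
#' @param rotations A 3x3xN array or list of 3x3 rotation matrices.
#' @param times Frame times in seconds (strictly increasing). Default:
#'   `(0:(N-1)) / rate_hz`.
#' @param rate_hz Nominal sampling rate in Hz (ex vivo capture runs at 30 Hz).
#' @param specimen,joint,side,context,trial,sequence Metadata: specimen id,
#'   joint (`"hip"`/`"knee"`), side (`"left"`/`"right"`), context
#'   (`"ex_vivo"`/`"in_vivo"`), trial id, and the sweep-sequence label (one of
#'   FAL, FLA, AFL, ALF, LFA, LAF, a planar label, or `"stride"`).
#' @param torque Optional per-frame passive torque channel (N mm).
#' @param validate Check every frame against the rotation invariants.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(rotations, times = NULL, rate_hz = 30,
                          specimen = NA_character_, joint = NA_character_,
                          side = NA_character_, context = NA_character_,
                          trial = NA_character_, sequence = NA_character_,
                          torque = NULL, validate = TRUE) {
  if (is.list(rotations)) {
    rotations <- array(unlist(rotations), dim = c(3L, 3L, length(rotations)))
  }
  if (is.matrix(rotations) && all(dim(rotations) == c(3L, 3L))) {
    rotations <- array(rotations, dim = c(3L, 3L, 1L))
  }
  stopifnot(length(dim(rotations)) == 3L, all(dim(rotations)[1:2] == 3L))
  n <- dim(rotations)[3L]
  if (n < 1L) stop("pose sequence needs at least one frame", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0) {
    stop("rate_hz must be positive", call. = FALSE)
  }
  if (is.null(times)) times <- (seq_len(n) - 1L) / rate_hz
  if (length(times) != n || any(diff(times) <= 0)) {
    stop("times must match frame count and be strictly increasing", call. = FALSE)
  }
  if (validate) {
    for (i in seq_len(n)) {
      ok <- tryCatch({ check_rotation(rotations[, , i]); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop(sprintf("invalid-rotation at frame %d", i), call. = FALSE)
    }
  }
  if (!is.null(torque) && length(torque) != n) {
    stop("torque channel length must match frame count", call. = FALSE)
  }
  structure(
    list(rotations = rotations, times = as.numeric(times),
         rate_hz = rate_hz, torque = torque,
         meta = list(specimen = specimen, joint = joint, side = side,
                     context = context, trial = trial, sequence = sequence)),
    class = "pose_sequence")
}

#' @export
length.pose_sequence <- function(x) dim(x$rotations)[3L]

#' @export
print.pose_sequence <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<pose_sequence> %d frames @ %g Hz | specimen=%s joint=%s side=%s context=%s sequence=%s\n",
    length(x), x$rate_hz, m$specimen, m$joint, m$side, m$context, m$sequence))
  invisible(x)
}

#' Euler decomposition of every frame in a pose sequence
#'
#' @param seq A [pose_sequence()].
#' @return A data.frame with columns `frame`, `time_s`, `fe_z`, `abad_y`,
#'   `lar_x` (degrees).
#' @export
pose_sequence_euler <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  e <- matrix_to_euler_many(seq$rotations)
  data.frame(frame = seq_len(length(seq)), time_s = seq$times,
             fe_z = e[, 1L], abad_y = e[, 2L], lar_x = e[, 3L])
}

#' Mirror every frame of a left-side sequence to the right-side convention
#'
#' @param seq A [pose_sequence()] with `side = "left"`.
#' @return The mirrored sequence with `side` set to `"right"`.
#' @export
mirror_sequence <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  out <- seq
  out$rotations <- mirror_pose_many(seq$rotations)
  out$meta$side <- "right"
  out
}
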