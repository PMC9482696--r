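# Anatomical coordinate system (ACS) construction from bone landmarks.
#
# All limb-bone ACSs follow the convention Z = flexion/extension (FE),
# Y = abduction/adduction (ABAD), X = long-axis rotation (LAR); the pelvis
# uses X = anteroposterior (caudal), Y = mediolateral (right), Z =
# dorsoventral (up). Every ACS is a right-handed orthonormal triad.

#' Landmark set for one bone
#'
#' Container for the perimeter points placed around the articular ends of a
#' bone plus named reference points used to disambiguate axis directions
#' (e.g. a point on the ventral side of the femur).
#'
#' @param proximal_perimeter,distal_perimeter n x 3 matrices of points (mm)
#'   around the proximal/distal articular perimeters.
#' @param reference_points Named list of 3-vectors (mm).
#' @param bone,side Labels (`side` is `"left"` or `"right"`).
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(proximal_perimeter, distal_perimeter,
                         reference_points = list(), bone = "long_bone",
                         side = "right") {
  structure(list(proximal_perimeter = as_points(proximal_perimeter),
                 distal_perimeter = as_points(distal_perimeter),
                 reference_points = reference_points,
                 bone = bone, side = side),
            class = "landmark_set")
}

new_acs <- function(origin, x_axis, y_axis, z_axis, bone = NA_character_,
                    side = NA_character_) {
  structure(list(origin = as.numeric(origin),
                 x_axis = as.numeric(x_axis), y_axis = as.numeric(y_axis),
                 z_axis = as.numeric(z_axis), bone = bone, side = side),
            class = "acs")
}

#' @export
print.acs <- function(x, ...) {
  cat(sprintf("<acs> bone=%s side=%s origin=(%.3f, %.3f, %.3f)\n",
              x$bone, x$side, x$origin[1L], x$origin[2L], x$origin[3L]))
  invisible(x)
}

#' Rotation matrix whose columns are the ACS axes
#'
#' The world orientation of an ACS: `cbind(x_axis, y_axis, z_axis)`. Feeding
#' two of these to [relative_rotation()] yields the joint pose.
#'
#' @param a An `acs` object.
#' @return A 3x3 rotation matrix.
#' @export
acs_rotation <- function(a) {
  stopifnot(inherits(a, "acs"))
  unname(cbind(a$x_axis, a$y_axis, a$z_axis))
}

#' Validate an ACS triad
#'
#' Reports orthogonality, unit-norm and handedness residuals and whether the
#' triad passes at `tol`.
#'
#' @param a An `acs` object.
#' @param tol Residual tolerance (default 1e-9).
#' @return List with `orthogonality`, `unit_norm`, `handedness` residuals and
#'   logical `pass`.
#' @export
validate_acs <- function(a, tol = 1e-9) {
  stopifnot(inherits(a, "acs"))
  ax <- list(a$x_axis, a$y_axis, a$z_axis)
  ortho <- max(abs(sum(ax[[1]] * ax[[2]])), abs(sum(ax[[2]] * ax[[3]])),
               abs(sum(ax[[1]] * ax[[3]])))
  norms <- max(abs(vapply(ax, function(v) sqrt(sum(v^2)), 0) - 1))
  hand <- max(abs(cross3(a$x_axis, a$y_axis) - a$z_axis))
  list(orthogonality = ortho, unit_norm = norms, handedness = hand,
       pass = ortho <= tol && norms <= tol && hand <= tol)
}

# Enforce that `reference` lies on the `ref_sign` side of axis `ref_axis`,
# flipping the two axes in `flippable` together (preserves handedness and the
# retained axis).
.apply_reference_sign <- function(axes, origin, reference, ref_axis, ref_sign,
                                  flippable) {
  if (!(ref_axis %in% flippable)) {
    stop(sprintf("missing-reference: cannot enforce sign on retained axis '%s'",
                 ref_axis), call. = FALSE)
  }
  s <- sum((reference - origin) * axes[[ref_axis]])
  if (sign(s) != 0 && sign(s) != ref_sign) {
    for (nm in flippable) axes[[nm]] <- -axes[[nm]]
  }
  axes
}

#' Build a long-bone ACS from perimeter landmarks
#'
#' The preliminary X axis (LAR) runs from the mean of the proximal perimeter
#' points to the mean of the distal ones (the anatomical long axis); the
#' preliminary Z axis (FE) is the total-least-squares line through the `end`
#' perimeter; Y (ABAD) is their cross product (order chosen so the triad is
#' right-handed). Because bone morphology makes the preliminary X and Z not
#' exactly perpendicular, one axis is recomputed:
#'
#' * `mode = "keep_long_axis"` (proximal femur, tibia/fibula): X is retained
#'   along the anatomical long axis and Z is recomputed as X x Y.
#' * `mode = "keep_fe_axis"` (distal femur): Z is retained along the
#'   perimeter line fit and X is recomputed as Y x Z.
#'
#' Axis signs are then fixed so that the named reference point (by default
#' any point whose name contains `"ventral"` or `"flexor"`, else the first
#' reference point) lies on the negative side of `ref_axis`.
#'
#' @param lm A [landmark_set()].
#' @param mode `"keep_long_axis"` or `"keep_fe_axis"`.
#' @param end Which perimeter carries the origin and the FE line fit:
#'   `"proximal"` or `"distal"`.
#' @param ref_axis Axis whose sign the reference point disambiguates
#'   (default `"z"` for `keep_long_axis`, `"y"` for `keep_fe_axis`).
#' @param ref_sign Required sign of the reference point's coordinate along
#'   `ref_axis` (default -1: ventral/flexor side is negative).
#' @return An `acs` object (attribute `sign_canonicalized` is `TRUE` when no
#'   reference point was available and the line-fit sign fell back to the
#'   lexicographic rule).
#' @export
build_long_bone_acs <- function(lm, mode = c("keep_long_axis", "keep_fe_axis"),
                                end = c("proximal", "distal"),
                                ref_axis = NULL, ref_sign = -1) {
  stopifnot(inherits(lm, "landmark_set"))
  mode <- match.arg(mode)
  end <- match.arg(end)
  if (is.null(ref_axis)) ref_axis <- if (mode == "keep_long_axis") "z" else "y"
  mp <- colMeans(lm$proximal_perimeter)
  md <- colMeans(lm$distal_perimeter)
  end_perim <- if (end == "proximal") lm$proximal_perimeter else lm$distal_perimeter
  origin <- colMeans(end_perim)
  x_prelim <- normalize(md - mp)
  z_prelim <- fit_line(end_perim)$direction
  if (abs(sum(x_prelim * z_prelim)) > 1 - 1e-8) {
    stop("degenerate-geometry: perimeter line parallel to long axis", call. = FALSE)
  }
  y <- normalize(cross3(z_prelim, x_prelim))
  if (mode == "keep_long_axis") {
    x <- x_prelim
    z <- cross3(x, y)
    flippable <- c("y", "z")
  } else {
    z <- z_prelim
    y <- normalize(cross3(z, x_prelim))
    x <- cross3(y, z)
    # the line-fit sign of z is arbitrary: anchor x along the anatomical
    # long axis by flipping the (x, z) pair if needed (preserves
    # handedness and the retained-axis-up-to-sign rule)
    if (sum(x * x_prelim) < 0) { x <- -x; z <- -z }
    flippable <- c("y", "z")
  }
  axes <- list(x = x, y = y, z = z)
  refs <- lm$reference_points
  canonical <- FALSE
  if (length(refs)) {
    # prefer the reference matching the axis being disambiguated: a
    # flexor-surface point constrains Y, a ventral point constrains Z
    want <- if (ref_axis == "y") "flexor" else "ventral"
    nm <- grep(want, names(refs), value = TRUE)
    if (!length(nm)) nm <- grep("ventral|flexor", names(refs), value = TRUE)
    ref <- if (length(nm)) refs[[nm[1L]]] else refs[[1L]]
    axes <- .apply_reference_sign(axes, origin, ref, ref_axis, ref_sign, flippable)
  } else {
    canonical <- TRUE
  }
  out <- new_acs(origin, axes$x, axes$y, axes$z, bone = lm$bone, side = lm$side)
  attr(out, "sign_canonicalized") <- canonical
  out
}

#' Build the pelvis and both acetabular ACSs
#'
#' Spheres are fitted to the two acetabular point clouds; the line through
#' their centroids is the pelvic mediolateral axis (Y, pointing right) and
#' the point midway between them the pelvis origin. A cylinder fitted to the
#' sacral vertebral body gives the anteroposterior direction; its axis is
#' projected onto the plane perpendicular to Y (discarding yaw, keeping
#' pitch) to form the pelvis X axis (pointing caudally). Z = X x Y points
#' dorsally. Each acetabular ACS sits at its sphere centroid with the pelvis
#' axes re-labeled so hip X (LAR) points laterally out of the acetabulum,
#' hip Z (FE) stays dorsoventral, and hip Y (ABAD) completes the
#' right-handed triad.
#'
#' @param left_acet,right_acet Point clouds (n x 3, mm) on the left/right
#'   acetabular articular surfaces.
#' @param sacral_body Point cloud on the sacral vertebral body.
#' @param caudal_ref 3-vector marking the caudal direction (axis-sign
#'   disambiguation).
#' @param up Optional unit 3-vector giving the world vertical. When
#'   supplied, the sacral axis's pitch (its elevation out of the horizontal
#'   plane) is preserved exactly while the yaw is discarded; without it the
#'   axis is orthogonally projected onto the plane perpendicular to Y, which
#'   perturbs the pitch slightly when the yaw is large.
#' @return List with `pelvis`, `left_hip`, `right_hip` (`acs` objects) and
#'   `primitives` (the fitted sphere/cylinder objects).
#' @export
build_pelvis_and_acetabular_acs <- function(left_acet, right_acet, sacral_body,
                                            caudal_ref, up = NULL) {
  sph_l <- fit_sphere(left_acet)
  sph_r <- fit_sphere(right_acet)
  sep <- sqrt(sum((sph_r$center - sph_l$center)^2))
  if (sep < 1e-9) {
    stop("degenerate-geometry: acetabular centroids coincide", call. = FALSE)
  }
  y <- normalize(sph_r$center - sph_l$center)   # mediolateral, points right
  origin <- (sph_l$center + sph_r$center) / 2
  cyl <- fit_cylinder(sacral_body, caudal_reference = caudal_ref)
  a <- cyl$axis_direction
  if (is.null(up)) {
    x <- a - sum(a * y) * y                     # discard the Y component
    if (sqrt(sum(x^2)) < 1e-9) {
      stop("degenerate-geometry: sacral axis parallel to mediolateral axis",
           call. = FALSE)
    }
    x <- normalize(x)
  } else {
    # pitch-preserving: rebuild the axis in the midline sagittal plane with
    # the same elevation out of the horizontal plane, zero yaw
    up <- normalize(up)
    f <- cross3(y, up)
    if (sqrt(sum(f^2)) < 1e-9) {
      stop("degenerate-geometry: up parallel to mediolateral axis", call. = FALSE)
    }
    f <- normalize(f)
    horiz <- a - sum(a * up) * up
    if (sum(horiz * f) < 0) f <- -f
    pitch <- asin(pmin(1, pmax(-1, sum(a * up))))
    x <- cos(pitch) * f + sin(pitch) * up
  }
  if (sum(x * (caudal_ref - origin)) < 0) x <- -x   # caudal
  z <- cross3(x, y)                             # dorsal (up)
  pelvis <- new_acs(origin, x, y, z, bone = "pelvis", side = "both")
  right_hip <- new_acs(sph_r$center, x_axis = y, y_axis = cross3(z, y),
                       z_axis = z, bone = "acetabulum", side = "right")
  left_hip <- new_acs(sph_l$center, x_axis = -y, y_axis = cross3(z, -y),
                      z_axis = z, bone = "acetabulum", side = "left")
  list(pelvis = pelvis, left_hip = left_hip, right_hip = right_hip,
       primitives = list(left_sphere = sph_l, right_sphere = sph_r,
                         sacral_cylinder = cyl))
}
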