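# Rigid pose recovery from motion-capture marker clouds and the trial
# quality rules applied before RoM analysis.

#' Marker template
#'
#' Reference marker positions in the rigid-body (handle) frame.
#'
#' @param reference_positions n x 3 matrix (mm), n >= 3, non-collinear.
#' @param marker_ids Optional character labels (default `m1..mn`).
#' @return Object of class `marker_template`.
#' @export
marker_template <- function(reference_positions, marker_ids = NULL) {
  p <- as_points(reference_positions)
  if (nrow(p) < 3L) {
    stop("insufficient-markers: a template needs at least 3 markers", call. = FALSE)
  }
  sv <- svd(sweep(p, 2L, colMeans(p)), nu = 0L, nv = 0L)$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1)) {
    stop("degenerate-geometry: template markers are collinear", call. = FALSE)
  }
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(nrow(p)))
  rownames(p) <- marker_ids
  structure(list(marker_ids = marker_ids, reference_positions = p),
            class = "marker_template")
}

#' Rigid transform
#'
#' @param rotation 3x3 proper rotation.
#' @param translation 3-vector (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  check_rotation(rotation)
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf A `rigid_transform`.
#' @param points n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  p <- as_points(points)
  sweep(p %*% t(tf$rotation), 2L, -tf$translation)
}

#' Least-squares rigid pose from markers
#'
#' Recovers the rigid transform taking template (body-frame) marker positions
#' to their observed world positions by centroid alignment plus the
#' SVD-based optimal rotation (Kabsch), with the determinant corrected so a
#' reflection is never returned. Markers flagged invisible (or containing
#' `NA`) are excluded.
#'
#' @param template A [marker_template()].
#' @param positions n x 3 matrix of observed marker positions (mm), rows
#'   matching the template order; occluded markers as `NA` rows.
#' @param visible Optional logical vector; `FALSE` rows are ignored.
#' @return List with `transform` (a `rigid_transform`), `rmsd` (mm) and
#'   `n_used`.
#' @export
pose_from_markers <- function(template, positions, visible = NULL) {
  stopifnot(inherits(template, "marker_template"))
  obs <- as.matrix(positions)
  storage.mode(obs) <- "double"
  if (!all(dim(obs) == dim(template$reference_positions))) {
    stop("insufficient-markers: observed positions must match template size",
         call. = FALSE)
  }
  ok <- stats::complete.cases(obs)
  if (!is.null(visible)) ok <- ok & as.logical(visible)
  if (sum(ok) < 3L) {
    stop("insufficient-markers: need at least 3 visible markers", call. = FALSE)
  }
  ref <- template$reference_positions[ok, , drop = FALSE]
  obs <- obs[ok, , drop = FALSE]
  sv0 <- svd(sweep(ref, 2L, colMeans(ref)), nu = 0L, nv = 0L)$d
  if (sv0[2L] < 1e-9 * max(sv0[1L], 1)) {
    stop("degenerate-geometry: visible markers are collinear", call. = FALSE)
  }
  cr <- colMeans(ref); co <- colMeans(obs)
  h <- crossprod(sweep(ref, 2L, cr), sweep(obs, 2L, co))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- co - as.numeric(rot %*% cr)
  fit <- sweep(ref %*% t(rot), 2L, -tr)
  rmsd <- sqrt(mean(rowSums((fit - obs)^2)))
  list(transform = rigid_transform(rot, tr), rmsd = rmsd, n_used = sum(ok))
}

#' Compose rigid transforms
#'
#' `compose_chain(a, b, c)` returns the transform applying `c` first, then
#' `b`, then `a` — e.g. world-from-markers, markers-from-plate,
#' plate-from-bone composes to world-from-bone. Equivalent to the product of
#' the corresponding 4x4 homogeneous matrices.
#'
#' @param ... `rigid_transform` objects, outermost first.
#' @return A `rigid_transform`.
#' @export
compose_chain <- function(...) {
  tfs <- list(...)
  if (!length(tfs)) stop("invalid-transform: empty chain", call. = FALSE)
  for (tf in tfs) {
    if (!inherits(tf, "rigid_transform")) {
      stop("invalid-transform: all elements must be rigid_transform objects",
           call. = FALSE)
    }
  }
  rot <- diag(3); tr <- c(0, 0, 0)
  for (tf in tfs) {
    tr <- tr + as.numeric(rot %*% tf$translation)
    rot <- rot %*% tf$rotation
  }
  rigid_transform(rot, tr)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Detect pose jumps in a sequence
#'
#' During ex vivo trials a sudden jump of the pose outside the previously
#' covered pose space indicates joint damage. This flags every frame whose
#' geodesic rotation step from the previous frame exceeds `max_step_deg`.
#'
#' @param seq A [pose_sequence()].
#' @param max_step_deg Threshold in degrees between consecutive frames
#'   (default 15 at the nominal 30 Hz capture rate).
#' @return data.frame with columns `frame` (index of the frame after the
#'   jump) and `step_deg`; zero rows when the sequence is smooth.
#' @export
detect_pose_jumps <- function(seq, max_step_deg = 15) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- length(seq)
  if (n < 2L) return(data.frame(frame = integer(), step_deg = numeric()))
  r <- seq$rotations
  # tr(t(R[i-1]) R[i]) without forming products: elementwise sum
  tr <- colSums(colSums(r[, , -n, drop = FALSE] * r[, , -1L, drop = FALSE]))
  step <- rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2))))
  idx <- which(step > max_step_deg) + 1L
  data.frame(frame = idx, step_deg = step[idx - 1L])
}

.PLANAR_LABELS <- c("planar-FE", "planar-ABAD", "planar-LAR")
.SWEEP_SEQUENCES <- c("FAL", "FLA", "AFL", "ALF", "LFA", "LAF")

#' Filter trials and assess specimen sufficiency
#'
#' Rejects trials containing pose jumps, then applies the sufficiency rule:
#' a specimen's data are sufficient when all three planar trials (about FE,
#' ABAD and LAR individually) are present and clean, and at least two trials
#' including interaction of degrees of freedom (any of the six hierarchical
#' sweep sequences) survive.
#'
#' @param trials List of [pose_sequence()] objects whose `meta$sequence` is
#'   one of `"planar-FE"`, `"planar-ABAD"`, `"planar-LAR"`, `"FAL"`, `"FLA"`,
#'   `"AFL"`, `"ALF"`, `"LFA"`, `"LAF"`.
#' @param max_step_deg Jump threshold passed to [detect_pose_jumps()].
#' @return List with `kept`, `rejected` (lists of sequences), and
#'   `sufficient` (logical).
#' @export
filter_sufficient_trials <- function(trials, max_step_deg = 15) {
  stopifnot(is.list(trials), length(trials) > 0)
  labels <- vapply(trials, function(tr) {
    lab <- tr$meta$sequence
    if (is.na(lab) || !(lab %in% c(.PLANAR_LABELS, .SWEEP_SEQUENCES))) {
      stop(sprintf("missing-label: trial label '%s' not recognised", lab),
           call. = FALSE)
    }
    lab
  }, character(1))
  clean <- vapply(trials, function(tr) {
    nrow(detect_pose_jumps(tr, max_step_deg)) == 0L
  }, logical(1))
  kept <- trials[clean]
  kept_labels <- labels[clean]
  sufficient <- all(.PLANAR_LABELS %in% kept_labels) &&
    sum(kept_labels %in% .SWEEP_SEQUENCES) >= 2L
  list(kept = kept, rejected = trials[!clean], sufficient = sufficient)
}
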