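# Synthetic ground truth: a coupled-ellipsoid joint-limit model, the
# hierarchical torque-thresholded sweep protocol, in vivo-style stride
# cycles, landmark fixtures and marker trials. These generators define the
# study conditions under which the analysis pipeline is exercised; they are
# first-class, tested code, not fixtures.

#' Joint-limit model: a coupled ellipsoid in Euler space
#'
#' The feasible pose set is `{ e : || coupling %*% (e - center) / semi_axes || <= 1 }`
#' (elementwise division by `semi_axes`), the simplest smooth set exhibiting
#' interaction of degrees of freedom: the attainable extreme about one axis
#' depends on the current rotations about the other two. Passive torque is
#' zero inside the set and grows linearly with the Euler-space distance
#' beyond the boundary (measured along the ray from the center):
#' `torque = stiffness * max(0, ||e - center|| * (1 - 1/r))` where `r` is the
#' ellipsoid gauge of `e`.
#'
#' @param center Euler triple `c(fe, abad, lar)` (degrees), the feasible-set
#'   center.
#' @param semi_axes Three positive semi-axis lengths (degrees).
#' @param coupling 3x3 well-conditioned matrix modelling interaction of
#'   degrees of freedom (identity = axis-aligned, no interaction).
#' @param stiffness Passive stiffness beyond the boundary (N mm per degree).
#' @param torque_threshold Torque limit tau (N mm) at which a sweep stops.
#' @return Object of class `joint_limit_model`.
#' @export
joint_limit_model <- function(center = c(0, 0, 0), semi_axes = c(60, 40, 50),
                              coupling = diag(3), stiffness = 2,
                              torque_threshold = 10) {
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L,
            all(is.finite(center)), all(semi_axes > 0),
            is.matrix(coupling), all(dim(coupling) == c(3L, 3L)),
            stiffness >= 0, torque_threshold >= 0)
  if (kappa(coupling, exact = TRUE) > 1e8) {
    stop("invalid-model: coupling matrix is ill-conditioned", call. = FALSE)
  }
  structure(list(center = center, semi_axes = semi_axes, coupling = coupling,
                 stiffness = stiffness, torque_threshold = torque_threshold),
            class = "joint_limit_model")
}

# Ellipsoid gauge r(e) for rows of an n x 3 Euler matrix: r <= 1 inside.
model_gauge <- function(model, e) {
  d <- sweep(as.matrix(e), 2L, model$center)
  u <- d %*% t(model$coupling)
  s <- sweep(u, 2L, model$semi_axes, "/")
  sqrt(rowSums(s^2))
}

#' Passive torque of the joint-limit model at given poses
#'
#' @param model A [joint_limit_model()].
#' @param e n x 3 matrix (or length-3 vector) of Euler poses, degrees.
#' @return Torque in N mm, zero inside the feasible set.
#' @export
model_torque <- function(model, e) {
  if (!is.matrix(e)) e <- matrix(e, nrow = 1L)
  r <- model_gauge(model, e)
  d <- sqrt(rowSums(sweep(e, 2L, model$center)^2))
  model$stiffness * pmax(0, d * (1 - 1 / pmax(r, 1e-12))) * (r > 1)
}

# Per-axis extent of the feasible set from its support function: the extreme
# of axis i over the ellipsoid is center_i +/- || row_i(solve(coupling) %*%
# diag(semi_axes)) ||. The torque-limited sweep boundary adds tau/stiffness.
#' Analytic per-axis extremes of a joint-limit model
#'
#' @param model A [joint_limit_model()].
#' @param torque_limited Add the `tau / stiffness` overshoot the sweep
#'   protocol permits before stopping. The addition is exact for
#'   axis-aligned models; for coupled models it is an upper bound (the
#'   torque margin is measured along the ray from the center, which is not
#'   axis-aligned at the support point), so treat torque-limited extents of
#'   coupled models as approximate to within `tau / stiffness`.
#' @return 3 x 2 matrix (rows fe/abad/lar, cols min/max), degrees.
#' @export
model_axis_extents <- function(model, torque_limited = TRUE) {
  m <- solve(model$coupling) %*% diag(model$semi_axes)
  ext <- sqrt(rowSums(m^2))
  if (torque_limited && model$stiffness > 0) {
    ext <- ext + model$torque_threshold / model$stiffness
  }
  out <- cbind(min = model$center - ext, max = model$center + ext)
  rownames(out) <- c("fe_z", "abad_y", "lar_x")
  out
}

#' Sweep specification for an ex vivo trial
#'
#' @param sequence One of `"FAL"`, `"FLA"`, `"AFL"`, `"ALF"`, `"LFA"`,
#'   `"LAF"` — the hierarchical order in which axes are manipulated; the
#'   first letter is swept at the highest frequency.
#' @param steps Step sizes in degrees, named `fe`, `abad`, `lar`.
#' @param rate_hz Emission rate (capture runs at 30 Hz).
#' @param seed Integer seed (the protocol is deterministic; kept for the
#'   reproducibility contract).
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(sequence = "FAL", steps = c(fe = 2, abad = 2, lar = 2),
                       rate_hz = 30, seed = 1L) {
  sequence <- toupper(sequence)
  if (!sequence %in% .SWEEP_SEQUENCES) {
    stop("invalid sweep sequence; must be one of FAL, FLA, AFL, ALF, LFA, LAF",
         call. = FALSE)
  }
  steps <- steps[c("fe", "abad", "lar")]
  stopifnot(all(is.finite(steps)), all(steps > 0), rate_hz > 0)
  structure(list(sequence = sequence, steps = steps, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Simulate an ex vivo sweep trial
#'
#' Emulates the hierarchical sweep protocol on a synthetic joint: the
#' innermost axis is swept in both directions until the passive torque at
#' the next step would reach the threshold tau, then the next axis is
#' incremented and the inner sweep repeats, until the limits about the
#' outermost axis are reached. The experimenter's live feedback is emulated
#' by starting each inner sweep from the torque-minimising pose of its
#' sweep line, so the emitted poses tile the entire torque-admissible grid
#' (every grid pose with torque strictly below tau, each emitted once, in
#' sweep order). With `tau = 0` only the center pose is emitted. The
#' emitted boundary therefore lies up to `tau / stiffness` degrees beyond
#' the zero-torque ellipsoid surface, and within one step of the
#' torque-limited extents of [model_axis_extents()].
#'
#' @param model A [joint_limit_model()].
#' @param spec A [sweep_spec()].
#' @param specimen,joint,side Metadata labels for the emitted sequence.
#' @return A [pose_sequence()] with a per-frame `torque` channel (all values
#'   `< tau`), `context = "ex_vivo"`.
#' @export
simulate_exvivo_trial <- function(model, spec, specimen = "synthetic",
                                  joint = "hip", side = "right") {
  stopifnot(inherits(model, "joint_limit_model"), inherits(spec, "sweep_spec"))
  axis_of <- c(F = 1L, A = 2L, L = 3L)
  letters_ <- strsplit(spec$sequence, "")[[1L]]
  inner <- axis_of[[letters_[1L]]]
  mid <- axis_of[[letters_[2L]]]
  outer <- axis_of[[letters_[3L]]]
  steps <- unname(spec$steps)  # fe, abad, lar order
  ext <- model_axis_extents(model, torque_limited = TRUE)
  grid_vals <- lapply(1:3, function(i) {
    kmax <- ceiling((ext[i, "max"] - model$center[i]) / steps[i]) + 1L
    kmin <- floor((ext[i, "min"] - model$center[i]) / steps[i]) - 1L
    model$center[i] + steps[i] * (kmin:kmax)
  })
  tau <- model$torque_threshold
  # full grid torque, ordered outer-slowest / inner-fastest
  g <- expand.grid(i = grid_vals[[inner]], m = grid_vals[[mid]],
                   o = grid_vals[[outer]])
  e <- matrix(0, nrow(g), 3L)
  e[, inner] <- g$i; e[, mid] <- g$m; e[, outer] <- g$o
  tq <- model_torque(model, e)
  feasible <- tq < tau
  if (!any(feasible)) {
    e_keep <- matrix(model$center, 1L, 3L)
    tq_keep <- model_torque(model, e_keep)
  } else {
    ni <- length(grid_vals[[inner]])
    nm <- length(grid_vals[[mid]])
    keep <- integer(0)
    idx <- seq_len(nrow(g))
    dim(idx) <- c(ni, nm, length(grid_vals[[outer]]))
    last <- NULL
    for (oo in seq_len(dim(idx)[3L])) {
      mm_order <- seq_len(nm)
      if (!is.null(last) &&
          abs(grid_vals[[mid]][nm] - last[mid]) <
            abs(grid_vals[[mid]][1L] - last[mid])) {
        mm_order <- rev(mm_order)   # resume the mid sweep from where it ended
      }
      for (mm in mm_order) {
        run <- idx[, mm, oo][feasible[idx[, mm, oo]]]
        if (!length(run)) next
        # sweep each run from whichever end is nearer the previous pose:
        # the experimenter moves the joint continuously, never teleporting
        if (!is.null(last)) {
          d_head <- sum((e[run[1L], ] - last)^2)
          d_tail <- sum((e[run[length(run)], ] - last)^2)
          if (d_tail < d_head) run <- rev(run)
        }
        keep <- c(keep, run)
        last <- e[run[length(run)], ]
      }
    }
    e_keep <- e[keep, , drop = FALSE]
    tq_keep <- tq[keep]
  }
  rot <- euler_to_matrix_many(e_keep)
  pose_sequence(rot, rate_hz = spec$rate_hz, specimen = specimen,
                joint = joint, side = side, context = "ex_vivo",
                trial = spec$sequence, sequence = spec$sequence,
                torque = tq_keep, validate = FALSE)
}

#' Simulate all six sweep sequences for one specimen
#'
#' @param model A [joint_limit_model()].
#' @param steps,rate_hz Passed to [sweep_spec()] for each sequence.
#' @param specimen,joint,side Metadata labels.
#' @return Named list of six [pose_sequence()] objects (FAL ... LAF).
#' @export
simulate_exvivo_protocol <- function(model, steps = c(fe = 2, abad = 2, lar = 2),
                                     rate_hz = 30, specimen = "synthetic",
                                     joint = "hip", side = "right") {
  out <- lapply(.SWEEP_SEQUENCES, function(sq) {
    simulate_exvivo_trial(model, sweep_spec(sq, steps, rate_hz),
                          specimen = specimen, joint = joint, side = side)
  })
  names(out) <- .SWEEP_SEQUENCES
  out
}

#' Stride specification
#'
#' One periodic stride cycle as per-axis sinusoids in Euler space:
#' `e_i(t) = mean_i + amplitude_i * sin(2*pi*t + phase_i)` over one cycle.
#'
#' @param n_frames Frames per cycle (default 401, one rotoscoped stride).
#' @param mean,amplitude,phase Length-3 numeric (fe, abad, lar); degrees and
#'   radians (phase).
#' @param margin Containment margin: the stride must fit inside the
#'   joint-limit model's feasible set shrunk by this fraction.
#' @param rate_hz Video frame rate (default 500).
#' @param noise_deg Optional Gaussian jitter per frame and axis (degrees).
#' @param seed Seed for the jitter.
#' @return Object of class `stride_spec`.
#' @export
stride_spec <- function(n_frames = 401L, mean = c(0, 0, 0),
                        amplitude = c(30, 10, 15),
                        phase = c(0, pi / 2, pi), margin = 0.1,
                        rate_hz = 500, noise_deg = 0, seed = 1L) {
  stopifnot(n_frames >= 2L, length(mean) == 3L, length(amplitude) == 3L,
            length(phase) == 3L, margin >= 0, margin < 1, noise_deg >= 0)
  structure(list(n_frames = as.integer(n_frames), mean = as.numeric(mean),
                 amplitude = as.numeric(amplitude), phase = as.numeric(phase),
                 margin = margin, rate_hz = rate_hz, noise_deg = noise_deg,
                 seed = as.integer(seed)),
            class = "stride_spec")
}

#' Construct a stride spec guaranteed to fit inside a model
#'
#' Amplitudes are set per axis to `frac` of the model's axis-aligned
#' feasible extent through the center; because the three sinusoids add, the
#' worst-case ellipsoid gauge is bounded by `3 * frac`, so `frac <= 0.3`
#' guarantees containment at a 10% margin regardless of phases.
#'
#' @param model A [joint_limit_model()].
#' @param frac Fraction of each axis-aligned extent (default 0.3).
#' @param ... Passed to [stride_spec()].
#' @return A [stride_spec()] centered on the model.
#' @export
contained_stride_spec <- function(model, frac = 0.3, ...) {
  amp <- vapply(1:3, function(i) {
    e <- rep(0, 3); e[i] <- 1
    frac / model_gauge(model, matrix(model$center + e, 1L, 3L))
  }, 0)
  stride_spec(mean = model$center, amplitude = amp, ...)
}

#' Simulate one in vivo stride cycle
#'
#' @param model A [joint_limit_model()] the stride must respect.
#' @param spec A [stride_spec()].
#' @param specimen,joint,side Metadata labels.
#' @return A [pose_sequence()] with `context = "in_vivo"`,
#'   `sequence = "stride"`. Errors (`infeasible-stride`) if any frame leaves
#'   the feasible set shrunk by `spec$margin`.
#' @export
simulate_stride <- function(model, spec, specimen = "synthetic",
                            joint = "hip", side = "right") {
  stopifnot(inherits(model, "joint_limit_model"), inherits(spec, "stride_spec"))
  t_ <- seq(0, 1, length.out = spec$n_frames)
  e <- sapply(1:3, function(i) {
    spec$mean[i] + spec$amplitude[i] * sin(2 * pi * t_ + spec$phase[i])
  })
  if (spec$noise_deg > 0) {
    set.seed(spec$seed)
    e <- e + matrix(stats::rnorm(length(e), sd = spec$noise_deg),
                    nrow = nrow(e))
  }
  shrunk <- model
  shrunk$semi_axes <- model$semi_axes * (1 - spec$margin)
  r <- model_gauge(shrunk, e)
  if (any(r > 1)) {
    stop(sprintf(
      "infeasible-stride: %d frame(s) leave the feasible set shrunk by the %.0f%% margin (max gauge %.3f)",
      sum(r > 1), 100 * spec$margin, max(r)), call. = FALSE)
  }
  pose_sequence(euler_to_matrix_many(e), rate_hz = spec$rate_hz,
                specimen = specimen, joint = joint, side = side,
                context = "in_vivo", trial = "stride", sequence = "stride",
                validate = FALSE)
}

#' Hip-like and knee-like joint-limit presets
#'
#' Synthetic presets whose RoM tables resemble published salamander
#' hindlimb magnitudes: a hip with broad motion about all three axes
#' centered well away from the null pose (all poses internally rotated, so
#' the feasible set excludes the null pose), and an FE-dominant knee. The
#' centers and semi-axes are set to the pooled published ex vivo per-axis
#' extremes (hip FE -95..43, ABAD -70..71, LAR -147..-12; knee FE 5..133,
#' ABAD -38..26, LAR -35..33). Clearly synthetic; not fitted to any
#' individual specimen.
#'
#' @param joint `"hip"` or `"knee"`.
#' @return A [joint_limit_model()].
#' @export
joint_limit_preset <- function(joint = c("hip", "knee")) {
  joint <- match.arg(joint)
  cpl <- matrix(c(1, 0.15, 0.10,
                  0.10, 1, 0.12,
                  0, 0.08, 1), 3L, 3L, byrow = TRUE)
  if (joint == "hip") {
    joint_limit_model(center = c(-26, 0, -80), semi_axes = c(69, 70, 68),
                      coupling = cpl, stiffness = 2, torque_threshold = 10)
  } else {
    joint_limit_model(center = c(69, -6, -1), semi_axes = c(64, 32, 34),
                      coupling = cpl, stiffness = 2, torque_threshold = 10)
  }
}

#' Stride presets resembling walking kinematics
#'
#' Sinusoid parameters chosen so one cycle spans FE-dominant hip and knee
#' excursions of in vivo-walking magnitude (hip FE range ~ 117 deg, knee FE
#' range ~ 115 deg, ABAD about a third of the ex vivo range).
#'
#' @param joint `"hip"` or `"knee"`.
#' @return A [stride_spec()].
#' @export
stride_preset <- function(joint = c("hip", "knee")) {
  joint <- match.arg(joint)
  if (joint == "hip") {
    stride_spec(mean = c(5.5, 11, -84.5), amplitude = c(58.5, 20, 48.5),
                phase = c(0, pi / 2, pi))
  } else {
    stride_spec(mean = c(67, 3.5, -6.5), amplitude = c(57, 18.5, 15.5),
                phase = c(0, pi / 2, pi))
  }
}

#' Synthetic landmark fixtures with known ground-truth ACS
#'
#' Generates perimeter landmark sets for a long bone (elliptical articular
#' perimeters at both ends plus a ventral reference point), or the point
#' clouds of a pelvis fixture (two acetabular sphere caps and a pitched
#' sacral cylinder), optionally noise-perturbed and rigidly placed.
#'
#' @param bone `"long_bone"` or `"pelvis"`.
#' @param n_perimeter Points per perimeter/surface patch.
#' @param noise_sd Isotropic Gaussian noise (mm).
#' @param pose Optional [rigid_transform()] placing the fixture in the world.
#' @param seed Seed for sampling and noise.
#' @param length_mm,pitch_deg,yaw_deg Geometry parameters (bone length; the
#'   sacral cylinder's pitch and yaw for the pelvis).
#' @return For `"long_bone"`: list with `landmarks` (a [landmark_set()]) and
#'   `truth` (list of `acs` ground truth at `proximal` and `distal` ends).
#'   For `"pelvis"`: list with `left_acet`, `right_acet`, `sacral_body`
#'   point matrices, `caudal_ref`, and `truth` (list `pelvis`, `left_hip`,
#'   `right_hip`, plus true sphere `centers`).
#' @export
synth_landmarks <- function(bone = c("long_bone", "pelvis"), n_perimeter = 24L,
                            noise_sd = 0, pose = NULL, seed = 1L,
                            length_mm = 20, pitch_deg = 10, yaw_deg = 0) {
  bone <- match.arg(bone)
  set.seed(seed)
  place <- function(p) if (is.null(pose)) p else apply_transform(pose, p)
  place_acs <- function(a) {
    if (is.null(pose)) return(a)
    new_acs(as.numeric(pose$rotation %*% a$origin) + pose$translation,
            as.numeric(pose$rotation %*% a$x_axis),
            as.numeric(pose$rotation %*% a$y_axis),
            as.numeric(pose$rotation %*% a$z_axis), a$bone, a$side)
  }
  noisy <- function(p) {
    if (noise_sd > 0) p + matrix(stats::rnorm(length(p), sd = noise_sd),
                                 nrow = nrow(p)) else p
  }
  if (bone == "long_bone") {
    th <- seq(0, 2 * pi, length.out = n_perimeter + 1L)[-(n_perimeter + 1L)]
    prox <- cbind(0, 2.0 * sin(th), 3.0 * cos(th))       # major axis along z
    dist <- cbind(length_mm, 1.5 * sin(th), 2.5 * cos(th))
    ref_v <- c(length_mm / 2, 0, -4)                      # ventral: -z side
    ref_f <- c(length_mm / 2, -4, 0)                      # flexor: -y side
    lm <- landmark_set(place(noisy(prox)), place(noisy(dist)),
                       reference_points = list(
                         ventral = as.numeric(place(matrix(ref_v, 1L))),
                         flexor = as.numeric(place(matrix(ref_f, 1L)))),
                       bone = "long_bone", side = "right")
    truth <- list(
      proximal = place_acs(new_acs(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(0, 0, 1), "long_bone", "right")),
      distal = place_acs(new_acs(c(length_mm, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(0, 0, 1), "long_bone", "right")))
    return(list(landmarks = lm, truth = truth))
  }
  # pelvis fixture: mediolateral = y, caudal = +x, up = +z
  cap_points <- function(center, outward, n) {
    pts <- matrix(stats::rnorm(3L * n), ncol = 3L)
    pts <- pts / sqrt(rowSums(pts^2))
    # keep directions within 60 deg of `outward`, reflect the rest
    dp <- pts %*% outward
    pts[dp[, 1L] < 0, ] <- -pts[dp[, 1L] < 0, , drop = FALSE]
    dp <- abs(dp)
    mix <- 0.55 + 0.45 * stats::runif(n)   # avoid exact-hemisphere degeneracy
    dirs <- pts * mix + outer(as.numeric(1 - mix), outward)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    sweep(2.0 * dirs, 2L, center, "+")
  }
  c_l <- c(0, -5, 0); c_r <- c(0, 5, 0)
  left <- cap_points(c_l, c(0, -1, 0), n_perimeter * 3L)
  right <- cap_points(c_r, c(0, 1, 0), n_perimeter * 3L)
  p <- deg2rad(pitch_deg); yw <- deg2rad(yaw_deg)
  dir <- c(cos(p) * cos(yw), cos(p) * sin(yw), -sin(p))
  axis_pt <- c(5, 0, 1)
  tt <- stats::runif(n_perimeter * 3L, -3, 3)
  ph <- stats::runif(n_perimeter * 3L, 0, 2 * pi)
  u <- normalize(cross3(dir, c(0, 0, 1)))
  v <- cross3(dir, u)
  sacral <- outer(rep(1, length(tt)), axis_pt) + outer(tt, dir) +
    1.5 * (cos(ph) %o% u + sin(ph) %o% v)
  caudal_ref <- c(20, 0, 0)
  x_true <- normalize(c(cos(p), 0, -sin(p)))
  y_true <- c(0, 1, 0)
  z_true <- cross3(x_true, y_true)
  truth <- list(
    pelvis = place_acs(new_acs(c(0, 0, 0), x_true, y_true, z_true,
                               "pelvis", "both")),
    right_hip = place_acs(new_acs(c_r, y_true, cross3(z_true, y_true), z_true,
                                  "acetabulum", "right")),
    left_hip = place_acs(new_acs(c_l, -y_true, cross3(z_true, -y_true), z_true,
                                 "acetabulum", "left")),
    centers = list(left = c_l, right = c_r))
  up_world <- if (is.null(pose)) c(0, 0, 1) else
    as.numeric(pose$rotation %*% c(0, 0, 1))
  list(left_acet = place(noisy(left)), right_acet = place(noisy(right)),
       sacral_body = place(noisy(sacral)),
       caudal_ref = as.numeric(place(matrix(caudal_ref, 1L))),
       up = up_world, truth = truth)
}

#' Simulate a marker trial from a pose sequence
#'
#' Transforms the template markers by each frame's rotation (plus an
#' optional translation track) and adds isotropic Gaussian noise — the
#' fixture for testing marker-based pose recovery round trips.
#'
#' @param template A [marker_template()].
#' @param seq A [pose_sequence()].
#' @param noise_mm Marker noise standard deviation (mm).
#' @param seed Seed for the noise.
#' @param translations Optional n x 3 matrix of per-frame translations (mm).
#' @return List with `positions` (array: markers x 3 x frames), `times`, and
#'   the `template`.
#' @export
synth_marker_trial <- function(template, seq, noise_mm = 0, seed = 1L,
                               translations = NULL) {
  stopifnot(inherits(template, "marker_template"), inherits(seq, "pose_sequence"))
  n <- length(seq)
  ref <- template$reference_positions
  if (is.null(translations)) translations <- matrix(0, n, 3L)
  set.seed(seed)
  pos <- array(NA_real_, dim = c(nrow(ref), 3L, n))
  for (i in seq_len(n)) {
    p <- ref %*% t(seq$rotations[, , i])
    p <- sweep(p, 2L, translations[i, ], "+")
    if (noise_mm > 0) {
      p <- p + matrix(stats::rnorm(length(p), sd = noise_mm), nrow = nrow(p))
    }
    pos[, , i] <- p
  }
  list(positions = pos, times = seq$times, template = template)
}

#' Recover a pose sequence from a marker trial
#'
#' Runs [pose_from_markers()] on every frame; frames with fewer than three
#' visible markers are dropped (and reported), not interpolated.
#'
#' @param trial A [synth_marker_trial()]-shaped list (`positions`, `times`,
#'   `template`).
#' @param rate_hz Sampling rate for the recovered sequence.
#' @param meta Named list of metadata passed to [pose_sequence()].
#' @return List with `sequence` (a [pose_sequence()]), `rmsd` per recovered
#'   frame, and `dropped` (indices of unsolvable frames).
#' @export
recover_pose_sequence <- function(trial, rate_hz = 30, meta = list()) {
  n <- dim(trial$positions)[3L]
  rots <- vector("list", n)
  rmsd <- rep(NA_real_, n)
  dropped <- integer(0)
  for (i in seq_len(n)) {
    res <- tryCatch(pose_from_markers(trial$template, trial$positions[, , i]),
                    error = function(e) NULL)
    if (is.null(res)) { dropped <- c(dropped, i); next }
    rots[[i]] <- res$transform$rotation
    rmsd[i] <- res$rmsd
  }
  ok <- which(!vapply(rots, is.null, logical(1)))
  if (!length(ok)) stop("insufficient-markers: no frame could be solved", call. = FALSE)
  args <- c(list(rotations = rots[ok], times = trial$times[ok],
                 rate_hz = rate_hz, validate = FALSE), meta)
  list(sequence = do.call(pose_sequence, args), rmsd = rmsd[ok],
       dropped = dropped)
}
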