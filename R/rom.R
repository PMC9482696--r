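# Per-axis RoM summaries with interaction of degrees of freedom, pooling of
# specimens, and the in vivo vs ex vivo pose-space comparison.

# The published integer tables round half away from zero; base round() is
# round-half-even, so this is done by hand.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Joint sign conventions
#'
#' Records what a positive rotation about each axis means for a given joint
#' and side, and the null-pose definition. Defaults follow the hip
#' (positive Z = extension/retraction) and knee (positive Z = flexion)
#' conventions for right-side joints.
#'
#' @param joint `"hip"` or `"knee"`.
#' @param side `"left"` or `"right"`.
#' @return Object of class `joint_convention`.
#' @export
joint_convention <- function(joint = c("hip", "knee"),
                             side = c("right", "left")) {
  joint <- match.arg(joint)
  side <- match.arg(side)
  if (joint == "hip") {
    structure(list(
      joint = joint, side = side,
      positive_z = "extension (retraction)", positive_y = "abduction",
      positive_x = "external rotation",
      null_pose = "proximal femoral ACS aligned with the acetabular ACS (limb extended laterally)"),
      class = "joint_convention")
  } else {
    structure(list(
      joint = joint, side = side,
      positive_z = "flexion", positive_y = "abduction",
      positive_x = "external rotation",
      null_pose = "proximal tibial/fibular ACS aligned with the distal femoral ACS (limb extended)"),
      class = "joint_convention")
  }
}

#' Per-axis RoM summary with concomitant angles
#'
#' Decomposes every frame into Z-Y-X Euler angles and reports, for each of
#' FE, ABAD and LAR, the maximum and minimum (unrounded), their range, and
#' the rotations about the other two axes at the extremal frames —
#' interaction of degrees of freedom. Ties are broken by the earliest frame.
#' The range is computed on unrounded extrema; [rom_table()] rounds for
#' presentation, so a printed range may differ from rounded-max minus
#' rounded-min by 1 degree.
#'
#' @param seq A [pose_sequence()].
#' @param convention Optional [joint_convention()] attached as metadata.
#' @return Object of class `rom_summary`: data.frame with one row per axis
#'   (`FE`, `ABAD`, `LAR`) and columns `max`, `min`, `range`, the extremal
#'   frame indices, and the concomitant angles `fe_at_max`, `abad_at_max`,
#'   `lar_at_max`, `fe_at_min`, `abad_at_min`, `lar_at_min` (degrees,
#'   unrounded). Attribute `n_gimbal` counts gimbal-locked frames.
#' @export
rom_summary <- function(seq, convention = NULL) {
  e <- pose_sequence_euler(seq)
  n_gimbal <- sum(abs(abs(e$abad_y) - 90) < 1e-6)
  if (n_gimbal > 0) {
    warning(sprintf("%d gimbal-locked frame(s) included with lar_x = 0 convention",
                    n_gimbal))
  }
  cols <- c(FE = "fe_z", ABAD = "abad_y", LAR = "lar_x")
  rows <- lapply(names(cols), function(ax) {
    v <- e[[cols[[ax]]]]
    imax <- which.max(v); imin <- which.min(v)
    data.frame(axis = ax, max = v[imax], min = v[imin],
               range = v[imax] - v[imin],
               frame_at_max = imax, frame_at_min = imin,
               fe_at_max = e$fe_z[imax], abad_at_max = e$abad_y[imax],
               lar_at_max = e$lar_x[imax],
               fe_at_min = e$fe_z[imin], abad_at_min = e$abad_y[imin],
               lar_at_min = e$lar_x[imin])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$axis
  attr(out, "meta") <- seq$meta
  attr(out, "convention") <- convention
  attr(out, "n_gimbal") <- n_gimbal
  class(out) <- c("rom_summary", "data.frame")
  out
}

#' Integer-rounded RoM table
#'
#' Presentation view of one or more [rom_summary()] objects in the layout of
#' the published tables: every cell rounded to the nearest degree (half away
#' from zero), the range rounded from the unrounded extrema.
#'
#' @param ... `rom_summary` objects (or a single list of them).
#' @param specimen Optional character vector of specimen labels.
#' @return data.frame with columns `specimen`, `context`, `axis`, `max`,
#'   `min`, `range`, `conc1_at_max`, `conc2_at_max`, `conc1_at_min`,
#'   `conc2_at_min` — the concomitant columns hold the rotations about the
#'   other two axes (in Z, Y, X order skipping the axis itself).
#' @export
rom_table <- function(..., specimen = NULL) {
  sums <- list(...)
  if (length(sums) == 1L && !inherits(sums[[1L]], "rom_summary")) {
    sums <- sums[[1L]]
  }
  conc <- list(FE = c("abad", "lar"), ABAD = c("fe", "lar"), LAR = c("fe", "abad"))
  out <- do.call(rbind, lapply(seq_along(sums), function(i) {
    s <- sums[[i]]
    meta <- attr(s, "meta")
    spec <- if (!is.null(specimen)) specimen[[i]] else
      if (!is.null(meta$specimen)) meta$specimen else NA_character_
    ctx <- if (!is.null(meta$context)) meta$context else NA_character_
    do.call(rbind, lapply(s$axis, function(ax) {
      row <- s[ax, ]
      cc <- conc[[ax]]
      data.frame(
        specimen = spec, context = ctx, axis = ax,
        max = round_half_away(row$max), min = round_half_away(row$min),
        range = round_half_away(row$range),
        conc1_at_max = round_half_away(row[[paste0(cc[1L], "_at_max")]]),
        conc2_at_max = round_half_away(row[[paste0(cc[2L], "_at_max")]]),
        conc1_at_min = round_half_away(row[[paste0(cc[1L], "_at_min")]]),
        conc2_at_min = round_half_away(row[[paste0(cc[2L], "_at_min")]]))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Pool SFP traces across specimens
#'
#' Concatenates axis tips from several traces of the same joint under the
#' right-side convention, retaining specimen provenance. Left-side traces
#' must be mirrored (see [mirror_sequence()]) before pooling.
#'
#' @param traces List of `sfp_trace` objects.
#' @return An `sfp_trace` whose `meta$specimen` is a per-frame provenance
#'   vector.
#' @export
pool_specimens <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  joints <- vapply(traces, function(tr) as.character(tr$meta$joint), "")
  if (length(unique(joints[!is.na(joints) & joints != "NA"])) > 1L) {
    stop("incompatible-data: cannot pool traces from different joints",
         call. = FALSE)
  }
  sides <- vapply(traces, function(tr) as.character(tr$meta$side), "")
  if (any(sides == "left", na.rm = TRUE)) {
    stop("incompatible-data: left-side traces must be mirrored to the right-side convention before pooling",
         call. = FALSE)
  }
  prov <- unlist(lapply(traces, function(tr) {
    rep(as.character(tr$meta$specimen), nrow(tr$x_tips))
  }))
  structure(list(x_tips = do.call(rbind, lapply(traces, `[[`, "x_tips")),
                 y_tips = do.call(rbind, lapply(traces, `[[`, "y_tips")),
                 z_tips = do.call(rbind, lapply(traces, `[[`, "z_tips")),
                 meta = list(specimen = prov, joint = joints[[1L]],
                             side = "right", context = "pooled",
                             roles = .AXIS_ROLES, colors = .AXIS_COLORS)),
            class = "sfp_trace")
}

#' Build per-axis regions from an SFP trace
#'
#' @param trace An `sfp_trace` (possibly pooled).
#' @param method,alpha_deg Passed to [build_region()].
#' @return Named list of `spherical_region` objects (`x`, `y`, `z`).
#' @export
sfp_regions <- function(trace, method = "convex_hull", alpha_deg = 15) {
  stopifnot(inherits(trace, "sfp_trace"))
  list(x = build_region(trace$x_tips, method, alpha_deg, axis_role = "x"),
       y = build_region(trace$y_tips, method, alpha_deg, axis_role = "y"),
       z = build_region(trace$z_tips, method, alpha_deg, axis_role = "z"))
}

#' Compare in vivo poses against ex vivo pose-space regions
#'
#' For each axis, the fraction of in vivo tip points lying inside the pooled
#' ex vivo region, the frames falling outside, the ratio of in vivo to
#' pooled ex vivo per-axis Euler range (when summaries are supplied), and
#' whether the null pose (identity: all three axis tips at their reference
#' positions) is inside all three ex vivo regions.
#'
#' @param invivo An `sfp_trace` of the in vivo sequence.
#' @param exvivo_regions Named list (`x`, `y`, `z`) of ex vivo
#'   [build_region()] results.
#' @param invivo_summary Optional [rom_summary()] of the in vivo sequence.
#' @param exvivo_summaries Optional list of ex vivo `rom_summary` objects;
#'   the pooled ex vivo range per axis is max(maxima) - min(minima).
#' @return Object of class `rom_comparison`: list with `inside_fraction`
#'   (named per axis), `outside_frames` (named list of frame indices),
#'   `range_ratio` (named per Euler axis, or `NULL`), and
#'   `null_pose_reachable`.
#' @export
compare_invivo_exvivo <- function(invivo, exvivo_regions,
                                  invivo_summary = NULL,
                                  exvivo_summaries = NULL) {
  stopifnot(inherits(invivo, "sfp_trace"),
            all(c("x", "y", "z") %in% names(exvivo_regions)))
  tips <- list(x = invivo$x_tips, y = invivo$y_tips, z = invivo$z_tips)
  inside <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    point_in_region(tips[[ax]], exvivo_regions[[ax]])
  })
  inside_fraction <- vapply(inside, mean, 0)
  outside_frames <- lapply(inside, function(v) which(!v))
  range_ratio <- NULL
  if (!is.null(invivo_summary) && !is.null(exvivo_summaries)) {
    range_ratio <- vapply(c(FE = "FE", ABAD = "ABAD", LAR = "LAR"), function(ax) {
      ev_max <- max(vapply(exvivo_summaries, function(s) s[ax, "max"], 0))
      ev_min <- min(vapply(exvivo_summaries, function(s) s[ax, "min"], 0))
      invivo_summary[ax, "range"] / (ev_max - ev_min)
    }, 0)
  }
  ident <- diag(3)
  null_ok <- all(vapply(c("x", "y", "z"), function(ax) {
    i <- match(ax, c("x", "y", "z"))
    point_in_region(ident[, i], exvivo_regions[[ax]])
  }, logical(1)))
  structure(list(inside_fraction = inside_fraction,
                 outside_frames = outside_frames,
                 range_ratio = range_ratio,
                 null_pose_reachable = null_ok),
            class = "rom_comparison")
}

#' @export
print.rom_comparison <- function(x, ...) {
  cat("<rom_comparison>\n")
  cat(sprintf("  inside fraction: x(LAR)=%.3f y(ABAD)=%.3f z(FE)=%.3f\n",
              x$inside_fraction[["x"]], x$inside_fraction[["y"]],
              x$inside_fraction[["z"]]))
  if (!is.null(x$range_ratio)) {
    cat(sprintf("  range ratio (in vivo / ex vivo): FE=%.2f ABAD=%.2f LAR=%.2f\n",
                x$range_ratio[["FE"]], x$range_ratio[["ABAD"]],
                x$range_ratio[["LAR"]]))
  }
  cat(sprintf("  null pose reachable: %s\n", x$null_pose_reachable))
  invisible(x)
}
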