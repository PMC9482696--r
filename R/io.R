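# File formats: pose tables (CSV, matrix or Euler form, with #-comment
# metadata), landmark CSV/JSON, ACS JSON, RoM table CSV, SFP JSON export.
# Readers reject malformed input rather than coercing; writers are
# deterministic given identical inputs.

.MATRIX_HEADER <- c("frame", "time_s", "r11", "r12", "r13", "r21", "r22",
                    "r23", "r31", "r32", "r33")
.EULER_HEADER <- c("frame", "time_s", "fe_z", "abad_y", "lar_x")

.read_hash_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[trimws(substr(kv, 1L, eq - 1L))]] <- trimws(substr(kv, eq + 1L, nchar(kv)))
    }
  }
  meta
}

#' Read a pose-sequence table
#'
#' Accepts two CSV layouts, auto-detected from the header: rotation-matrix
#' form (`frame,time_s,r11,...,r33`, row-major) or Euler form
#' (`frame,time_s,fe_z,abad_y,lar_x`, degrees). Metadata may be supplied as
#' leading comment lines (`# specimen=...`, `# joint=...`, `# side=...`,
#' `# context=...`, `# sequence=...`) or a sidecar JSON file
#' (`<path>.meta.json`).
#'
#' @param path CSV file path.
#' @param tol Orthonormality tolerance for matrix-form validation.
#' @return A [pose_sequence()].
#' @export
read_pose_table <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  meta <- .read_hash_meta(path)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                              meta)
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  hdr <- names(df)
  get_meta <- function(k, default = NA_character_) {
    if (!is.null(meta[[k]])) as.character(meta[[k]]) else default
  }
  mk <- function(rot, times) {
    pose_sequence(rot, times = times,
                  rate_hz = as.numeric(get_meta("rate_hz", "30")),
                  specimen = get_meta("specimen"), joint = get_meta("joint"),
                  side = get_meta("side"), context = get_meta("context"),
                  trial = get_meta("trial"), sequence = get_meta("sequence"),
                  validate = FALSE)
  }
  for (col in intersect(hdr, c(.MATRIX_HEADER, .EULER_HEADER))) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      stop(sprintf("validation error: column '%s' contains non-numeric or missing values",
                   col), call. = FALSE)
    }
  }
  if (identical(hdr, .MATRIX_HEADER)) {
    n <- nrow(df)
    # rows are row-major r11..r33; column-major fill then transpose per frame
    rot <- aperm(array(as.numeric(t(as.matrix(df[, 3:11]))), c(3L, 3L, n)),
                 c(2L, 1L, 3L))
    for (i in seq_len(n)) {
      ok <- tryCatch({ check_rotation(rot[, , i], tol = tol); TRUE },
                     error = function(e) FALSE)
      if (!ok) {
        stop(sprintf("validation error: row %d is not a proper rotation", i),
             call. = FALSE)
      }
    }
    return(mk(rot, df$time_s))
  }
  if (identical(hdr, .EULER_HEADER)) {
    e <- as.matrix(df[, c("fe_z", "abad_y", "lar_x")])
    if (any(!is.finite(e))) {
      stop("validation error: non-finite Euler angle", call. = FALSE)
    }
    return(mk(euler_to_matrix_many(e), df$time_s))
  }
  stop("format error: header matches neither the matrix nor the Euler pose-table layout",
       call. = FALSE)
}

#' Write a pose-sequence table
#'
#' @param seq A [pose_sequence()].
#' @param path Output CSV path.
#' @param form `"matrix"` (row-major r11..r33) or `"euler"` (degrees).
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(seq, path, form = c("matrix", "euler")) {
  stopifnot(inherits(seq, "pose_sequence"))
  form <- match.arg(form)
  m <- seq$meta
  hdr <- character(0)
  for (k in c("specimen", "joint", "side", "context", "trial", "sequence")) {
    if (!is.na(m[[k]])) hdr <- c(hdr, sprintf("# %s=%s", k, m[[k]]))
  }
  hdr <- c(hdr, sprintf("# rate_hz=%g", seq$rate_hz))
  n <- length(seq)
  if (form == "matrix") {
    flat <- t(apply(seq$rotations, 3L, function(r) as.numeric(t(r))))
    df <- data.frame(frame = seq_len(n), time_s = seq$times, flat)
    names(df) <- .MATRIX_HEADER
  } else {
    e <- matrix_to_euler_many(seq$rotations)
    df <- data.frame(frame = seq_len(n), time_s = seq$times,
                     fe_z = e[, 1L], abad_y = e[, 2L], lar_x = e[, 3L])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an integer-rounded RoM table
#'
#' Writes the [rom_table()] view of one or more summaries as CSV with a
#' deterministic column order; re-reading reproduces the rounded values
#' exactly.
#'
#' @param summaries List of [rom_summary()] objects (or a single one).
#' @param path Output CSV path.
#' @param specimen Optional specimen labels.
#' @return The written data.frame, invisibly.
#' @export
write_rom_table <- function(summaries, path, specimen = NULL) {
  if (inherits(summaries, "rom_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop("empty-input: no summaries to write", call. = FALSE)
  tab <- rom_table(summaries, specimen = specimen)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Read a RoM table written by [write_rom_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_rom_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read landmarks from CSV or JSON
#'
#' CSV layout: `name,region,x,y,z` with `region` in `proximal_perimeter`,
#' `distal_perimeter`, `reference`. JSON layout: an object with those keys
#' (arrays of 3-vectors; `reference` a named object).
#'
#' @param path File path (`.csv` or `.json`).
#' @param bone,side Labels for the resulting [landmark_set()].
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, bone = "long_bone", side = "right") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    refs <- as.list(as.data.frame(t(j$reference)))
    return(landmark_set(j$proximal_perimeter, j$distal_perimeter,
                        reference_points = refs, bone = bone, side = side))
  }
  df <- utils::read.csv(path)
  need <- c("name", "region", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("format error: landmark CSV needs columns name,region,x,y,z",
         call. = FALSE)
  }
  if (!is.numeric(df$x) || !is.numeric(df$y) || !is.numeric(df$z) ||
      anyNA(df[, c("x", "y", "z")])) {
    stop("validation error: non-numeric landmark coordinates", call. = FALSE)
  }
  pick <- function(region) as.matrix(df[df$region == region, c("x", "y", "z")])
  refs_df <- df[df$region == "reference", ]
  refs <- stats::setNames(
    lapply(seq_len(nrow(refs_df)),
           function(i) as.numeric(refs_df[i, c("x", "y", "z")])),
    refs_df$name)
  landmark_set(pick("proximal_perimeter"), pick("distal_perimeter"),
               reference_points = refs, bone = bone, side = side)
}

#' Export an ACS as JSON
#'
#' @param a An `acs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acs_json <- function(a, path) {
  stopifnot(inherits(a, "acs"))
  rep_ <- validate_acs(a, tol = 1e-9)
  jsonlite::write_json(
    list(origin = a$origin, x_axis = a$x_axis, y_axis = a$y_axis,
         z_axis = a$z_axis, bone = a$bone, side = a$side,
         residuals = rep_[c("orthogonality", "unit_norm", "handedness")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ACS from JSON
#' @param path JSON path.
#' @return An `acs` object.
#' @export
read_acs_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_acs(j$origin, j$x_axis, j$y_axis, j$z_axis, j$bone, j$side)
}

#' Export an SFP trace as JSON
#'
#' Writes `{"x": [[x,y,z],...], "y": ..., "z": ...}` tip lists (one unit
#' vector per frame per axis).
#'
#' @param trace An `sfp_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfp_json <- function(trace, path) {
  stopifnot(inherits(trace, "sfp_trace"))
  jsonlite::write_json(list(x = trace$x_tips, y = trace$y_tips,
                            z = trace$z_tips),
                       path, digits = NA)
  invisible(path)
}

#' Published salamander hindlimb RoM reference table
#'
#' The published extremal Euler poses (Z, Y, X = FE, ABAD, LAR, integer
#' degrees) and printed per-axis ranges for fire-salamander hip and knee
#' joints: four ex vivo hips (Sal10-Sal14), two ex vivo knees (Sal06,
#' Sal08) and the in vivo individual (Sal22). Used as the worked example
#' for the RoM-table arithmetic: the printed range is computed before
#' rounding, so in a handful of cells it differs by 1 degree from
#' rounded-max minus rounded-min.
#'
#' @return data.frame with columns `joint`, `specimen`, `context`, `axis`,
#'   `max_fe`, `max_abad`, `max_lar`, `min_fe`, `min_abad`, `min_lar`,
#'   `printed_range`. The `max_*`/`min_*` triples are the full poses at the
#'   extremes of `axis` (concomitant angles included).
#' @export
salamander_rom_reference <- function() {
  path <- system.file("extdata", "salamander_rom_tables.csv",
                      package = "romsfp", mustWork = TRUE)
  utils::read.csv(path)
}

#' Read a run configuration from YAML
#'
#' Keys: file paths, joint conventions, region `method` and `alpha_deg`,
#' `jump_threshold_deg`, `round` toggle, `seed`. Returns defaults merged
#' with whatever the file supplies.
#'
#' @param path YAML path (optional; omit for all defaults).
#' @return Named list of configuration values.
#' @export
run_config <- function(path = NULL) {
  cfg <- list(method = "convex_hull", alpha_deg = 15,
              jump_threshold_deg = 15, round = TRUE, seed = 1L)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read config files", call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!cfg$method %in% c("convex_hull", "alpha_shape")) {
    stop("validation error: method must be convex_hull or alpha_shape",
         call. = FALSE)
  }
  cfg
}
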