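# Spherical frame projections (SFPs): the pose space of a joint traced as
# the tips of the distal ACS's unit axes on a sphere fixed in the proximal
# ACS. Regions on the sphere are built and queried through a gnomonic chart
# about the tips' spherical centroid (great circles map to straight lines,
# so a spherical convex hull is the planar hull in the chart).

.AXIS_ROLES <- c(x = "LAR", y = "ABAD", z = "FE")
.AXIS_COLORS <- c(x = "red", y = "green", z = "blue")

#' Project a pose sequence onto the sphere
#'
#' For every frame, the three columns of the relative rotation matrix are the
#' distal X (LAR), Y (ABAD) and Z (FE) unit axes expressed in the proximal
#' frame; their tips trace the SFP. Role/colour mapping follows the standard
#' convention blue = FE (z), green = ABAD (y), red = LAR (x).
#'
#' @param seq A [pose_sequence()] of relative rotations.
#' @return Object of class `sfp_trace`: list with `x_tips`, `y_tips`,
#'   `z_tips` (n x 3 matrices of unit vectors) and `meta`.
#' @export
project_sfp <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  r <- seq$rotations
  structure(list(x_tips = t(r[, 1L, , drop = TRUE]),
                 y_tips = t(r[, 2L, , drop = TRUE]),
                 z_tips = t(r[, 3L, , drop = TRUE]),
                 meta = c(seq$meta, list(roles = .AXIS_ROLES,
                                         colors = .AXIS_COLORS))),
            class = "sfp_trace")
}

# Orthonormal tangent basis at unit vector c.
.tangent_basis <- function(ctr) {
  seed <- if (abs(ctr[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(cross3(ctr, seed))
  v <- cross3(ctr, u)
  list(u = u, v = v)
}

# Gnomonic projection of unit vectors (rows of `tips`) into the tangent
# plane at `ctr`; errors if any tip is at or beyond 90 deg from `ctr`.
.gnomonic <- function(tips, ctr, basis, guard = TRUE) {
  w <- tips %*% ctr
  if (guard && any(w <= 1e-6)) {
    stop("region-too-large: tips span a hemisphere or more about their centroid; split the data",
         call. = FALSE)
  }
  cbind(tips %*% basis$u, tips %*% basis$v) / as.numeric(w)
}

.ungnomonic <- function(xy, ctr, basis) {
  p <- outer(rep(1, nrow(xy)), ctr) + outer(xy[, 1L], basis$u) +
    outer(xy[, 2L], basis$v)
  p / sqrt(rowSums(p^2))
}

#' Build a spherical region from axis-tip points
#'
#' The tips are projected gnomonically about their spherical centroid (they
#' must fit in an open hemisphere); the region boundary is the planar convex
#' hull (default), or for `method = "alpha_shape"` the contour of the
#' nearest-tip distance field at `alpha_deg` — the boundary of the union of
#' spherical caps of radius `alpha_deg` around the tips, which hugs
#' non-convex pose spaces. The alpha method assumes a connected tip cloud
#' (the longest closed contour is kept); split disconnected data into
#' separate regions. The boundary is returned in counterclockwise order
#' viewed from outside the sphere.
#'
#' @param tips n x 3 matrix of unit vectors (n >= 3 distinct).
#' @param method `"convex_hull"` or `"alpha_shape"`.
#' @param alpha_deg Cap radius in degrees for the alpha method (default 15).
#' @param axis_role Which axis tip this region summarises (`"x"`, `"y"`,
#'   `"z"`), recorded as metadata.
#' @return Object of class `spherical_region` with `boundary` (m x 3 unit
#'   vectors), `centroid`, `max_angular_radius` (deg), `method`, plus the
#'   chart (`basis`, planar `boundary_xy`) used for membership tests.
#' @export
build_region <- function(tips, method = c("convex_hull", "alpha_shape"),
                         alpha_deg = 15, axis_role = NA_character_) {
  method <- match.arg(method)
  tips <- as_points(tips)
  nrm <- sqrt(rowSums(tips^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("invalid-input: tips must be unit vectors", call. = FALSE)
  }
  tips <- tips / nrm
  if (nrow(unique(round(tips, 9))) < 3L) {
    stop("degenerate-geometry: need at least 3 distinct tips", call. = FALSE)
  }
  ctr <- colMeans(tips)
  if (sqrt(sum(ctr^2)) < 1e-9) {
    stop("region-too-large: tips have no well-defined spherical centroid",
         call. = FALSE)
  }
  ctr <- normalize(ctr)
  basis <- .tangent_basis(ctr)
  xy <- .gnomonic(tips, ctr, basis)
  if (method == "convex_hull") {
    xyu <- unique(xy)                           # duplicates perturb chull
    h <- grDevices::chull(xyu[, 1L], xyu[, 2L]) # clockwise
    bxy <- xyu[rev(h), , drop = FALSE]          # counterclockwise
  } else {
    bxy <- .alpha_boundary(xy, tips, ctr, alpha_deg)
  }
  if (nrow(bxy) < 3L) {
    stop("degenerate-geometry: boundary collapsed below 3 vertices", call. = FALSE)
  }
  bnd <- .ungnomonic(bxy, ctr, basis)
  maxr <- max(rad2deg(acos(pmin(1, tips %*% ctr))))
  structure(list(axis_role = axis_role, boundary = bnd, centroid = ctr,
                 max_angular_radius = maxr, method = method,
                 alpha_deg = if (method == "alpha_shape") alpha_deg else NA_real_,
                 basis = basis, boundary_xy = bxy),
            class = "spherical_region")
}

# Union-of-caps boundary: contour the angular distance to the nearest tip at
# alpha_deg on a grid in the gnomonic chart, keep the longest closed contour.
.alpha_boundary <- function(xy, tips, ctr, alpha_deg, n_grid = 161L) {
  # thin dense tip clouds to ~alpha/5 resolution: the union of caps is
  # unchanged up to that scale and the distance field stays tractable
  cell <- tan(deg2rad(max(alpha_deg / 5, 0.25)))
  keep <- !duplicated(round(xy / cell))
  tips <- tips[keep, , drop = FALSE]
  # grid sized by angular extent: the dilated region reaches at most
  # max tip angle + alpha from the centroid, and the gnomonic chart
  # stretches as tan() toward the rim
  maxang <- max(rad2deg(acos(pmin(1, tips %*% ctr))))
  reach <- maxang + 1.5 * alpha_deg
  if (reach >= 88) {
    stop("region-too-large: tips dilated by alpha_deg approach the hemisphere rim",
         call. = FALSE)
  }
  L <- tan(deg2rad(reach))
  gx <- seq(-L, L, length.out = n_grid)
  gy <- gx
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  basis <- .tangent_basis(ctr)
  gpts <- .ungnomonic(grid, ctr, basis)
  # angular distance from each grid point to its nearest tip (chunked)
  best <- rep(-1, nrow(gpts))
  step <- max(1L, floor(2e7 / max(nrow(gpts), 1L)))
  for (j in seq(1L, nrow(tips), by = step)) {
    jj <- j:min(j + step - 1L, nrow(tips))
    best <- pmax(best, apply(gpts %*% t(tips[jj, , drop = FALSE]), 1L, max))
  }
  dmin <- rad2deg(acos(pmin(1, best)))
  z <- matrix(dmin, nrow = n_grid)
  cl <- grDevices::contourLines(gx, gy, z, levels = alpha_deg)
  if (!length(cl)) {
    stop("degenerate-geometry: alpha contour not found; increase alpha_deg",
         call. = FALSE)
  }
  cell_sz <- 2 * L / (n_grid - 1L)
  closed <- vapply(cl, function(c_) {
    sqrt((c_$x[1L] - c_$x[length(c_$x)])^2 +
           (c_$y[1L] - c_$y[length(c_$y)])^2) < 2 * cell_sz
  }, logical(1))
  if (!any(closed)) {
    stop("degenerate-geometry: no closed alpha contour; increase alpha_deg or split the data",
         call. = FALSE)
  }
  cl <- cl[closed]
  best <- cl[[which.max(vapply(cl, function(c_) length(c_$x), 0))]]
  bxy <- cbind(best$x, best$y)
  if (sqrt(sum((bxy[1L, ] - bxy[nrow(bxy), ])^2)) < 1e-9) {
    bxy <- bxy[-nrow(bxy), , drop = FALSE]
  }
  # enforce counterclockwise orientation (positive signed area)
  area <- sum(bxy[, 1L] * bxy[c(2:nrow(bxy), 1L), 2L] -
                bxy[c(2:nrow(bxy), 1L), 1L] * bxy[, 2L]) / 2
  if (area < 0) bxy <- bxy[rev(seq_len(nrow(bxy))), , drop = FALSE]
  bxy
}

#' Point-in-region test on the sphere
#'
#' Membership is evaluated in the region's own gnomonic chart: a half-plane
#' test against each hull edge for convex regions, a crossing-number test
#' with an on-boundary tolerance otherwise. Boundary points count as inside
#' (closed region); points outside the region's hemisphere return `FALSE`.
#'
#' @param p Unit 3-vector, or an n x 3 matrix of unit vectors.
#' @param region A [build_region()] result.
#' @param tol Planar tolerance for the closed-boundary convention.
#' @return Logical (vector).
#' @export
point_in_region <- function(p, region, tol = 1e-9) {
  stopifnot(inherits(region, "spherical_region"))
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  p <- as_points(p)
  p <- p / sqrt(rowSums(p^2))
  w <- as.numeric(p %*% region$centroid)
  inside <- rep(FALSE, nrow(p))
  ok <- w > 1e-6
  if (!any(ok)) return(inside)
  xy <- .gnomonic(p[ok, , drop = FALSE], region$centroid, region$basis,
                  guard = FALSE)
  b <- region$boundary_xy
  nb <- nrow(b)
  nxt <- c(2:nb, 1L)
  if (region$method == "convex_hull") {
    res <- rep(TRUE, nrow(xy))
    for (i in seq_len(nb)) {
      e <- b[nxt[i], ] - b[i, ]
      # boundary is counterclockwise: interior has non-negative cross product
      cr <- e[1L] * (xy[, 2L] - b[i, 2L]) - e[2L] * (xy[, 1L] - b[i, 1L])
      res <- res & (cr >= -tol * max(1, sqrt(sum(e^2))))
    }
  } else {
    res <- .crossing_inside(xy, b, tol)
  }
  inside[ok] <- res
  inside
}

# Crossing-number point-in-polygon with an on-edge tolerance (closed region).
.crossing_inside <- function(xy, b, tol) {
  nb <- nrow(b)
  nxt <- c(2:nb, 1L)
  n <- nrow(xy)
  res <- logical(n)
  for (k in seq_len(n)) {
    x <- xy[k, 1L]; y <- xy[k, 2L]
    crossings <- 0L
    on_edge <- FALSE
    for (i in seq_len(nb)) {
      x1 <- b[i, 1L]; y1 <- b[i, 2L]; x2 <- b[nxt[i], 1L]; y2 <- b[nxt[i], 2L]
      # distance to segment
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t_ <- if (len2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2)) else 0
      d2 <- (x - (x1 + t_ * dx))^2 + (y - (y1 + t_ * dy))^2
      if (d2 <= tol * tol * max(1, len2)) { on_edge <- TRUE; break }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * dx
        if (x < xint) crossings <- crossings + 1L
      }
    }
    res[k] <- on_edge || (crossings %% 2L == 1L)
  }
  res
}
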