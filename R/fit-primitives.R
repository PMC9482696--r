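# Least-squares geometric primitives used for ACS construction.
# Points are n x 3 matrices in mm throughout.

as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || anyNA(points)) {
    stop("degenerate-geometry: points must be an n x 3 numeric matrix",
         call. = FALSE)
  }
  points
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate-geometry: zero-length direction", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Total-least-squares line fit
#'
#' Fits a line through a 3D point cloud: the line passes through the centroid
#' along the first principal axis of the points. The direction sign is
#' canonicalized toward `reference` (if given) or lexicographically (first
#' nonzero component positive).
#'
#' @param points n x 3 matrix (n >= 2 distinct points), mm.
#' @param reference Optional 3-vector; the returned direction has positive dot
#'   product with `reference - centroid`.
#' @return List with `point` (centroid), `direction` (unit 3-vector) and
#'   `rms_residual` (mm, perpendicular distances).
#' @export
fit_line <- function(points, reference = NULL) {
  p <- as_points(points)
  if (nrow(unique(round(p, 12))) < 2L) {
    stop("degenerate-geometry: need at least 2 distinct points for a line",
         call. = FALSE)
  }
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  sv <- svd(q, nu = 0L, nv = 3L)
  dir <- sv$v[, 1L]
  if (!is.null(reference)) {
    s <- sum(dir * (reference - ctr))
    if (s < 0) dir <- -dir
  } else {
    nz <- which(abs(dir) > 1e-12)[1L]
    if (dir[nz] < 0) dir <- -dir
  }
  perp <- q - tcrossprod(q %*% dir, dir)
  list(point = ctr, direction = dir,
       rms_residual = sqrt(mean(rowSums(perp^2))))
}

#' Least-squares sphere fit
#'
#' Algebraic least squares (linear system in center and radius) followed by
#' geometric Gauss-Newton refinement of the summed squared radial residuals.
#' Used for acetabular articular surfaces.
#'
#' @param points n x 3 matrix, n >= 4, not coplanar, mm.
#' @return List of class `sphere_primitive`: `center` (3-vector, mm),
#'   `radius` (mm), `rms_residual` (mm).
#' @export
fit_sphere <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 4L) {
    stop("degenerate-geometry: sphere fit needs at least 4 points", call. = FALSE)
  }
  # coplanarity / conditioning guard
  q <- sweep(p, 2L, colMeans(p))
  sv <- svd(q, nu = 0L, nv = 0L)$d
  if (sv[3L] < 1e-8 * max(sv[1L], 1)) {
    stop("degenerate-geometry: points are (nearly) coplanar; sphere fit ill-posed",
         call. = FALSE)
  }
  # algebraic fit: |x|^2 = 2 c.x + (r^2 - |c|^2)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  ctr <- sol[1:3]
  r <- sqrt(max(sol[4L] + sum(ctr^2), 1e-12))
  # geometric refinement
  obj <- function(th) {
    d <- sqrt(rowSums(sweep(p, 2L, th[1:3])^2))
    sum((d - th[4L])^2)
  }
  opt <- stats::optim(c(ctr, r), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  ctr <- opt$par[1:3]; r <- opt$par[4L]
  if (r <= 0) stop("degenerate-geometry: sphere fit collapsed", call. = FALSE)
  d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
  structure(list(center = unname(ctr), radius = unname(r),
                 rms_residual = sqrt(mean((d - r)^2))),
            class = "sphere_primitive")
}

#' Least-squares cylinder fit
#'
#' Axis initialised from the first principal component of the points, then
#' axis direction, axis point and radius refined jointly by minimising squared
#' radial residuals. Used for the sacral vertebral body.
#'
#' @param points n x 3 matrix, n >= 6, with nonzero extent along one
#'   direction, mm.
#' @param caudal_reference Optional 3-vector; axis direction sign is chosen to
#'   point toward it.
#' @return List of class `cylinder_primitive`: `axis_point` (3-vector, mm),
#'   `axis_direction` (unit 3-vector), `radius` (mm), `rms_residual` (mm).
#' @export
fit_cylinder <- function(points, caudal_reference = NULL) {
  p <- as_points(points)
  if (nrow(p) < 6L) {
    stop("degenerate-geometry: cylinder fit needs at least 6 points", call. = FALSE)
  }
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  sv <- svd(q, nu = 0L, nv = 3L)
  if (sv$d[1L] < 1e-10) {
    stop("degenerate-geometry: all points coincide", call. = FALSE)
  }
  # parametrize axis direction by spherical angles, axis point by its 2
  # components perpendicular to the direction (in a local basis), plus radius
  dir0 <- sv$v[, 1L]
  ang0 <- c(acos(pmin(1, pmax(-1, dir0[3L]))), atan2(dir0[2L], dir0[1L]))
  resid <- function(dir, pt) {
    rel <- sweep(p, 2L, pt)
    axial <- rel %*% dir
    sqrt(pmax(rowSums(rel^2) - axial^2, 0))
  }
  obj <- function(th) {
    dir <- c(sin(th[1L]) * cos(th[2L]), sin(th[1L]) * sin(th[2L]), cos(th[1L]))
    pt <- ctr + th[3L] * sv$v[, 2L] + th[4L] * sv$v[, 3L]
    d <- resid(dir, pt)
    sum((d - mean(d))^2)   # radius profiled out as mean radial distance
  }
  opt <- stats::optim(c(ang0, 0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  th <- opt$par
  dir <- c(sin(th[1L]) * cos(th[2L]), sin(th[1L]) * sin(th[2L]), cos(th[1L]))
  pt <- ctr + th[3L] * sv$v[, 2L] + th[4L] * sv$v[, 3L]
  d <- resid(dir, pt)
  r <- mean(d)
  if (!is.finite(r) || r < 1e-9) {
    stop("degenerate-geometry: cylinder fit collapsed (radius ~ 0)", call. = FALSE)
  }
  if (stats::sd(d) > 0.5 * r && diff(range(p %*% dir)) < 1e-6 * r) {
    stop("degenerate-geometry: no cylindrical structure in points", call. = FALSE)
  }
  if (!is.null(caudal_reference)) {
    if (sum(dir * (caudal_reference - pt)) < 0) dir <- -dir
  }
  structure(list(axis_point = unname(pt), axis_direction = unname(dir),
                 radius = unname(r),
                 rms_residual = sqrt(mean((d - r)^2))),
            class = "cylinder_primitive")
}
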