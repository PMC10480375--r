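#' Rigid transform (rotation + translation)
#'
#' Maps points from a moving scan's frame into a fixed scan's frame as
#' `R p + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation 3-vector (mm).
#' @param tol orthonormality tolerance.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > tol ||
      abs(det(rotation) - 1) > tol)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle", format(rotation_angle_deg(x), digits = 5),
      "deg, translation", format(sqrt(sum(x$translation^2)), digits = 5), "mm\n")
  invisible(x)
}

#' Apply a rigid transform to points or a mesh
#' @param transform a `rigid_transform`.
#' @param x an n x 3 point matrix, a `triangle_mesh`, or a `landmark_set`.
#' @return object of the same type, transformed.
#' @export
apply_transform <- function(transform, x) {
  if (is_triangle_mesh(x)) {
    v <- apply_transform(transform, x$vertices)
    return(triangle_mesh(v, x$faces, oriented = mesh_is_oriented(x)))
  }
  if (inherits(x, "landmark_set")) {
    p <- apply_transform(transform, unclass(x))
    return(landmark_set(p, labels = attr(x, "labels")))
  }
  p <- matrix(as.numeric(x), ncol = 3)
  sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms (`b` applied after `a`)
#' @param a,b `rigid_transform` objects.
#' @return the composite `rigid_transform` `x -> b(a(x))`.
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rotation angle of a rigid transform in degrees
#' @param transform a `rigid_transform`.
#' @return scalar angle in degrees.
#' @export
rotation_angle_deg <- function(transform) {
  ctheta <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Convert to/from a 4x4 homogeneous matrix
#' @param transform a `rigid_transform`.
#' @return 4x4 numeric matrix.
#' @export
transform_to_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname transform_to_matrix
#' @param m a 4x4 homogeneous matrix.
#' @export
transform_from_matrix <- function(m) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write / read a transform as a plain-text row-major 4x4 matrix
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @return the path (write) or a `rigid_transform` (read).
#' @export
write_transform <- function(transform, path) {
  m <- transform_to_matrix(transform)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  transform_from_matrix(m)
}

#' Weighted Kabsch rigid alignment of corresponded point sets
#'
#' Returns the rigid transform minimizing the weighted sum of squared
#' distances `sum w_i ||R s_i + t - t_i||^2` via the SVD of the weighted
#' cross-covariance (determinant-corrected so no reflection is returned).
#'
#' @param source n x 3 matrix of source points (mm).
#' @param target n x 3 matrix of corresponding target points.
#' @param weights optional non-negative weights (default uniform).
#' @return a `rigid_transform` with attributes `rms` (weighted residual RMS,
#'   mm) and `n_used` (points with positive weight).
#' @export
kabsch <- function(source, target, weights = NULL) {
  source <- matrix(as.numeric(source), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  n <- nrow(source)
  stopifnot(nrow(target) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  keep <- weights > 0
  if (sum(keep) < 3 || sum(weights) <= 0)
    stop("need at least 3 positively weighted point pairs", call. = FALSE)
  w <- weights[keep] / sum(weights[keep])
  s <- source[keep, , drop = FALSE]
  t_ <- target[keep, , drop = FALSE]
  cs <- colSums(s * w)
  ct <- colSums(t_ * w)
  sc <- sweep(s, 2, cs)
  tc <- sweep(t_, 2, ct)
  H <- t(sc * w) %*% tc
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: points are (nearly) collinear", call. = FALSE)
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, sign(d))) %*% t(sv$u)
  tr <- ct - as.numeric(R %*% cs)
  out <- rigid_transform(R, tr)
  res <- sc %*% t(R) - tc
  attr(out, "rms") <- sqrt(sum(w * rowSums(res^2)))
  attr(out, "n_used") <- sum(keep)
  out
}

#' Coarse three-point alignment
#'
#' Least-squares rigid transform (Kabsch on the three correspondences, no
#' scaling) mapping the moving landmark triple onto the fixed one.
#'
#' @param moving_landmarks,fixed_landmarks `landmark_set` objects in the same
#'   correspondence order.
#' @return a `rigid_transform` with attribute `rms` (residual RMS, mm).
#' @export
three_point_align <- function(moving_landmarks, fixed_landmarks) {
  stopifnot(inherits(moving_landmarks, "landmark_set"),
            inherits(fixed_landmarks, "landmark_set"))
  kabsch(unclass(moving_landmarks), unclass(fixed_landmarks))
}

#' Default ICP parameters
#'
#' @param max_iterations maximum ICP iterations. Point-to-point ICP converges
#'   slowly along surface-sliding directions, so the default is generous.
#' @param tolerance stop when the weighted RMS changes by less than this (mm).
#' @param max_correspondence_dist correspondences farther than this (mm) are
#'   discarded each iteration.
#' @param max_points at most this many positively weighted moving vertices
#'   are used (deterministic stride subsample); residual misalignment, not
#'   point count, limits accuracy on scan-density meshes.
#' @param rms_gate post-refinement weighted RMS above this (mm) raises a
#'   registration-quality warning (the numeric stand-in for visual
#'   confirmation of the match).
#' @return a list of parameters.
#' @export
icp_params <- function(max_iterations = 200, tolerance = 1e-6,
                       max_correspondence_dist = 5, max_points = 3000,
                       rms_gate = 0.5) {
  list(max_iterations = as.integer(max_iterations),
       tolerance = tolerance,
       max_correspondence_dist = max_correspondence_dist,
       max_points = as.integer(max_points),
       rms_gate = rms_gate)
}

#' Weighted iterative closest point refinement
#'
#' Point-to-point ICP: weighted moving vertices are corresponded to their
#' nearest points on the fixed surface (closest point on triangle via a
#' spatial grid), a weighted Kabsch fit is solved, and the loop repeats until
#' the weighted RMS stops improving. Vertices with weight zero (e.g. the
#' augmented region) never influence the result.
#'
#' @param moving,fixed `triangle_mesh` objects.
#' @param weights per-vertex weights for `moving` (default uniform).
#' @param init initial `rigid_transform`, typically from
#'   [three_point_align()]; default identity.
#' @param params see [icp_params()].
#' @return a `rigid_transform` (cumulative, maps original moving frame onto
#'   fixed) with attributes `trace` (per-iteration weighted RMS, mm),
#'   `rms` (final weighted RMS), `iterations`, and `quality_ok` (final RMS
#'   below the gate).
#' @export
weighted_icp <- function(moving, fixed, weights = NULL,
                         init = rigid_transform(), params = icp_params()) {
  if (is.null(weights)) weights <- rep(1, n_vertices(moving))
  weights <- vertex_weights(weights)
  stopifnot(length(weights) == n_vertices(moving))
  sel <- which(weights > 0)
  mp <- params$max_points
  if (!is.null(mp) && length(sel) > mp)
    sel <- sel[round(seq(1, length(sel), length.out = mp))]
  src <- moving$vertices[sel, , drop = FALSE]
  w <- weights[sel]

  current <- init
  trace <- numeric(0)
  prev_rms <- Inf
  iterations <- 0L
  for (it in seq_len(params$max_iterations)) {
    pts <- apply_transform(current, src)
    cp <- cpp_closest_points(fixed$vertices, fixed$faces, pts)
    ok <- cp$dist <= params$max_correspondence_dist
    if (sum(ok) < 3)
      stop("insufficient overlap: fewer than 3 correspondences within the ",
           "distance cap", call. = FALSE)
    fit <- kabsch(src[ok, , drop = FALSE], cp$points[ok, , drop = FALSE],
                  w[ok])
    current <- fit
    # RMS at the updated pose over the accepted correspondences
    resid <- apply_transform(current, src[ok, , drop = FALSE]) -
      cp$points[ok, , drop = FALSE]
    rms <- sqrt(sum(w[ok] * rowSums(resid^2)) / sum(w[ok]))
    trace <- c(trace, rms)
    iterations <- it
    if (abs(prev_rms - rms) < params$tolerance) break
    prev_rms <- rms
  }
  quality_ok <- trace[length(trace)] <= params$rms_gate
  if (!quality_ok)
    warning(sprintf(
      "registration quality gate: final weighted RMS %.3f mm exceeds %.3f mm",
      trace[length(trace)], params$rms_gate), call. = FALSE)
  structure(current, trace = trace, rms = trace[length(trace)],
            iterations = iterations, quality_ok = quality_ok)
}
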