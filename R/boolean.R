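#' Axis-aligned box mesh
#' @param min,max opposite corners (mm).
#' @return a watertight `triangle_mesh` (12 triangles, outward normals).
#' @export
make_box_mesh <- function(min, max) {
  lo <- as.numeric(min); hi <- as.numeric(max)
  stopifnot(all(hi > lo))
  corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                   z = c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 4), c(1, 4, 2),    # z = lo
             c(5, 6, 8), c(5, 8, 7),    # z = hi
             c(1, 2, 6), c(1, 6, 5),    # y = lo
             c(3, 7, 8), c(3, 8, 4),    # y = hi
             c(1, 5, 7), c(1, 7, 3),    # x = lo
             c(2, 4, 8), c(2, 8, 6))    # x = hi
  triangle_mesh(corners, f, oriented = TRUE)
}

#' Dual region-of-interest pair
#'
#' The outer solid is intersected with the baseline, the slightly scaled-down
#' inner copy with the augmented scans; the size offset guarantees that the
#' baseline walls fully cover the augmented walls so the Boolean subtraction
#' leaves only the grafted volume.
#'
#' @param shape a watertight `triangle_mesh`, or `list(min=, max=)` for an
#'   axis-aligned box.
#' @param scale scale factor for the inner copy, strictly between 0.9 and 1
#'   (default 0.98), applied about the solid's volume centroid.
#' @return an `roi_pair` with elements `outer` and `inner`.
#' @export
make_roi_pair <- function(shape, scale = 0.98) {
  if (!is_triangle_mesh(shape)) {
    stopifnot(is.list(shape), !is.null(shape$min), !is.null(shape$max))
    shape <- make_box_mesh(shape$min, shape$max)
  }
  s <- mesh_summary(shape)
  if (!s$closed) stop("ROI shape must be watertight", call. = FALSE)
  if (!(scale > 0.9 && scale < 1.0))
    stop("ROI scale must be strictly between 0.9 and 1", call. = FALSE)
  if (!mesh_is_oriented(shape)) shape <- normalize_orientation(shape)
  inner <- scale_mesh(shape, scale, center = mesh_centroid(shape))
  structure(list(outer = shape, inner = inner, scale = scale),
            class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("roi_pair: outer %.2f mm^3, inner %.2f mm^3 (scale %.3f)\n",
              enclosed_volume(x$outer)$volume_mm3,
              enclosed_volume(x$inner)$volume_mm3, x$scale))
  invisible(x)
}

# --- lattice CSG backend -----------------------------------------------------

default_voxel_mm <- function() getOption("augvol.voxel_mm", 0.1)

# grid snapped to the global lattice (origins at multiples of h) so chained
# Boolean operations on the same lattice are exact
lattice_grid <- function(lo, hi, h, pad = 2L) {
  i0 <- floor(lo / h) - pad
  i1 <- ceiling(hi / h) + pad
  list(origin = i0 * h, h = h, dims = as.integer(i1 - i0))
}

voxelize_on_grid <- function(mesh, grid) {
  cpp_voxelize(mesh$vertices, mesh$faces, grid$origin, grid$h,
               grid$dims[1], grid$dims[2], grid$dims[3])
}

mesh_from_voxels <- function(inside, grid) {
  if (!any(inside)) return(empty_mesh())
  surf <- cpp_extract_surface(inside, grid$dims[1], grid$dims[2],
                              grid$dims[3], grid$origin, grid$h)
  triangle_mesh(surf$vertices, surf$faces, oriented = TRUE)
}

empty_mesh <- function() {
  structure(triangle_mesh(matrix(numeric(0), 0, 3),
                          matrix(integer(0), 0, 3), oriented = TRUE),
            empty = TRUE)
}

#' Is a Boolean result empty?
#' @param mesh a `triangle_mesh`.
#' @return logical.
#' @export
is_empty_mesh <- function(mesh) n_faces(mesh) == 0

check_boolean_input <- function(mesh, what) {
  es <- cpp_edge_stats(mesh$faces, n_vertices(mesh))
  if (!isTRUE(es$directed_balanced))
    stop(what, " mesh must be watertight for Boolean operations",
         call. = FALSE)
  invisible(TRUE)
}

#' Boolean intersection of two watertight solids
#'
#' Computed on a voxel lattice: both solids are rasterized by vertical
#' ray-parity point-in-solid tests at voxel centers on a shared grid snapped
#' to the global lattice, combined, and the boundary surface extracted. This
#' trades exactness at the voxel scale for robustness on noisy scan meshes;
#' the lattice resolution is configurable.
#'
#' @param a,b watertight `triangle_mesh` solids.
#' @param voxel_mm lattice pitch in mm (default `getOption("augvol.voxel_mm",
#'   0.1)`).
#' @return a watertight `triangle_mesh`; an empty intersection yields an empty
#'   mesh (see [is_empty_mesh()]), not an error.
#' @export
boolean_intersect <- function(a, b, voxel_mm = default_voxel_mm()) {
  check_boolean_input(a, "first")
  check_boolean_input(b, "second")
  ba <- mesh_bbox(a); bb <- mesh_bbox(b)
  lo <- pmax(ba$min, bb$min); hi <- pmin(ba$max, bb$max)
  if (any(hi <= lo)) return(empty_mesh())
  grid <- lattice_grid(lo, hi, voxel_mm)
  inside <- voxelize_on_grid(a, grid) & voxelize_on_grid(b, grid)
  mesh_from_voxels(inside, grid)
}

#' Boolean subtraction of the baseline solid from the augmented solid
#'
#' `a - b` on the shared voxel lattice. In the pipeline `a` is the augmented
#' solid already intersected with the inner ROI and `b` the baseline solid
#' intersected with the outer ROI, so the remaining volume is the graft.
#'
#' @inheritParams boolean_intersect
#' @return a watertight `triangle_mesh`, possibly with several components.
#' @export
boolean_subtract <- function(a, b, voxel_mm = default_voxel_mm()) {
  check_boolean_input(a, "first")
  check_boolean_input(b, "second")
  ba <- mesh_bbox(a)
  grid <- lattice_grid(ba$min, ba$max, voxel_mm)
  inside <- voxelize_on_grid(a, grid) & !voxelize_on_grid(b, grid)
  mesh_from_voxels(inside, grid)
}

#' Drop disconnected fragments of a Boolean difference
#'
#' Free-floating particles that do not belong to the main augmented region are
#' removed. Components are found by face adjacency; per-component volumes
#' decide what is kept.
#'
#' @param diff a non-empty `triangle_mesh`, possibly multi-component.
#' @param policy `"largest"` keeps the single largest-volume component
#'   (ties broken deterministically by the lexicographically smallest minimum
#'   vertex coordinate); `"threshold"` keeps every component whose volume is
#'   at least `threshold` times the largest.
#' @param threshold fraction for `policy = "threshold"` (default 0.05).
#' @return the filtered `triangle_mesh`, with attribute `component_volumes`
#'   (mm^3, all components before filtering).
#' @export
drop_disconnected <- function(diff, policy = c("largest", "threshold"),
                              threshold = 0.05) {
  policy <- match.arg(policy)
  if (is_empty_mesh(diff)) stop("empty difference mesh", call. = FALSE)
  if (!mesh_is_oriented(diff)) diff <- normalize_orientation(diff)
  sv <- signed_volume_by_component(diff)
  vols <- abs(sv$volume)
  lab <- sv$labels
  keep <- if (policy == "largest") {
    best <- which(vols >= max(vols) * (1 - 1e-9))
    if (length(best) > 1) {
      # deterministic tie-break: lexicographically smallest minimum vertex
      mins <- t(vapply(best, function(k) {
        vs <- diff$vertices[unique(as.vector(diff$faces[lab == k, ])), ,
                            drop = FALSE]
        vs[do.call(order, as.data.frame(vs))[1], ]
      }, numeric(3)))
      best <- best[do.call(order, as.data.frame(mins))[1]]
    }
    best
  } else {
    which(vols >= threshold * max(vols))
  }
  out <- subset_faces(diff, lab %in% keep)
  attr(out, "component_volumes") <- vols
  out
}

#' Point-in-solid test by ray parity
#'
#' Counts crossings of an upward vertical ray with the surface; odd parity
#' means inside. Independent of the lattice CSG code path; used for
#' containment checks and as a brute-force oracle.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param points n x 3 matrix of query points (mm).
#' @return logical vector.
#' @export
points_in_mesh <- function(mesh, points) {
  points <- matrix(as.numeric(as.matrix(points)), ncol = 3)
  v <- mesh$vertices
  f <- mesh$faces
  # normalize projected winding to CCW so one boundary fill rule suffices
  ax <- v[f[, 1], 1]; ay <- v[f[, 1], 2]; az <- v[f[, 1], 3]
  bx <- v[f[, 2], 1]; by <- v[f[, 2], 2]; bz <- v[f[, 2], 3]
  cx <- v[f[, 3], 1]; cy <- v[f[, 3], 2]; cz <- v[f[, 3], 3]
  w <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  flip <- w < 0
  tmp <- bx[flip]; bx[flip] <- cx[flip]; cx[flip] <- tmp
  tmp <- by[flip]; by[flip] <- cy[flip]; cy[flip] <- tmp
  tmp <- bz[flip]; bz[flip] <- cz[flip]; cz[flip] <- tmp
  w <- abs(w)
  ok <- w > 0
  # boundary ownership rule matching the lattice kernel: an edge counts for
  # the triangle where it runs downward (or leftward when horizontal), so a
  # ray through a shared edge or vertex is counted exactly once; edge
  # functions within eps of zero are snapped so the two incident triangles
  # agree on who owns the boundary despite round-off
  edge_counts <- function(x1, y1, x2, y2)
    ifelse(y1 != y2, y1 > y2, x1 < x2)
  scale2 <- max(abs(range(v)))^2
  eps <- 1e-12 * max(scale2, 1)
  vapply(seq_len(nrow(points)), function(i) {
    px <- points[i, 1]; py <- points[i, 2]; pz <- points[i, 3]
    e0 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
    e1 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
    e2 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    z0 <- abs(e0) < eps; z1 <- abs(e1) < eps; z2 <- abs(e2) < eps
    hit <- ok &
      ((e0 > 0 & !z0) | (z0 & edge_counts(bx, by, cx, cy))) &
      ((e1 > 0 & !z1) | (z1 & edge_counts(cx, cy, ax, ay))) &
      ((e2 > 0 & !z2) | (z2 & edge_counts(ax, ay, bx, by)))
    if (!any(hit)) return(FALSE)
    z <- (e0[hit] * az[hit] + e1[hit] * bz[hit] + e2[hit] * cz[hit]) / w[hit]
    sum(z > pz) %% 2 == 1
  }, logical(1))
}
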