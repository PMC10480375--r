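#' Triangulated surface mesh
#'
#' The universal currency of the pipeline: an indexed triangle mesh with
#' vertices in millimetres. Face normals are always derived from winding
#' order; normals stored in scan files are unreliable and are discarded.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param oriented logical; set by constructors that guarantee a consistent
#'   outward winding (solidified and lattice-extracted surfaces), so that
#'   downstream volume code can skip re-orientation.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, oriented = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("face repeats a vertex index", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh", oriented = isTRUE(oriented))
}

#' @export
print.triangle_mesh <- function(x, ...) {
  s <- mesh_summary(x)
  cat(sprintf(
    "triangle_mesh: %d vertices, %d faces, %d component(s), %s\n",
    s$n_vertices, s$n_faces, s$n_components,
    if (s$watertight) "watertight" else
      sprintf("open (%d boundary edges)", s$n_boundary_edges)))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

n_faces <- function(mesh) nrow(mesh$faces)
n_vertices <- function(mesh) nrow(mesh$vertices)

mesh_is_oriented <- function(mesh) isTRUE(attr(mesh, "oriented"))

#' Axis-aligned bounding box of a mesh
#' @param mesh a `triangle_mesh`.
#' @return list with `min` and `max` 3-vectors (mm).
#' @export
mesh_bbox <- function(mesh) {
  stopifnot(n_vertices(mesh) > 0)
  list(min = apply(mesh$vertices, 2, min),
       max = apply(mesh$vertices, 2, max))
}

#' Per-face unit normals and areas (derived from winding order)
#' @param mesh a `triangle_mesh`.
#' @return list with `normals` (n x 3) and `areas` (mm^2).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))
  normals <- cr / pmax(len, .Machine$double.xmin)
  list(normals = normals, areas = len / 2)
}

#' Area-weighted per-vertex normals
#' @param mesh a `triangle_mesh`.
#' @return n_vertices x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  w <- fn$normals * fn$areas
  n <- matrix(0, n_vertices(mesh), 3)
  for (j in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(w[, d], mesh$faces[, j])
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.xmin)
}

#' Merge duplicate vertices within a tolerance
#'
#' STL files duplicate every vertex per facet; merging re-establishes shared
#' edges so that boundary loops and connectivity are well defined.
#'
#' @param mesh a `triangle_mesh`.
#' @param tol merge tolerance in mm (default 1e-6).
#' @return a `triangle_mesh` with deduplicated vertices.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  triangle_mesh(v[first, , drop = FALSE],
                matrix(map[mesh$faces], ncol = 3),
                oriented = mesh_is_oriented(mesh))
}

#' Validate and canonicalize a mesh
#'
#' Merges duplicate vertices, removes zero-area and duplicate faces, and makes
#' the winding globally consistent (outward for closed components, so signed
#' volumes are positive).
#'
#' @param mesh a `triangle_mesh`.
#' @param merge_tol vertex merge tolerance in mm.
#' @param area_tol faces with area below this (mm^2) are dropped.
#' @return a validated `triangle_mesh`.
#' @export
validate_mesh <- function(mesh, merge_tol = 1e-6, area_tol = 1e-10) {
  if (n_faces(mesh) == 0) stop("empty mesh", call. = FALSE)
  v <- mesh$vertices
  key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
               round(v[, 3] / merge_tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)

  # degenerate faces: repeated index after merging, or (near) zero area
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  if (nrow(f) == 0) stop("no faces survive validation", call. = FALSE)
  m <- triangle_mesh(v, f)
  areas <- face_normals(m)$areas
  f <- f[areas > area_tol, , drop = FALSE]

  # duplicate faces (same vertex triple, either winding)
  fk <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  f <- f[!duplicated(fk), , drop = FALSE]
  if (nrow(f) == 0) stop("no faces survive validation", call. = FALSE)

  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  m <- triangle_mesh(v[used, , drop = FALSE], matrix(remap[f], ncol = 3))
  normalize_orientation(m)
}

#' Make face winding globally consistent (outward for closed components)
#'
#' @param mesh a `triangle_mesh` with merged vertices.
#' @return a `triangle_mesh`; closed components are re-signed so their signed
#'   volume is positive (outward normals).
#' @export
normalize_orientation <- function(mesh) {
  res <- cpp_orient_faces(mesh$faces, n_vertices(mesh))
  f <- res$faces
  m <- triangle_mesh(mesh$vertices, f)
  # flip closed components whose signed volume is negative
  lab <- cpp_face_components(f, n_vertices(m))
  sv <- signed_volume_by_component(m, lab)
  for (comp in which(sv$closed & sv$volume < 0)) {
    idx <- lab == comp
    f[idx, c(2, 3)] <- f[idx, c(3, 2)]
  }
  structure(list(vertices = mesh$vertices, faces = f),
            class = "triangle_mesh", oriented = !res$conflict)
}

# signed volume per face-adjacency component; closed = directed-edge balanced
signed_volume_by_component <- function(mesh, labels = NULL) {
  if (is.null(labels)) labels <- cpp_face_components(mesh$faces, n_vertices(mesh))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  ccc <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * ccc[, 3] - b[, 3] * ccc[, 2]) -
          a[, 2] * (b[, 1] * ccc[, 3] - b[, 3] * ccc[, 1]) +
          a[, 3] * (b[, 1] * ccc[, 2] - b[, 2] * ccc[, 1])
  ncomp <- max(labels)
  vol <- as.numeric(rowsum(det6 / 6, labels)[, 1])
  closed <- vapply(seq_len(ncomp), function(k) {
    fs <- f[labels == k, , drop = FALSE]
    isTRUE(cpp_edge_stats(fs, n_vertices(mesh))$directed_balanced)
  }, logical(1))
  list(volume = vol, closed = closed, labels = labels)
}

#' Summarize a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return list: vertex/face counts, bounding box, `watertight` (every edge
#'   shared by exactly two faces), `closed` (directed edge multiset balanced,
#'   the condition under which the enclosed volume is defined), boundary-edge
#'   and connected-component counts.
#' @export
mesh_summary <- function(mesh) {
  es <- cpp_edge_stats(mesh$faces, n_vertices(mesh))
  lab <- cpp_face_components(mesh$faces, n_vertices(mesh))
  list(n_vertices = n_vertices(mesh),
       n_faces = n_faces(mesh),
       bbox = mesh_bbox(mesh),
       watertight = es$n_boundary_edges == 0L && es$n_nonmanifold_edges == 0L,
       closed = isTRUE(es$directed_balanced),
       n_boundary_edges = es$n_boundary_edges,
       n_nonmanifold_edges = es$n_nonmanifold_edges,
       n_components = if (length(lab)) max(lab) else 0L)
}

#' Connected components of a mesh by face adjacency
#' @param mesh a `triangle_mesh`.
#' @return integer vector of component labels, one per face.
#' @export
mesh_components <- function(mesh) {
  cpp_face_components(mesh$faces, n_vertices(mesh))
}

#' Extract a sub-mesh from a face subset
#' @param mesh a `triangle_mesh`.
#' @param face_idx logical or integer face selector.
#' @return a `triangle_mesh` with compacted vertex indices.
#' @export
subset_faces <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  if (nrow(f) == 0) stop("empty face subset", call. = FALSE)
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[f], ncol = 3),
                oriented = mesh_is_oriented(mesh))
}

#' Scale a mesh about a fixed point
#' @param mesh a `triangle_mesh`.
#' @param factor scalar scale factor.
#' @param center 3-vector; defaults to the volume centroid for closed meshes,
#'   the vertex centroid otherwise.
#' @return the scaled `triangle_mesh`.
#' @export
scale_mesh <- function(mesh, factor, center = NULL) {
  if (is.null(center)) {
    center <- tryCatch(mesh_centroid(mesh), error = function(e)
      colMeans(mesh$vertices))
  }
  v <- sweep(sweep(mesh$vertices, 2, center), 1, factor, "*")
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, mesh$faces, oriented = mesh_is_oriented(mesh))
}

#' Volume centroid of a closed mesh (divergence theorem)
#' @param mesh a closed, consistently oriented `triangle_mesh`.
#' @return 3-vector (mm).
#' @export
mesh_centroid <- function(mesh) {
  es <- cpp_edge_stats(mesh$faces, n_vertices(mesh))
  if (!isTRUE(es$directed_balanced))
    stop("centroid requires a closed mesh", call. = FALSE)
  if (!mesh_is_oriented(mesh)) mesh <- normalize_orientation(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  ccc <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * ccc[, 3] - b[, 3] * ccc[, 2]) -
          a[, 2] * (b[, 1] * ccc[, 3] - b[, 3] * ccc[, 1]) +
          a[, 3] * (b[, 1] * ccc[, 2] - b[, 2] * ccc[, 1])
  vol <- sum(det6) / 6
  if (abs(vol) < 1e-12) stop("degenerate (zero-volume) mesh", call. = FALSE)
  cen <- colSums((a + b + ccc) / 4 * det6 / 6) / vol
  as.numeric(cen)
}

#' Append meshes into one (disjoint components)
#' @param ... `triangle_mesh` objects.
#' @return a single `triangle_mesh` containing all inputs.
#' @export
combine_meshes <- function(...) {
  ms <- list(...)
  ms <- ms[vapply(ms, function(m) n_faces(m) > 0, logical(1))]
  stopifnot(length(ms) > 0)
  off <- 0L
  vs <- list(); fs <- list()
  for (m in ms) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + n_vertices(m)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs),
                oriented = all(vapply(ms, mesh_is_oriented, logical(1))))
}
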