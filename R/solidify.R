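#' Crop a mesh to a kept region
#'
#' Removes superfluous geometry before solidification: only faces whose three
#' vertices all satisfy the keep predicate survive. Vertex indices are
#' compacted.
#'
#' @param mesh a `triangle_mesh`.
#' @param keep_region one of: `list(type = "box", min=, max=)`,
#'   `list(type = "sphere", center=, radius=)`,
#'   `list(type = "halfspace", point=, normal=)` (keeps the side the normal
#'   points to), an integer/logical face selector, or a function mapping an
#'   n x 3 vertex matrix to a logical vector.
#' @return the cropped `triangle_mesh`.
#' @export
crop_mesh <- function(mesh, keep_region) {
  if (is.function(keep_region)) {
    vkeep <- keep_region(mesh$vertices)
  } else if (is.numeric(keep_region) || is.logical(keep_region)) {
    return(subset_faces(mesh, keep_region))
  } else if (is.list(keep_region) && !is.null(keep_region$type)) {
    v <- mesh$vertices
    vkeep <- switch(keep_region$type,
      box = {
        lo <- keep_region$min; hi <- keep_region$max
        v[, 1] >= lo[1] & v[, 1] <= hi[1] &
        v[, 2] >= lo[2] & v[, 2] <= hi[2] &
        v[, 3] >= lo[3] & v[, 3] <= hi[3]
      },
      sphere = {
        d2 <- rowSums(sweep(v, 2, keep_region$center)^2)
        d2 <= keep_region$radius^2
      },
      halfspace = {
        nrm <- keep_region$normal / sqrt(sum(keep_region$normal^2))
        as.numeric(sweep(v, 2, keep_region$point) %*% nrm) >= 0
      },
      stop("unknown keep_region type: ", keep_region$type, call. = FALSE))
  } else stop("invalid keep_region", call. = FALSE)
  fkeep <- vkeep[mesh$faces[, 1]] & vkeep[mesh$faces[, 2]] &
           vkeep[mesh$faces[, 3]]
  if (!any(fkeep)) stop("crop removes every face", call. = FALSE)
  subset_faces(mesh, fkeep)
}

#' Detect boundary loops of an open surface
#'
#' Boundary edges (edges with exactly one incident face) are chained into
#' closed, ordered vertex cycles following the face winding direction.
#'
#' @param mesh a validated `triangle_mesh` (merged vertices).
#' @return a `surface_patch`: list with `mesh` and `boundary_loops` (a list of
#'   integer vertex-index cycles; empty for watertight input).
#' @export
find_boundary_loops <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  ekey <- paste(pmin(from, to), pmax(from, to))
  cnt <- table(ekey)
  boundary <- cnt[ekey] == 1
  bf <- from[boundary]
  bt <- to[boundary]
  loops <- list()
  if (length(bf) > 0) {
    if (anyDuplicated(bf) > 0)
      stop("non-manifold boundary: a vertex starts more than one boundary edge",
           call. = FALSE)
    nxt <- structure(bt, names = as.character(bf))
    visited <- rep(FALSE, length(bf))
    names(visited) <- as.character(bf)
    for (start in as.character(bf)) {
      if (visited[start]) next
      loop <- integer(0)
      cur <- start
      repeat {
        if (is.na(nxt[cur]))
          stop("non-manifold boundary: boundary edges do not chain into ",
               "closed cycles", call. = FALSE)
        visited[cur] <- TRUE
        loop <- c(loop, as.integer(cur))
        cur <- as.character(nxt[cur])
        if (cur == start) break
        if (visited[cur])
          stop("non-manifold boundary: boundary edges do not chain into ",
               "closed cycles", call. = FALSE)
      }
      loops[[length(loops) + 1]] <- loop
    }
  }
  structure(list(mesh = mesh, boundary_loops = loops), class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("surface_patch: %d faces, %d boundary loop(s)\n",
              n_faces(x$mesh), length(x$boundary_loops)))
  invisible(x)
}

#' Close an open surface patch into a watertight solid
#'
#' The (single) boundary loop is extruded by `depth` along the closing
#' direction, side walls are built from the loop edges, and the displaced loop
#' is capped by a deterministic centroid-fan triangulation. Closed components
#' already present in the patch (e.g. free-floating particle fragments) pass
#' through unchanged.
#'
#' @param patch a `surface_patch` from [find_boundary_loops()] (or a
#'   `triangle_mesh`, in which case loops are detected first).
#' @param depth extrusion depth in mm (> 0); default 5. Only relative volumes
#'   matter downstream (the same closed baseline is subtracted) but the depth
#'   must exceed registration residuals.
#' @param direction `"auto"` (negated area-weighted mean patch normal, i.e.
#'   into the scanned body) or an explicit 3-vector.
#' @return a watertight, outward-oriented `triangle_mesh`.
#' @export
close_to_solid <- function(patch, depth = 5, direction = "auto") {
  if (is_triangle_mesh(patch)) patch <- find_boundary_loops(patch)
  stopifnot(inherits(patch, "surface_patch"), depth > 0)
  loops <- patch$boundary_loops
  if (length(loops) == 0)
    stop("input is already watertight: no boundary loop to extrude",
         call. = FALSE)
  if (length(loops) > 1)
    stop(sprintf(
      "%d boundary loops found; crop tighter so exactly one remains",
      length(loops)), call. = FALSE)
  mesh <- patch$mesh
  loop <- loops[[1]]

  fn <- face_normals(mesh)
  avg <- colSums(fn$normals * fn$areas)
  avg <- avg / sqrt(sum(avg^2))
  dir <- if (identical(direction, "auto")) -avg else {
    d <- as.numeric(direction); d / sqrt(sum(d^2))
  }

  # patch faces must point away from the closing direction (outward)
  faces <- mesh$faces
  if (sum(avg * dir) > 0) faces[, c(2, 3)] <- faces[, c(3, 2)]

  nv <- n_vertices(mesh)
  k <- length(loop)
  disp <- sweep(mesh$vertices[loop, , drop = FALSE], 2, dir * depth, "+")
  newidx <- nv + seq_len(k)                      # displaced loop vertices
  centroid <- colMeans(disp)
  cidx <- nv + k + 1L

  # side walls: boundary directed edge a->b (face winding) plus displaced pair
  a <- loop
  b <- loop[c(2:k, 1)]
  ad <- newidx
  bd <- newidx[c(2:k, 1)]
  walls <- rbind(cbind(b, a, ad), cbind(b, ad, bd))

  # cap: fan from the centroid of the displaced loop, normal along dir
  cap <- cbind(bd, ad, rep(cidx, k))

  verts <- rbind(mesh$vertices, disp, matrix(centroid, 1, 3))
  solid <- triangle_mesh(verts, rbind(faces, walls, cap))
  solid <- merge_vertices(solid, tol = 1e-9)
  s <- mesh_summary(solid)
  if (!s$closed)
    stop("solidify failure: extruded surface did not close", call. = FALSE)
  sv <- signed_volume_by_component(solid)
  f2 <- solid$faces
  lab <- sv$labels
  for (comp in which(sv$volume < 0))
    f2[lab == comp, c(2, 3)] <- f2[lab == comp, c(3, 2)]
  solid <- triangle_mesh(solid$vertices, f2, oriented = TRUE)
  if (enclosed_volume(solid)$volume_mm3 <= 0)
    stop("solidify failure: result has no enclosed volume", call. = FALSE)
  solid
}
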