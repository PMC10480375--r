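#' Read an STL surface scan
#'
#' Auto-detects the binary and ASCII STL dialects. Stored facet normals are
#' discarded; normals are recomputed from winding order during validation.
#' Duplicate vertices are merged so shared edges become topologically
#' connected. Units are taken to be millimetres (intraoral scanners export mm).
#'
#' @param path path to an `.stl` file.
#' @param merge_tol vertex merge tolerance in mm (default 1e-6).
#' @param validate run full validation (degenerate/duplicate face removal and
#'   consistent orientation); default `TRUE`.
#' @return a `triangle_mesh`.
#' @export
read_stl <- function(path, merge_tol = 1e-6, validate = TRUE) {
  if (!file.exists(path)) stop("cannot read STL file: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  mesh <- if (stl_is_binary(raw)) parse_stl_binary(raw) else parse_stl_ascii(raw)
  if (n_faces(mesh) == 0) stop("STL file contains no triangles: ", path,
                               call. = FALSE)
  if (validate) validate_mesh(mesh, merge_tol = merge_tol)
  else merge_vertices(mesh, tol = merge_tol)
}

stl_is_binary <- function(raw) {
  if (length(raw) < 84) return(FALSE)
  n <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  # a binary file's size is exactly header + count * 50-byte records
  if (!is.na(n) && n >= 0 && length(raw) == 84 + 50 * as.numeric(n)) return(TRUE)
  head <- tolower(rawToChar(raw[seq_len(min(512, length(raw)))]))
  !(startsWith(trimws(head), "solid") && grepl("facet", head, fixed = TRUE))
}

parse_stl_binary <- function(raw) {
  n <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  if (n == 0) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  body <- raw[-seq_len(84)]
  # each 50-byte record: 12 floats (normal + 3 vertices) + uint16 attribute
  rec <- matrix(body, nrow = 50)
  floats <- readBin(as.raw(rec[1:48, ]), "numeric", n = 12 * n, size = 4,
                    endian = "little")
  m <- matrix(floats, nrow = 12)            # columns = facets
  verts <- rbind(t(m[4:6, , drop = FALSE]),
                 t(m[7:9, , drop = FALSE]),
                 t(m[10:12, , drop = FALSE]))
  # interleave back to per-facet vertex order v1,v2,v3
  ord <- as.vector(rbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2 * n))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

parse_stl_ascii <- function(raw) {
  txt <- rawToChar(raw)
  # every "vertex x y z" line, in order; 3 consecutive vertices form a facet
  m <- gregexpr("vertex[ \t]+([-+0-9.eE]+)[ \t]+([-+0-9.eE]+)[ \t]+([-+0-9.eE]+)",
                txt)[[1]]
  if (m[1] == -1) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  chunks <- regmatches(txt, gregexpr(
    "vertex[ \t]+[-+0-9.eE]+[ \t]+[-+0-9.eE]+[ \t]+[-+0-9.eE]+", txt))[[1]]
  nums <- vapply(strsplit(sub("^vertex[ \t]+", "", chunks), "[ \t]+"),
                 function(x) as.numeric(x[1:3]), numeric(3))
  verts <- t(nums)
  nv <- nrow(verts)
  if (nv %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3",
                         call. = FALSE)
  faces <- matrix(seq_len(nv), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Write a mesh as STL
#'
#' @param mesh a non-empty `triangle_mesh`.
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (n_faces(mesh) == 0) stop("refusing to write an empty mesh", call. = FALSE)
  fn <- face_normals(mesh)$normals
  v <- mesh$vertices
  f <- mesh$faces
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("augvol binary STL", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # per facet: normal, v1, v2, v3 as float32, then uint16 attribute
    block <- rbind(t(fn), t(v[f[, 1], , drop = FALSE]),
                   t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    fl <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    recs <- matrix(fl, nrow = 48)
    out <- rbind(recs, matrix(as.raw(0), 2, ncol(recs)))
    writeBin(as.vector(out), con)
  } else {
    lines <- c("solid augvol")
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    lines <- c(lines, as.vector(rbind(
      sprintf("  facet normal %s", fmt(fn)),
      "    outer loop",
      sprintf("      vertex %s", fmt(a)),
      sprintf("      vertex %s", fmt(b)),
      sprintf("      vertex %s", fmt(cc)),
      "    endloop",
      "  endfacet")), "endsolid augvol")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a landmark sidecar file
#'
#' Landmarks are exactly three labelled points used for coarse three-point
#' alignment, stored as CSV with header `label,x,y,z` in mm.
#'
#' @param path CSV path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns label,x,y,z", call. = FALSE)
  landmark_set(as.matrix(df[, c("x", "y", "z")]), labels = df$label)
}

#' Write a landmark sidecar file
#' @param lm a `landmark_set`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(label = attr(lm, "labels"), x = lm[, 1], y = lm[, 2],
                   z = lm[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Labelled landmark triple
#'
#' @param points 3 x 3 numeric matrix (rows = points, mm), in a fixed
#'   correspondence order.
#' @param labels character vector of length 3.
#' @param tol minimum triangle area (mm^2) below which the points are
#'   considered collinear.
#' @return a `landmark_set` (a 3x3 matrix with labels).
#' @export
landmark_set <- function(points, labels = c("L1", "L2", "L3"), tol = 1e-6) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) != 3) stop("exactly 3 landmarks required", call. = FALSE)
  area <- triangle_area(points[1, ], points[2, ], points[3, ])
  if (area < tol) stop("landmarks are collinear", call. = FALSE)
  structure(points, class = "landmark_set", labels = as.character(labels))
}

triangle_area <- function(a, b, c) {
  cr <- crossprod3(b - a, c - a)
  sqrt(sum(cr^2)) / 2
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Read a per-vertex weight map sidecar
#'
#' CSV with columns `vertex_index,weight`; indices are 1-based into the
#' validated mesh, missing vertices default to weight 0.
#'
#' @param path CSV path.
#' @param n_vertices vertex count of the mesh the map belongs to.
#' @return a numeric weight vector of length `n_vertices`.
#' @export
read_weight_map <- function(path, n_vertices) {
  df <- utils::read.csv(path)
  if (!all(c("vertex_index", "weight") %in% names(df)))
    stop("weight file must have columns vertex_index,weight", call. = FALSE)
  w <- numeric(n_vertices)
  idx <- as.integer(df$vertex_index)
  if (any(idx < 1 | idx > n_vertices))
    stop("weight vertex_index out of range", call. = FALSE)
  w[idx] <- df$weight
  vertex_weights(w)
}

#' Write a per-vertex weight map sidecar
#' @param weights numeric weight vector.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_weight_map <- function(weights, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(weights),
                              weight = as.numeric(weights)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Validate a vertex weight map
#' @param w numeric vector of non-negative weights in `[0, 1]`.
#' @return the validated weight vector.
#' @export
vertex_weights <- function(w) {
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("weights must be finite and in [0, 1]", call. = FALSE)
  if (sum(w > 0) < 3)
    stop("at least 3 vertices must have positive weight", call. = FALSE)
  w
}
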