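test_that("STL round trip preserves the mesh in both dialects", {
  cube <- cube_mesh()
  for (dialect in c("binary", "ascii")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(cube, path, dialect)
    m <- read_stl(path)
    expect_equal(n_vertices(m), 8)
    expect_equal(n_faces(m), 12)
    # vertex sets agree within merge tolerance, independent of ordering
    ours <- cube$vertices[do.call(order, as.data.frame(cube$vertices)), ]
    theirs <- m$vertices[do.call(order, as.data.frame(m$vertices)), ]
    expect_lt(max(abs(ours - theirs)), 1e-6)
    expect_equal(enclosed_volume(m)$volume_mm3, 1, tolerance = 1e-9)
  }
  # the two dialects read back identically
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, p1, "binary")
  write_stl(cube, p2, "ascii")
  a <- read_stl(p1); b <- read_stl(p2)
  sa <- a$vertices[do.call(order, as.data.frame(a$vertices)), ]
  sb <- b$vertices[do.call(order, as.data.frame(b$vertices)), ]
  expect_lt(max(abs(sa - sb)), 1e-6)
})

test_that("validation removes degenerate triangles and duplicated vertices", {
  cube <- cube_mesh()
  # replace one face by a zero-area sliver: 11 real faces survive out of 12
  v <- cube$vertices
  f <- cube$faces[-1, , drop = FALSE]
  nv <- nrow(v)
  v <- rbind(v, c(0, 0, 0), c(0.5, 0.5, 0), c(1, 1, 0))  # collinear
  soup <- triangle_mesh(v, rbind(f, c(nv + 1, nv + 2, nv + 3)))
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(soup, path, "ascii")
  m <- read_stl(path)
  expect_equal(n_faces(m), 11)

  # duplicated faces collapse to one
  dup <- triangle_mesh(cube$vertices, rbind(cube$faces, cube$faces[1, ]))
  expect_equal(n_faces(validate_mesh(dup)), 12)
})

test_that("reading errors are informative", {
  expect_error(read_stl(file.path(tempdir(), "nope.stl")), "cannot read")
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid empty", "endsolid empty"), p)
  expect_error(read_stl(p), "no triangles")
  expect_error(write_stl(augvol:::empty_mesh(), withr::local_tempfile()),
               "empty")
})

test_that("mesh_summary reports watertightness and components", {
  cube <- cube_mesh()
  s <- mesh_summary(cube)
  expect_true(s$watertight)
  expect_true(s$closed)
  expect_equal(s$n_components, 1)

  open_cube <- subset_faces(cube, 1:11)
  so <- mesh_summary(open_cube)
  expect_false(so$watertight)
  expect_gt(so$n_boundary_edges, 0)

  two <- combine_meshes(cube, make_box_mesh(c(3, 3, 3), c(4, 4, 4)))
  expect_equal(mesh_summary(two)$n_components, 2)
})

test_that("watertightness flag agrees with brute-force edge incidence", {
  fixtures <- list(cube_mesh(), subset_faces(cube_mesh(), 1:11),
                   uv_hemisphere(1, 8, 16), icosphere_mesh(2),
                   grid_patch(seq(0, 1, 0.25), seq(0, 1, 0.25)))
  for (m in fixtures) {
    inc <- edge_incidence_bruteforce(m)
    expect_identical(mesh_summary(m)$watertight,
                     all(inc == 2))
  }
})

test_that("landmark sets validate non-collinearity and round trip", {
  expect_error(landmark_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
  lm <- landmark_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 2)),
                     labels = c("mesial", "distal", "lingual"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, p)
  lm2 <- read_landmarks(p)
  expect_equal(unclass(lm2), unclass(lm), ignore_attr = TRUE)
  expect_equal(attr(lm2, "labels"), c("mesial", "distal", "lingual"))
})

test_that("weight maps validate range and support", {
  expect_error(vertex_weights(c(1, 1, -0.1)), "finite and in")
  expect_error(vertex_weights(c(1, 0.5, 2)), "finite and in")
  expect_error(vertex_weights(c(1, 1, 0, 0)), "at least 3")
  p <- withr::local_tempfile(fileext = ".csv")
  write_weight_map(c(0.2, 0, 1, 0.7), p)
  expect_equal(read_weight_map(p, 4), c(0.2, 0, 1, 0.7))
  expect_error(read_weight_map(p, 3), "out of range")
})
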