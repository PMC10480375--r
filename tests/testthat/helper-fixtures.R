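# Shared geometric fixtures, built in code.

# unit cube as a raw triangle soup (STL-style duplicated vertices optional)
cube_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  make_box_mesh(lo, hi)
}

# hemisphere of radius r, boundary exactly on the equator, apex up
uv_hemisphere <- function(r = 1, nt = 40, np = 120) {
  th <- seq(0, pi / 2, length.out = nt + 1)
  ph <- seq(0, 2 * pi, length.out = np + 1)[-(np + 1)]
  verts <- rbind(c(0, 0, r))
  for (i in 2:(nt + 1))
    verts <- rbind(verts, cbind(r * sin(th[i]) * cos(ph),
                                r * sin(th[i]) * sin(ph),
                                r * cos(th[i])))
  ring <- function(i) 1 + (i - 2) * np + seq_len(np)
  f <- cbind(1, ring(2), c(ring(2)[-1], ring(2)[1]))
  for (i in 2:nt) {
    a <- ring(i); b <- ring(i + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    f <- rbind(f, cbind(a, b, b2), cbind(a, b2, a2))
  }
  normalize_orientation(triangle_mesh(verts, f))
}

# flat rectangular height-field patch z = f(x, y) on a regular grid
grid_patch <- function(xs, ys, f = function(x, y) 0 * x) {
  augvol:::heightfield_mesh(xs, ys, outer(xs, ys, f))
}

# 8x8-cell square patch with a clean 3x3-cell rectangular hole (two loops)
holey_patch <- function() {
  xs <- seq(0, 1, by = 0.125)
  patch <- grid_patch(xs, xs)
  ctrx <- (patch$vertices[patch$faces[, 1], 1] +
             patch$vertices[patch$faces[, 2], 1] +
             patch$vertices[patch$faces[, 3], 1]) / 3
  ctry <- (patch$vertices[patch$faces[, 1], 2] +
             patch$vertices[patch$faces[, 2], 2] +
             patch$vertices[patch$faces[, 3], 2]) / 3
  hole <- floor(ctrx / 0.125) %in% 3:5 & floor(ctry / 0.125) %in% 3:5
  subset_faces(patch, !hole)
}

# brute-force undirected edge incidence table (independent of the C++ kernel)
edge_incidence_bruteforce <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

# run code under a fixed seed without disturbing the session RNG
with_seed_test <- function(seed, code) augvol:::with_seed(seed, code)

# rotation matrix about z
rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# write a phantom scan pair to disk and build a pipeline config for it
phantom_case_config <- function(spec, dir = tempfile(), self_diff = FALSE,
                                roi_scale = 0.98, voxel_mm = 0.1) {
  dir.create(dir, showWarnings = FALSE)
  base <- generate_baseline(spec)
  aug <- generate_augmented(base, spec)
  write_stl(base$mesh, file.path(dir, "base.stl"))
  write_landmarks(base$landmarks, file.path(dir, "base_lm.csv"))
  if (self_diff) {
    file.copy(file.path(dir, "base.stl"), file.path(dir, "aug.stl"))
    write_landmarks(base$landmarks, file.path(dir, "aug_lm.csv"))
    wfile <- NULL
  } else {
    write_stl(aug$mesh, file.path(dir, "aug.stl"))
    write_landmarks(aug$landmarks, file.path(dir, "aug_lm.csv"))
    w <- augvol:::transfer_vertex_weights(aug$mesh, aug$weights,
                                          read_stl(file.path(dir, "aug.stl")))
    wfile <- file.path(dir, "aug_w.csv")
    write_weight_map(w, wfile)
  }
  bb <- aug$truth$aug_bbox
  cfg <- pipeline_config(
    baseline_stl = file.path(dir, "base.stl"),
    baseline_landmarks = file.path(dir, "base_lm.csv"),
    augmented = list(scan = list(stl = file.path(dir, "aug.stl"),
                                 landmarks = file.path(dir, "aug_lm.csv"),
                                 weights = wfile)),
    roi = list(min = bb$min, max = bb$max, scale = roi_scale),
    voxel_mm = voxel_mm)
  list(config = cfg, truth = aug$truth, dir = dir)
}
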