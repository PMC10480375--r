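#' Phantom specification
#'
#' Describes a synthetic scan pair: a ridge-like baseline surface plus one of
#' three augmentation geometries with analytically known added volume,
#' scanner-like vertex noise, an optional rigid pose perturbation of the
#' "augmented scan", and optional free-floating particle fragments.
#'
#' Default added-volume scales follow the three studied techniques: solid
#' block `B` about 0.35 cm^3, thin plate over particulate `S1` about
#' 0.76 cm^3, curved shell over particulate `S2` about 0.82 cm^3.
#'
#' @param technique `"B"`, `"S1"` or `"S2"`.
#' @param target_volume_cm3 added volume the augmentation is scaled to;
#'   default by technique (0.35 / 0.76 / 0.82).
#' @param ridge_length,ridge_width,ridge_height ridge dimensions in mm.
#' @param pitch tessellation edge length in mm (default 0.2, scanner-like).
#' @param perturb_amp amplitude (mm) of the smooth seeded surface undulation.
#' @param noise_sd scanner noise: sd (mm) of i.i.d. vertex displacement along
#'   local normals; 0 disables.
#' @param n_floating_fragments number of disconnected particle spheres near
#'   the augmentation.
#' @param fragment_radius radius (mm) of the floating fragments.
#' @param aug_shape `"plateau"` (technique-specific footprint) or
#'   `"hemisphere"` (analytic truth `(2/3) pi r^3`, ignores the target
#'   volume).
#' @param hemisphere_radius radius (mm) for `aug_shape = "hemisphere"`.
#' @param footprint augmentation footprint `c(a, b)` in mm (default by
#'   technique).
#' @param aug_center footprint center `c(x, y)` in the ridge frame; default
#'   on the crest at mid-length.
#' @param pose_angle_deg,pose_translation magnitude of the known rigid
#'   misalignment applied to the augmented scan (randomized direction).
#' @param landmark_sd sd (mm) of landmark placement jitter on the augmented
#'   scan.
#' @param margin minimum distance (mm) the augmentation must keep from the
#'   scan border.
#' @param allow_margin_violation keep a too-close-to-margin augmentation
#'   instead of raising an error (used to construct the margin-failure case).
#' @param seed integer; the same seed reproduces the phantom bit for bit.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(technique = c("B", "S1", "S2"),
                         target_volume_cm3 = NULL,
                         ridge_length = 36, ridge_width = 16,
                         ridge_height = 8, pitch = 0.2,
                         perturb_amp = 0.3, noise_sd = 0,
                         n_floating_fragments = 0, fragment_radius = 0.6,
                         aug_shape = c("plateau", "hemisphere"),
                         hemisphere_radius = 4.3,
                         footprint = NULL, aug_center = NULL,
                         pose_angle_deg = 5, pose_translation = 2,
                         landmark_sd = 0.2, margin = 2,
                         allow_margin_violation = FALSE, seed = 1) {
  technique <- match.arg(technique)
  aug_shape <- match.arg(aug_shape)
  if (is.null(target_volume_cm3))
    target_volume_cm3 <- c(B = 0.35, S1 = 0.76, S2 = 0.82)[[technique]]
  if (is.null(footprint))
    footprint <- switch(technique, B = c(10, 12), S1 = c(12, 15),
                        S2 = c(12, 16))
  if (is.null(aug_center)) aug_center <- c(0, ridge_length / 2)
  stopifnot(ridge_length > 0, ridge_width > 0, ridge_height > 0, pitch > 0,
            noise_sd >= 0, n_floating_fragments >= 0, target_volume_cm3 > 0)
  structure(list(technique = technique,
                 target_volume_cm3 = target_volume_cm3,
                 ridge_length = ridge_length, ridge_width = ridge_width,
                 ridge_height = ridge_height, pitch = pitch,
                 perturb_amp = perturb_amp, noise_sd = noise_sd,
                 n_floating_fragments = as.integer(n_floating_fragments),
                 fragment_radius = fragment_radius,
                 aug_shape = aug_shape, hemisphere_radius = hemisphere_radius,
                 footprint = footprint, aug_center = aug_center,
                 pose_angle_deg = pose_angle_deg,
                 pose_translation = pose_translation,
                 landmark_sd = landmark_sd, margin = margin,
                 allow_margin_violation = isTRUE(allow_margin_violation),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# smooth seeded undulation + rounded-trapezoid cross-profile of the ridge
ridge_height_fun <- function(spec) {
  coefs <- with_seed(spec$seed, matrix(stats::rnorm(12, 0, 1), 4, 3))
  W <- spec$ridge_width; L <- spec$ridge_length; H <- spec$ridge_height
  amp <- spec$perturb_amp
  function(x, y) {
    u <- abs(x) / (W / 2)                # 0 at crest, 1 at border
    prof <- ifelse(u <= 0.35, 1,
                   ifelse(u >= 1, 0, 0.5 * (1 + cos(pi * (u - 0.35) / 0.65))))
    und <- amp * (coefs[1, 1] * sin(2 * pi * y / L) *
                    cos(pi * x / W) +
                  coefs[2, 1] * sin(4 * pi * y / L + coefs[2, 2]) *
                    0.6 +
                  coefs[3, 1] * cos(2 * pi * x / W + coefs[3, 2]) *
                    sin(2 * pi * y / L + coefs[3, 3]) * 0.5)
    H * prof + und
  }
}

# unit-height added-height field of the augmentation, by technique
aug_delta_fun <- function(spec) {
  a <- spec$footprint[1] / 2
  b <- spec$footprint[2] / 2
  cx <- spec$aug_center[1]; cy <- spec$aug_center[2]
  if (spec$aug_shape == "hemisphere") {
    r <- spec$hemisphere_radius
    return(function(x, y) {
      rho2 <- (x - cx)^2 + (y - cy)^2
      sqrt(pmax(0, r^2 - rho2))
    })
  }
  p <- switch(spec$technique, B = 4, S1 = 6, S2 = 2)
  texture <- spec$technique %in% c("S1", "S2")
  tex_coef <- with_seed(spec$seed + 1000L, matrix(stats::runif(24, -1, 1), 8, 3))
  function(x, y) {
    u <- ((abs(x - cx) / a)^p + ((abs(y - cy)) / b)^p)^(1 / p)
    base <- ifelse(u >= 1, 0,
                   if (spec$technique == "S2") sqrt(pmax(0, 1 - u^2))
                   else 0.5 * (1 + cos(pi * pmin(u, 1))))
    if (texture) {
      # particulate graininess: small seeded ripples inside the footprint
      rip <- 0
      for (k in 1:4)
        rip <- rip + tex_coef[k, 1] *
          sin(2 * pi * (x - cx) / (1.5 + k / 2) + tex_coef[k, 2]) *
          cos(2 * pi * (y - cy) / (2 + k / 3) + tex_coef[k, 3])
      base <- pmax(0, base * (1 + 0.03 * rip))
    }
    base
  }
}

# peak height scaling the unit delta to the target volume (quadrature on a
# fine grid, disjoint from the mesh machinery)
aug_height_for_target <- function(spec, delta_unit) {
  if (spec$aug_shape == "hemisphere") return(1)
  a <- spec$footprint[1] / 2; b <- spec$footprint[2] / 2
  q <- 0.05
  xs <- seq(spec$aug_center[1] - a, spec$aug_center[1] + a, by = q)
  ys <- seq(spec$aug_center[2] - b, spec$aug_center[2] + b, by = q)
  g <- expand.grid(x = xs, y = ys)
  unit_vol <- sum(delta_unit(g$x, g$y)) * q * q
  spec$target_volume_cm3 * 1000 / unit_vol
}

ridge_grid <- function(spec) {
  xs <- seq(-spec$ridge_width / 2, spec$ridge_width / 2, by = spec$pitch)
  ys <- seq(0, spec$ridge_length, by = spec$pitch)
  list(xs = xs, ys = ys)
}

# height-field tessellation with upward (outward) normals
heightfield_mesh <- function(xs, ys, z) {
  nx <- length(xs); ny <- length(ys)
  verts <- cbind(rep(xs, times = ny), rep(ys, each = nx), as.vector(z))
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  triangle_mesh(verts, faces)
}

phantom_landmark_xy <- function(spec) {
  W <- spec$ridge_width; L <- spec$ridge_length
  rbind(c(-W / 2 + 2, 4), c(W / 2 - 2, 4), c(0, L - 3))
}

#' Generate the baseline phantom scan
#'
#' An open ridge-like surface (extruded rounded-trapezoid profile with smooth
#' seeded undulations) tessellated at scanner-like density, with three
#' reproducible landmark positions outside the future augmentation zone.
#' The same seed reproduces the mesh bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return list with `mesh` (a `triangle_mesh`), `landmarks`
#'   (a `landmark_set`) and `spec`.
#' @export
generate_baseline <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- ridge_grid(spec)
  hf <- ridge_height_fun(spec)
  z <- outer(g$xs, g$ys, hf)
  mesh <- heightfield_mesh(g$xs, g$ys, z)
  if (spec$noise_sd > 0) {
    vn <- vertex_normals(mesh)
    d <- with_seed(spec$seed + 1L,
                   stats::rnorm(n_vertices(mesh), 0, spec$noise_sd))
    mesh <- triangle_mesh(mesh$vertices + vn * d, mesh$faces)
  }
  lxy <- phantom_landmark_xy(spec)
  lz <- hf(lxy[, 1], lxy[, 2])
  list(mesh = mesh, landmarks = landmark_set(cbind(lxy, lz)), spec = spec)
}

#' Generate the augmented phantom scan with known ground truth
#'
#' Adds the technique-specific added-height field to the ridge surface,
#' computes the ground-truth added volume as the exact prism integral of the
#' piecewise-linear (noise-free) added-height surface - machinery disjoint
#' from the measurement pipeline - applies scanner noise and a known random
#' rigid pose, and optionally appends free-floating particle spheres.
#'
#' @param baseline output of [generate_baseline()] (same spec).
#' @param spec a [phantom_spec()].
#' @return list with `mesh` (posed, noisy augmented scan), `landmarks` (posed,
#'   jittered), `weights` (per-vertex ICP weights: 0 over the augmentation,
#'   graded ramp to 1 outside), and `truth` (a `phantom_truth`: ground-truth
#'   volume, analytic value where available, applied pose, augmentation
#'   bounding box in the baseline frame).
#' @export
generate_augmented <- function(baseline, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- ridge_grid(spec)
  hf <- ridge_height_fun(spec)
  du <- aug_delta_fun(spec)
  h <- aug_height_for_target(spec, du)

  # margin check: the augmentation must stay clear of the scan border
  half <- if (spec$aug_shape == "hemisphere")
    rep(spec$hemisphere_radius, 2) else spec$footprint / 2
  lo <- spec$aug_center - half
  hi <- spec$aug_center + half
  W <- spec$ridge_width; L <- spec$ridge_length
  if (lo[1] < -W / 2 + spec$margin || hi[1] > W / 2 - spec$margin ||
      lo[2] < spec$margin || hi[2] > L - spec$margin) {
    if (!spec$allow_margin_violation)
      stop("phantom spec error: augmentation extends into the scan margin (",
           "the scan border is too close to measure the volume)",
           call. = FALSE)
  }

  zbase <- outer(g$xs, g$ys, hf)
  delta <- h * outer(g$xs, g$ys, du)
  mesh <- heightfield_mesh(g$xs, g$ys, zbase + delta)

  # ground truth: exact integral of the piecewise-linear added-height surface
  nx <- length(g$xs); ny <- length(g$ys)
  cell <- spec$pitch^2 / 2      # area of each of the two triangles per cell
  d00 <- delta[-nx, -ny]; d10 <- delta[-1, -ny]
  d01 <- delta[-nx, -1];  d11 <- delta[-1, -1]
  truth_mm3 <- cell * (sum(d00 + d10 + d11) + sum(d00 + d11 + d01)) / 3
  analytic <- if (spec$aug_shape == "hemisphere")
    2 / 3 * pi * spec$hemisphere_radius^3 else NA_real_

  # ICP weight map: 0 over the (dilated) augmentation, cosine ramp to 1
  v <- mesh$vertices
  ramp <- 2
  dx <- pmax(abs(v[, 1] - spec$aug_center[1]) - half[1], 0)
  dy <- pmax(abs(v[, 2] - spec$aug_center[2]) - half[2], 0)
  dd <- sqrt(dx^2 + dy^2)
  weights <- ifelse(dd <= 0, 0,
                    ifelse(dd >= ramp, 1, 0.5 * (1 - cos(pi * dd / ramp))))

  if (spec$noise_sd > 0) {
    vn <- vertex_normals(mesh)
    d <- with_seed(spec$seed + 2L,
                   stats::rnorm(n_vertices(mesh), 0, spec$noise_sd))
    mesh <- triangle_mesh(mesh$vertices + vn * d, mesh$faces)
  }

  if (spec$n_floating_fragments > 0) {
    frag <- with_seed(spec$seed + 3L, {
      lapply(seq_len(spec$n_floating_fragments), function(i) {
        cx <- stats::runif(1, lo[1], hi[1])
        cy <- stats::runif(1, lo[2], hi[2])
        cz <- hf(cx, cy) + h * du(cx, cy) + spec$fragment_radius +
          stats::runif(1, 0.8, 1.8)
        m <- icosphere_mesh(2)
        triangle_mesh(sweep(m$vertices * spec$fragment_radius, 2,
                            c(cx, cy, cz), "+"), m$faces, oriented = TRUE)
      })
    })
    nfrag_v <- sum(vapply(frag, n_vertices, integer(1)))
    mesh <- do.call(combine_meshes, c(list(mesh), frag))
    weights <- c(weights, numeric(nfrag_v))
  }

  pose <- with_seed(spec$seed + 4L,
                    random_rigid_transform(spec$pose_angle_deg,
                                           spec$pose_translation))
  mesh <- apply_transform(pose, mesh)

  lxy <- phantom_landmark_xy(spec)
  lz <- hf(lxy[, 1], lxy[, 2])
  lm <- cbind(lxy, lz)
  jit <- with_seed(spec$seed + 5L,
                   matrix(stats::rnorm(9, 0, spec$landmark_sd), 3, 3))
  lm_posed <- apply_transform(pose, lm) + jit

  # ROI suggestion: brackets the augmentation with a safety margin, bottom
  # well above the solidified caps, top above the augmented surface
  foot <- outer(g$xs, g$ys, function(x, y)
    abs(x - spec$aug_center[1]) <= half[1] + 2 &
    abs(y - spec$aug_center[2]) <= half[2] + 2)
  zfoot <- zbase[foot]
  roi_min <- c(lo - 1.5, min(zfoot) - 2.5)
  roi_max <- c(hi + 1.5, max((zbase + delta)[foot]) + 1.5)
  truth <- structure(list(ground_truth_volume_mm3 = truth_mm3,
                          ground_truth_volume_cm3 = truth_mm3 / 1000,
                          analytic_volume_mm3 = analytic,
                          applied_pose = pose,
                          aug_bbox = list(min = roi_min, max = roi_max),
                          technique = spec$technique),
                     class = "phantom_truth")
  list(mesh = mesh, landmarks = landmark_set(lm_posed),
       weights = weights, truth = truth)
}

#' Random rigid transform of given magnitude
#' @param angle_deg rotation angle (degrees) about a uniformly random axis.
#' @param translation translation length (mm) in a uniformly random direction.
#' @return a `rigid_transform`. Uses the current RNG stream.
#' @export
random_rigid_transform <- function(angle_deg, translation) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tdir <- stats::rnorm(3)
  tdir <- tdir / sqrt(sum(tdir^2))
  rigid_transform(R, tdir * translation)
}

#' Icosphere (subdivided icosahedron, unit radius)
#' @param subdivisions number of 4-to-1 subdivisions (default 3).
#' @return a watertight `triangle_mesh`.
#' @export
icosphere_mesh <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(ek)
    mid_of <- match(ek, uk)
    ue <- edges[!duplicated(ek), , drop = FALSE]
    mids <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    base <- nrow(v)
    v <- rbind(v, mids)
    m12 <- base + mid_of[seq_len(nf)]
    m23 <- base + mid_of[nf + seq_len(nf)]
    m31 <- base + mid_of[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  normalize_orientation(triangle_mesh(v, f))
}

# carry per-vertex weights from a source mesh onto a re-read/re-indexed copy
# of the same surface: each target vertex inherits the weight of the nearest
# source vertex
transfer_vertex_weights <- function(source_mesh, weights, target_mesh) {
  cp <- cpp_closest_points(source_mesh$vertices, source_mesh$faces,
                           target_mesh$vertices)
  f <- source_mesh$faces[cp$face, , drop = FALSE]
  vt <- target_mesh$vertices
  d2 <- sapply(1:3, function(j)
    rowSums((source_mesh$vertices[f[, j], , drop = FALSE] - vt)^2))
  pick <- f[cbind(seq_len(nrow(f)), max.col(-d2))]
  weights[pick]
}

#' Generate a multi-specimen phantom study on disk
#'
#' Emulates the in vitro study design: per specimen a baseline scan plus one
#' augmented scan per technique at the studied volume scales, written as STL
#' files with landmark and weight sidecars plus a ground-truth manifest.
#'
#' @param n_specimens number of specimens (>= 1).
#' @param out_dir output directory (created).
#' @param techniques subset of `c("B", "S1", "S2")`.
#' @param seed study seed; per-specimen seeds and target volumes derive from
#'   it reproducibly. Target volumes are drawn around the per-technique scale
#'   (B 0.35 +/- 0.085, S1 0.76 +/- 0.15, S2 0.82 +/- 0.17 cm^3).
#' @param spec_overrides named list of [phantom_spec()] arguments applied to
#'   every specimen (e.g. `noise_sd`, `pitch`, `n_floating_fragments`).
#' @return the manifest as a data frame (also written to
#'   `manifest.csv`): specimen, technique, truth_cm3 and file paths.
#' @export
generate_study <- function(n_specimens, out_dir,
                           techniques = c("B", "S1", "S2"),
                           seed = 1, spec_overrides = list()) {
  stopifnot(n_specimens >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scales <- list(B = c(0.35, 0.085), S1 = c(0.76, 0.15), S2 = c(0.82, 0.17))
  rows <- list()
  for (i in seq_len(n_specimens)) {
    # derived per-specimen seed, kept inside the 32-bit integer range
    sp_seed <- as.integer((as.numeric(seed) * 10000 + i) %% 2147483629)
    targets <- with_seed(sp_seed, {
      sapply(techniques, function(tech)
        max(0.15, stats::rnorm(1, scales[[tech]][1], scales[[tech]][2])))
    })
    sdir <- file.path(out_dir, sprintf("specimen_%02d", i))
    dir.create(sdir, showWarnings = FALSE)
    base_args <- c(list(technique = techniques[1], seed = sp_seed),
                   spec_overrides)
    base_spec <- do.call(phantom_spec, base_args)
    baseline <- generate_baseline(base_spec)
    write_stl(baseline$mesh, file.path(sdir, "baseline.stl"))
    write_landmarks(baseline$landmarks, file.path(sdir, "baseline_landmarks.csv"))
    for (tech in techniques) {
      args <- c(list(technique = tech, seed = sp_seed,
                     target_volume_cm3 = targets[[tech]]),
                spec_overrides)
      spec <- do.call(phantom_spec, args)
      aug <- generate_augmented(baseline, spec)
      stl <- file.path(sdir, sprintf("aug_%s.stl", tech))
      lmf <- file.path(sdir, sprintf("aug_%s_landmarks.csv", tech))
      wf <- file.path(sdir, sprintf("aug_%s_weights.csv", tech))
      pf <- file.path(sdir, sprintf("aug_%s_pose.txt", tech))
      write_stl(aug$mesh, stl)
      write_landmarks(aug$landmarks, lmf)
      # weight indices must refer to the mesh as re-read from the STL
      # (validation reorders vertices)
      w_read <- transfer_vertex_weights(aug$mesh, aug$weights, read_stl(stl))
      write_weight_map(w_read, wf)
      write_transform(aug$truth$applied_pose, pf)
      bb <- aug$truth$aug_bbox
      rows[[length(rows) + 1]] <- data.frame(
        specimen = i, technique = tech,
        truth_cm3 = aug$truth$ground_truth_volume_cm3,
        stl = stl, landmarks = lmf, weights = wf, pose = pf,
        baseline_stl = file.path(sdir, "baseline.stl"),
        baseline_landmarks = file.path(sdir, "baseline_landmarks.csv"),
        roi_min_x = bb$min[1], roi_min_y = bb$min[2], roi_min_z = bb$min[3],
        roi_max_x = bb$max[1], roi_max_y = bb$max[2], roi_max_z = bb$max[3])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
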