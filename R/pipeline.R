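#' Pipeline configuration
#'
#' Everything needed to run the semiautomatic measurement end to end for one
#' baseline scan and any number of augmented scans.
#'
#' @param baseline_stl,baseline_landmarks paths to the baseline scan and its
#'   landmark sidecar.
#' @param augmented named list; each element a list with `stl`, `landmarks`,
#'   and optionally `weights` (per-vertex ICP weight CSV).
#' @param roi region of interest: `list(min=, max=)` box corners in the
#'   baseline frame (or a path to an STL solid under `mesh`), plus optional
#'   `scale` (inner/outer factor, default 0.98).
#' @param crop_margin mm added around the ROI box when trimming superfluous
#'   geometry (default 3).
#' @param solidify_depth extrusion depth in mm (default 5).
#' @param voxel_mm Boolean lattice pitch in mm (default 0.1).
#' @param icp see [icp_params()].
#' @param fragment_policy `"largest"` or `"threshold"` for
#'   [drop_disconnected()].
#' @param slice_oracle slice thickness (mm) to also run the slice-based volume
#'   oracle, or `NULL` to skip (default 0.25).
#' @param out_dir directory for intermediate artefacts and the results JSON,
#'   or `NULL` to keep everything in memory.
#' @param seed integer seed (the pipeline itself is deterministic; the seed
#'   covers optional jitter in study re-runs).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(baseline_stl, baseline_landmarks, augmented,
                            roi, crop_margin = 3, solidify_depth = 5,
                            voxel_mm = 0.1, icp = icp_params(),
                            fragment_policy = "largest",
                            slice_oracle = 0.25, out_dir = NULL, seed = 1) {
  for (p in c(baseline_stl, baseline_landmarks))
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
  stopifnot(is.list(augmented), length(augmented) > 0)
  if (is.null(names(augmented)) || any(names(augmented) == ""))
    names(augmented) <- paste0("scan", seq_along(augmented))
  for (a in augmented) {
    for (p in c(a$stl, a$landmarks, a$weights))
      if (!is.null(p) && !file.exists(p))
        stop("missing file: ", p, call. = FALSE)
  }
  if (is.null(roi$scale)) roi$scale <- 0.98
  structure(list(baseline_stl = baseline_stl,
                 baseline_landmarks = baseline_landmarks,
                 augmented = augmented, roi = roi,
                 crop_margin = crop_margin,
                 solidify_depth = solidify_depth, voxel_mm = voxel_mm,
                 icp = icp, fragment_policy = fragment_policy,
                 slice_oracle = slice_oracle, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

roi_outer_mesh <- function(roi) {
  if (!is.null(roi$mesh)) read_stl(roi$mesh) else
    make_box_mesh(roi$min, roi$max)
}

#' Run the semiautomatic volume measurement pipeline
#'
#' For every augmented scan: coarse three-point alignment onto the baseline,
#' weighted ICP refinement (augmented region down-weighted), trimming of
#' superfluous geometry around the ROI, solidification of both open patches,
#' intersection of the baseline solid with the outer ROI and the augmented
#' solid with the slightly smaller inner ROI, Boolean subtraction, removal of
#' free-floating fragments, and volume computation in cm^3.
#'
#' A stage failure aborts that scan with a structured error record; other
#' scans continue. An augmentation reaching the trimmed scan border is
#' reported as a structured `margin_failure` (the measured volume would be
#' clipped by the scan edge).
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: per-scan records with `status`
#'   (`"ok"`/`"error"`/`"margin_failure"`), the [enclosed_volume()] result,
#'   the optional slice-oracle volume, the registration transform, RMS trace
#'   and quality gate, and component volumes before fragment removal.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  baseline <- read_stl(config$baseline_stl)
  base_lm <- read_landmarks(config$baseline_landmarks)
  roi_pair <- make_roi_pair(roi_outer_mesh(config$roi),
                            scale = config$roi$scale)
  bb_roi <- mesh_bbox(roi_pair$outer)
  crop_box <- list(type = "box",
                   min = bb_roi$min - config$crop_margin,
                   max = bb_roi$max + config$crop_margin)
  # trim the baseline once; its z extent must cover the solidify depth
  crop_box_base <- crop_box
  crop_box_base$min[3] <- crop_box$min[3] - config$solidify_depth - 2
  base_patch <- crop_mesh(baseline, crop_box_base)
  base_loops <- find_boundary_loops(base_patch)
  base_dir <- -patch_mean_normal(base_patch)
  base_solid <- close_to_solid(base_loops, depth = config$solidify_depth,
                               direction = base_dir)
  base_roi <- boolean_intersect(base_solid, roi_pair$outer,
                                voxel_mm = config$voxel_mm)

  results <- list()
  for (nm in names(config$augmented)) {
    a <- config$augmented[[nm]]
    rec <- tryCatch({
      moving <- read_stl(a$stl)
      mov_lm <- read_landmarks(a$landmarks)
      w <- if (!is.null(a$weights))
        read_weight_map(a$weights, n_vertices(moving))
      else rep(1, n_vertices(moving))
      init <- three_point_align(mov_lm, base_lm)
      if (!is.null(config$icp$init_jitter))
        init <- compose_transforms(config$icp$init_jitter, init)
      icp <- weighted_icp(moving, baseline, weights = w, init = init,
                          params = config$icp)
      aligned <- apply_transform(icp, moving)

      aug_patch <- crop_mesh(aligned, crop_box_base)
      aug_loops <- find_boundary_loops(aug_patch)
      open_comp_loops <- aug_loops$boundary_loops
      aug_solid <- close_to_solid(aug_loops, depth = config$solidify_depth,
                                  direction = base_dir)
      aug_roi <- boolean_intersect(aug_solid, roi_pair$inner,
                                   voxel_mm = config$voxel_mm)
      diff <- boolean_subtract(aug_roi, base_roi,
                               voxel_mm = config$voxel_mm)

      if (is_empty_mesh(diff)) {
        vol <- enclosed_volume(diff)
        slice <- NULL
        comp_vols <- numeric(0)
        main <- diff
      } else {
        main <- drop_disconnected(diff, policy = config$fragment_policy)
        comp_vols <- attr(main, "component_volumes")
        vol <- enclosed_volume(main)
        slice <- if (!is.null(config$slice_oracle))
          slice_volume_oracle(main, thickness = config$slice_oracle)
      }

      status <- "ok"
      msg <- NULL
      if (!is_empty_mesh(main) &&
          margin_too_close(main, aug_patch, open_comp_loops,
                           tol = 2 * config$voxel_mm + 0.05)) {
        status <- "margin_failure"
        msg <- paste("the scan margin is too close to the augmentation to",
                     "accurately calculate the volume difference")
      }
      if (!is.null(out_dir)) {
        write_transform(icp, file.path(out_dir, paste0(nm, "_transform.txt")))
        if (!is_empty_mesh(main))
          write_stl(main, file.path(out_dir, paste0(nm, "_diff.stl")))
        write_stl(aug_solid, file.path(out_dir, paste0(nm, "_solid.stl")))
      }
      list(scan = nm, status = status, message = msg,
           volume = vol, slice_volume = slice,
           transform = strip_attrs(icp),
           registration_rms = attr(icp, "rms"),
           registration_trace = attr(icp, "trace"),
           registration_quality_ok = attr(icp, "quality_ok"),
           component_volumes_mm3 = comp_vols)
    }, error = function(e) {
      list(scan = nm, status = "error", message = conditionMessage(e),
           volume = NULL, slice_volume = NULL)
    })
    results[[nm]] <- rec
  }
  out <- structure(list(results = results,
                        baseline_volume_mm3 =
                          enclosed_volume(base_roi)$volume_mm3,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    json <- file.path(out_dir, "results.json")
    jsonlite::write_json(pipeline_result_json(out), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  out
}

strip_attrs <- function(tr) rigid_transform(tr$rotation, tr$translation)

patch_mean_normal <- function(mesh) {
  fn <- face_normals(mesh)
  avg <- colSums(fn$normals * fn$areas)
  avg / sqrt(sum(avg^2))
}

# the measured graft must stay clear of the open scan border: if the kept
# difference component comes within `tol` of the trimmed scan's boundary
# loop the measurement is clipped by the scan edge
margin_too_close <- function(main, patch, loops, tol) {
  if (length(loops) == 0) return(FALSE)
  loop_pts <- patch$vertices[unlist(loops), , drop = FALSE]
  v <- main$vertices
  # subsample for speed; the diff surface is dense
  if (nrow(v) > 4000) v <- v[seq(1, nrow(v), length.out = 4000), , drop = FALSE]
  for (i in seq_len(nrow(loop_pts))) {
    d2 <- (v[, 1] - loop_pts[i, 1])^2 + (v[, 2] - loop_pts[i, 2])^2 +
      (v[, 3] - loop_pts[i, 3])^2
    if (min(d2) < tol^2) return(TRUE)
  }
  FALSE
}

pipeline_result_json <- function(x) {
  lapply(x$results, function(r) {
    o <- list(scan = r$scan, status = r$status)
    if (!is.null(r$message)) o$message <- r$message
    if (!is.null(r$volume)) {
      o$volume_cm3 <- r$volume$volume_cm3
      o$volume_mm3 <- r$volume$volume_mm3
      o$n_components <- r$volume$n_components
    }
    if (!is.null(r$slice_volume))
      o$slice_volume_cm3 <- r$slice_volume$volume_cm3
    if (!is.null(r$registration_rms)) {
      o$registration_rms_mm <- r$registration_rms
      o$registration_quality_ok <- r$registration_quality_ok
    }
    o
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  for (r in x$results) {
    if (r$status == "ok")
      cat(sprintf("%s: %.4f cm^3 (reg RMS %.3f mm)\n", r$scan,
                  r$volume$volume_cm3, r$registration_rms))
    else
      cat(sprintf("%s: %s - %s\n", r$scan, r$status, r$message))
  }
  invisible(x)
}

#' Run a phantom study through the pipeline
#'
#' Processes every specimen/technique of a study directory produced by
#' [generate_study()] (or a compatible manifest), optionally several times
#' with jittered ROI placement and registration initialization to emulate
#' independent re-measurement sessions, and returns the tidy measurement
#' table consumed by [summarize_table()] and
#' [icc_two_way_mixed_single()].
#'
#' @param study_dir directory containing `manifest.csv`.
#' @param n_runs number of measurement repetitions (default 2, emulating the
#'   two reading timepoints).
#' @param jitter list with `roi_shift_sd` (mm, random ROI displacement) and
#'   `init_angle_deg`/`init_translation` (perturbation of the ICP
#'   initialization) applied to runs after the first.
#' @param voxel_mm,solidify_depth,crop_margin,fragment_policy,icp,roi_scale
#'   pipeline settings, see [pipeline_config()].
#' @param slice_oracle slice thickness (mm) or NULL.
#' @param seed seed for the jitter draws.
#' @return data frame: specimen, technique, run, timepoint, volume_cm3,
#'   slice_volume_cm3, truth_cm3, status, registration_rms.
#' @export
run_study <- function(study_dir, n_runs = 2,
                      jitter = list(roi_shift_sd = 0.3, init_angle_deg = 0.5,
                                    init_translation = 0.3),
                      voxel_mm = 0.1, solidify_depth = 5, crop_margin = 3,
                      fragment_policy = "largest", icp = icp_params(),
                      roi_scale = 0.98, slice_oracle = 0.25, seed = 1) {
  manifest_path <- file.path(study_dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("study directory has no manifest.csv: ", study_dir, call. = FALSE)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("specimen", "technique", "truth_cm3", "stl", "landmarks",
            "baseline_stl", "baseline_landmarks",
            "roi_min_x", "roi_max_x")
  if (!all(need %in% names(manifest)))
    stop("manifest is missing required columns", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    for (run in seq_len(n_runs)) {
      roi_min <- c(m$roi_min_x, m$roi_min_y, m$roi_min_z)
      roi_max <- c(m$roi_max_x, m$roi_max_y, m$roi_max_z)
      icp_run <- icp
      if (run > 1) {
        shift <- stats::rnorm(3, 0, jitter$roi_shift_sd)
        roi_min <- roi_min + shift
        roi_max <- roi_max + shift
        icp_run$init_jitter <- random_rigid_transform(
          jitter$init_angle_deg * stats::runif(1),
          jitter$init_translation * stats::runif(1))
      }
      cfg <- pipeline_config(
        baseline_stl = m$baseline_stl,
        baseline_landmarks = m$baseline_landmarks,
        augmented = stats::setNames(
          list(list(stl = m$stl, landmarks = m$landmarks,
                    weights = if ("weights" %in% names(m)) m$weights)),
          m$technique),
        roi = list(min = roi_min, max = roi_max, scale = roi_scale),
        crop_margin = crop_margin, solidify_depth = solidify_depth,
        voxel_mm = voxel_mm, icp = icp_run,
        fragment_policy = fragment_policy, slice_oracle = slice_oracle,
        seed = seed)
      res <- run_pipeline(cfg)$results[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        specimen = m$specimen, technique = m$technique, run = run,
        timepoint = paste0("t", run - 1),
        volume_cm3 = if (res$status != "error") res$volume$volume_cm3 else NA,
        slice_volume_cm3 = if (!is.null(res$slice_volume))
          res$slice_volume$volume_cm3 else NA,
        truth_cm3 = m$truth_cm3, status = res$status,
        registration_rms = if (!is.null(res$registration_rms))
          res$registration_rms else NA)
    }
  }
  do.call(rbind, rows)
}
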