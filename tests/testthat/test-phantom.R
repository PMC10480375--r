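test_that("baseline phantom is an open ridge and fully reproducible", {
  spec <- phantom_spec("B", seed = 12)
  b1 <- generate_baseline(spec)
  b2 <- generate_baseline(spec)
  expect_identical(b1$mesh$vertices, b2$mesh$vertices)
  expect_identical(b1$mesh$faces, b2$mesh$faces)
  s <- mesh_summary(b1$mesh)
  expect_false(s$watertight)
  expect_equal(s$n_components, 1)
  expect_length(find_boundary_loops(b1$mesh)$boundary_loops, 1)
  # landmarks sit on the surface, away from the augmentation zone
  cp <- augvol:::cpp_closest_points(b1$mesh$vertices, b1$mesh$faces,
                                    unclass(b1$landmarks))
  expect_lt(max(cp$dist), 0.05)
})

test_that("scanner noise displaces vertices by the requested amount", {
  clean <- generate_baseline(phantom_spec("B", seed = 13, noise_sd = 0))
  noisy <- generate_baseline(phantom_spec("B", seed = 13, noise_sd = 0.05))
  expect_identical(dim(clean$mesh$vertices), dim(noisy$mesh$vertices))
  expect_identical(clean$mesh$faces, noisy$mesh$faces)
  disp <- sqrt(rowSums((noisy$mesh$vertices - clean$mesh$vertices)^2))
  expect_equal(sqrt(mean(disp^2)), 0.05, tolerance = 0.05)
})

test_that("hemisphere ground truth matches the analytic value", {
  spec <- phantom_spec("B", aug_shape = "hemisphere", hemisphere_radius = 4.3,
                       seed = 14)
  aug <- generate_augmented(generate_baseline(spec), spec)
  expect_equal(aug$truth$analytic_volume_mm3, 2 / 3 * pi * 4.3^3)
  expect_equal(aug$truth$ground_truth_volume_mm3,
               aug$truth$analytic_volume_mm3, tolerance = 0.01)
})

test_that("plateau phantoms are scaled to their target volume", {
  for (tech in c("B", "S1", "S2")) {
    spec <- phantom_spec(tech, seed = 15)
    aug <- generate_augmented(generate_baseline(spec), spec)
    expect_equal(aug$truth$ground_truth_volume_cm3, spec$target_volume_cm3,
                 tolerance = 0.01)
  }
})

test_that("floating fragments appear as extra disconnected components", {
  spec <- phantom_spec("S1", seed = 16, n_floating_fragments = 3)
  aug <- generate_augmented(generate_baseline(spec), spec)
  expect_gte(mesh_summary(aug$mesh)$n_components, 4)
  # fragment vertices (3 icospheres of 162 vertices) carry zero ICP weight
  expect_true(all(utils::tail(aug$weights, 3 * 162) == 0))
})

test_that("an augmentation in the scan margin is rejected", {
  spec <- phantom_spec("B", seed = 17, aug_center = c(-6, 33))
  expect_error(generate_augmented(generate_baseline(spec), spec),
               "margin")
  ok <- phantom_spec("B", seed = 17, aug_center = c(-6, 33),
                     allow_margin_violation = TRUE)
  expect_no_error(generate_augmented(generate_baseline(ok), ok))
})

test_that("the applied pose is recorded and actually applied", {
  spec <- phantom_spec("B", seed = 18, landmark_sd = 0, noise_sd = 0)
  base <- generate_baseline(spec)
  aug <- generate_augmented(base, spec)
  pose <- aug$truth$applied_pose
  expect_equal(rotation_angle_deg(pose), spec$pose_angle_deg,
               tolerance = 1e-9)
  expect_equal(sqrt(sum(pose$translation^2)), spec$pose_translation,
               tolerance = 1e-9)
  # un-posing the augmented scan puts it back over the baseline
  back <- apply_transform(invert_transform(pose), aug$mesh)
  far_from_aug <- aug$weights == 1
  expect_lt(max(abs(back$vertices[far_from_aug, ] -
                      base$mesh$vertices[far_from_aug, ])), 1e-9)
})

test_that("generate_study writes a reproducible, well-formed study", {
  d1 <- withr::local_tempdir()
  man <- generate_study(1, d1, techniques = c("B", "S1", "S2"), seed = 6,
                        spec_overrides = list(pitch = 0.4))
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$stl)))
  expect_true(all(file.exists(man$landmarks)))
  expect_true(all(file.exists(man$weights)))
  expect_true(file.exists(file.path(d1, "manifest.csv")))

  d2 <- withr::local_tempdir()
  man2 <- generate_study(1, d2, techniques = c("B", "S1", "S2"), seed = 6,
                         spec_overrides = list(pitch = 0.4))
  expect_equal(man$truth_cm3, man2$truth_cm3, tolerance = 1e-12)
  # identical STL bytes for identical seeds
  expect_identical(readBin(man$stl[1], "raw", file.size(man$stl[1])),
                   readBin(man2$stl[1], "raw", file.size(man2$stl[1])))
})

test_that("study target volumes follow the configured technique scales", {
  d <- withr::local_tempdir()
  man <- generate_study(8, d, techniques = "B", seed = 9,
                        spec_overrides = list(pitch = 0.5))
  expect_true(all(man$truth_cm3 > 0.35 - 3.5 * 0.085))
  expect_true(all(man$truth_cm3 < 0.35 + 3.5 * 0.085))
  expect_lt(abs(mean(man$truth_cm3) - 0.35), 0.12)
})
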