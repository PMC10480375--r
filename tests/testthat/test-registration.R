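test_that("rigid transforms validate, compose and invert", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  tr <- rigid_transform(rot_z(0.3), c(1, -2, 0.5))
  id <- compose_transforms(invert_transform(tr), tr)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  # 4x4 matrix round trip through a file
  p <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, p)
  tr2 <- read_transform(p)
  expect_equal(tr2$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(tr2$translation, tr$translation, tolerance = 1e-12)
})

test_that("three-point alignment recovers exact and noisy poses", {
  fixed <- landmark_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 3)))
  # identity
  t0 <- three_point_align(fixed, fixed)
  expect_lt(max(abs(t0$rotation - diag(3))), 1e-9)
  expect_lt(attr(t0, "rms"), 1e-9)
  # 90 degrees about z plus translation: exact recovery
  truth <- rigid_transform(rot_z(pi / 2), c(5, 0, 0))
  moving <- apply_transform(invert_transform(truth), fixed)
  fit <- three_point_align(moving, fixed)
  expect_lt(max(abs(fit$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - truth$translation)), 1e-9)
  # collinear landmarks are rejected at construction
  expect_error(landmark_set(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("three-point residual stays within 3 sigma under landmark noise", {
  set.seed(101)
  fixed <- landmark_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 3)))
  sigma <- 0.1
  for (i in 1:100) {
    noisy <- unclass(fixed) + matrix(rnorm(9, 0, sigma), 3, 3)
    fit <- three_point_align(landmark_set(noisy), fixed)
    expect_lte(attr(fit, "rms"), 3 * sigma)
  }
})

test_that("kabsch recovers exact poses and ignores zero-weight outliers", {
  set.seed(7)
  P <- matrix(rnorm(60, sd = 5), ncol = 3)
  truth <- random_rigid_transform(37, 8)
  Q <- apply_transform(truth, P)
  fit <- kabsch(P, Q)
  expect_lt(max(abs(fit$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - truth$translation)), 1e-9)

  # gross outliers with weight zero leave the fit untouched
  P2 <- rbind(P, matrix(rnorm(30, mean = 100), ncol = 3))
  Q2 <- rbind(Q, matrix(rnorm(30, mean = -100), ncol = 3))
  w <- c(rep(1, 20), rep(0, 10))
  fit2 <- kabsch(P2, Q2, w)
  expect_lt(max(abs(fit2$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit2$translation - truth$translation)), 1e-9)

  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch(line, line + 1), "collinear")
})

test_that("kabsch objective beats random perturbed transforms", {
  set.seed(8)
  P <- matrix(rnorm(45, sd = 3), ncol = 3)
  Q <- apply_transform(random_rigid_transform(20, 5), P) +
    matrix(rnorm(45, sd = 0.2), ncol = 3)
  w <- runif(15)
  fit <- kabsch(P, Q, w)
  objective <- function(tr) sum(w * rowSums((apply_transform(tr, P) - Q)^2))
  best <- objective(fit)
  for (i in 1:1000) {
    pert <- compose_transforms(random_rigid_transform(runif(1, 0, 10),
                                                      runif(1, 0, 1)), fit)
    expect_lte(best, objective(pert) + 1e-9)
  }
})

test_that("kabsch residual is invariant to a common pre-rotation", {
  set.seed(9)
  P <- matrix(rnorm(30, sd = 4), ncol = 3)
  Q <- apply_transform(random_rigid_transform(15, 3), P) +
    matrix(rnorm(30, sd = 0.1), ncol = 3)
  pre <- random_rigid_transform(53, 11)
  r1 <- attr(kabsch(P, Q), "rms")
  r2 <- attr(kabsch(apply_transform(pre, P), apply_transform(pre, Q)), "rms")
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("weighted ICP recovers a known pose on the ridge phantom", {
  spec <- phantom_spec("B", seed = 42)
  base <- generate_baseline(spec)
  truth <- with_seed_test(1, random_rigid_transform(5, 2))
  moving <- apply_transform(truth, base$mesh)
  fit <- weighted_icp(moving, base$mesh,
                      init = rigid_transform(),
                      params = icp_params(max_iterations = 400))
  err <- compose_transforms(fit, truth)
  expect_lt(rotation_angle_deg(err), 0.1)
  expect_lt(sqrt(sum(err$translation^2)), 0.05)
  # rms trace is non-increasing beyond numerical tolerance
  tr <- attr(fit, "trace")
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("a zero-weighted bump does not degrade ICP recovery", {
  spec <- phantom_spec("B", seed = 43, pose_angle_deg = 5,
                       pose_translation = 2, landmark_sd = 0)
  base <- generate_baseline(spec)
  aug <- generate_augmented(base, spec)
  init <- three_point_align(aug$landmarks, base$landmarks)
  fit_bump <- weighted_icp(aug$mesh, base$mesh, weights = aug$weights,
                           init = init)
  err_bump <- compose_transforms(fit_bump, aug$truth$applied_pose)

  plain <- apply_transform(aug$truth$applied_pose, base$mesh)
  fit_free <- weighted_icp(plain, base$mesh, init = init)
  err_free <- compose_transforms(fit_free, aug$truth$applied_pose)

  expect_lt(rotation_angle_deg(err_bump),
            rotation_angle_deg(err_free) + 0.05)
  expect_lt(sqrt(sum(err_bump$translation^2)),
            sqrt(sum(err_free$translation^2)) + 0.025)
})

test_that("ICP initialized at the ground truth does not diverge", {
  spec <- phantom_spec("B", seed = 44)
  base <- generate_baseline(spec)
  moved <- apply_transform(random_rigid_transform(4, 1.5), base$mesh)
  # use the exact inverse as init: the first rms is already ~0
  truth <- attr(weighted_icp(moved, base$mesh), "rms")  # converged reference
  fitted <- weighted_icp(moved, base$mesh,
                         init = weighted_icp(moved, base$mesh),
                         params = icp_params(max_iterations = 5))
  expect_lt(attr(fitted, "rms"), max(truth, 1e-6) + 1e-4)
})

test_that("zero-weight vertices are provably inert", {
  spec <- phantom_spec("B", seed = 45, pitch = 0.4)
  base <- generate_baseline(spec)
  aug <- generate_augmented(base, spec)
  fit1 <- weighted_icp(aug$mesh, base$mesh, weights = aug$weights,
                       init = three_point_align(aug$landmarks,
                                                base$landmarks),
                       params = icp_params(max_iterations = 10))
  # arbitrarily mangle every zero-weight vertex
  mangled <- aug$mesh$vertices
  idx <- aug$weights == 0
  mangled[idx, ] <- mangled[idx, ] + matrix(runif(3 * sum(idx), -50, 50),
                                            ncol = 3)
  m2 <- triangle_mesh(mangled, aug$mesh$faces)
  fit2 <- weighted_icp(m2, base$mesh, weights = aug$weights,
                       init = three_point_align(aug$landmarks,
                                                base$landmarks),
                       params = icp_params(max_iterations = 10))
  expect_identical(fit1$rotation, fit2$rotation)
  expect_identical(fit1$translation, fit2$translation)
})

test_that("ICP errors on insufficient overlap", {
  spec <- phantom_spec("B", seed = 46, pitch = 0.5)
  base <- generate_baseline(spec)
  far <- apply_transform(rigid_transform(diag(3), c(500, 0, 0)), base$mesh)
  expect_error(weighted_icp(far, base$mesh,
                            params = icp_params(max_correspondence_dist = 1)),
               "insufficient overlap")
})
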