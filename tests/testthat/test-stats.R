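test_that("TOST declares equivalence and non-equivalence correctly", {
  set.seed(21)
  tiny <- rnorm(19, 0, 0.005)
  r <- tost_paired(tiny, margin = 0.15)
  expect_true(r$equivalent)
  expect_false(r$different_from_zero)

  big <- rnorm(19, 0.5, 0.01)
  r2 <- tost_paired(big, margin = 0.15)
  expect_false(r2$equivalent)
  expect_true(r2$different_from_zero)
})

test_that("TOST reproduces a known confidence interval exactly", {
  # n = 19 differences with mean -0.0145 and the sd implied by a 90% CI of
  # [-0.062, 0.033]: sd = half_width * sqrt(n) / t_{0.95, 18}
  n <- 19
  half_width <- (0.033 - (-0.062)) / 2
  s <- half_width * sqrt(n) / qt(0.95, n - 1)
  set.seed(22)
  d <- as.numeric(scale(rnorm(n))) * s + (-0.0145)
  r <- tost_paired(d, margin = 0.15)
  expect_equal(r$ci90, c(-0.062, 0.033), tolerance = 1e-3)
  expect_lt(r$tost_p, 0.001)
  expect_true(r$equivalent)
  expect_false(r$different_from_zero)
  # independent cross-check of the one-sided p values against t.test
  p_upper <- t.test(d, mu = 0.15, alternative = "less")$p.value
  p_lower <- t.test(d, mu = -0.15, alternative = "greater")$p.value
  expect_equal(r$tost_p, max(p_upper, p_lower), tolerance = 1e-12)
})

test_that("TOST decision is equivalent to the 90% CI lying in the bounds", {
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(5:30, 1)
    d <- rnorm(n, runif(1, -0.3, 0.3), runif(1, 0.01, 0.3))
    r <- tost_paired(d, margin = 0.15)
    in_bounds <- r$ci90[1] > -0.15 && r$ci90[2] < 0.15
    expect_identical(r$equivalent, in_bounds)
    expect_identical(r$equivalent, r$tost_p < 0.05)
  }
})

test_that("TOST handles degenerate and missing data", {
  r <- tost_paired(rep(0.01, 10), margin = 0.15)
  expect_true(r$degenerate)
  expect_true(r$equivalent)
  pm <- paired_measurements(c(1, 2, 3, NA, 5), c(1.1, 2, 2.9, 4, NA))
  expect_equal(attr(pm, "n_excluded"), 2)
  expect_equal(nrow(pm), 3)
  expect_error(tost_paired(c(0.1, 0.2), margin = 0.15), "at least 3")
})

test_that("ICC is exact against the ANOVA oracle and known fixture", {
  # frozen fixture: two-way design verified against an independent
  # mixed-model implementation (12 subjects, 2 timepoints)
  t0 <- c(0.828745, 0.728946, 0.876891, 0.867465, 0.631782, 0.663626,
          0.829075, 0.77054, 0.794791, 0.709607, 0.903597, 0.866911)
  t1 <- c(0.828858, 0.709359, 0.888187, 0.90196, 0.642661, 0.70142,
          0.864339, 0.77341, 0.798243, 0.716951, 0.901465, 0.902581)
  a <- icc_two_way_mixed_single(cbind(t0, t1), "agreement")
  expect_equal(a$icc, 0.9706954342681088, tolerance = 1e-12)
  expect_equal(a$ci95, c(0.858126, 0.992283), tolerance = 1e-5)
  expect_equal(a$interpretation, "excellent")
  cc <- icc_two_way_mixed_single(cbind(t0, t1), "consistency")
  expect_equal(cc$icc, 0.9791564620225635, tolerance = 1e-12)

  # mean squares match aov() sums of squares to near machine precision
  df <- data.frame(score = c(t0, t1), subj = factor(rep(1:12, 2)),
                   tp = factor(rep(1:2, each = 12)))
  ms <- summary(aov(score ~ subj + tp, data = df))[[1]]$`Mean Sq`
  expect_equal(a$ms_rows, ms[1], tolerance = 1e-10)
  expect_equal(a$ms_cols, ms[2], tolerance = 1e-10)
  expect_equal(a$ms_error, ms[3], tolerance = 1e-10)
})

test_that("ICC behaves at the design extremes", {
  x <- c(0.3, 0.5, 0.8, 0.4, 0.9, 0.66, 0.21)
  perfect <- icc_two_way_mixed_single(cbind(x, x))
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$interpretation, "excellent")

  set.seed(24)
  noise <- matrix(rnorm(100), 50, 2)   # no subject effect
  r <- icc_two_way_mixed_single(noise)
  expect_lt(abs(r$icc), 0.35)
  # aov oracle on the random data as well
  df <- data.frame(score = as.vector(noise), subj = factor(rep(1:50, 2)),
                   tp = factor(rep(1:2, each = 50)))
  ms <- summary(aov(score ~ subj + tp, data = df))[[1]]$`Mean Sq`
  expect_equal(r$ms_rows, ms[1], tolerance = 1e-10)
  expect_equal(r$ms_error, ms[3], tolerance = 1e-10)

  expect_error(icc_two_way_mixed_single(cbind(1:3, 1:3)), "at least 5")
  expect_error(icc_two_way_mixed_single(cbind(c(1:5, NA), 1:6)),
               "incomplete")
})

test_that("ICC distinguishes agreement from consistency and shifts", {
  set.seed(25)
  x <- rnorm(20, 0.8, 0.09)
  y <- x + rnorm(20, 0, 0.02)
  base_a <- icc_two_way_mixed_single(cbind(x, y), "agreement")$icc
  # adding the same constant to all ratings changes nothing
  shifted <- icc_two_way_mixed_single(cbind(x, y) + 5, "agreement")$icc
  expect_equal(shifted, base_a, tolerance = 1e-12)
  # a systematic rater offset lowers absolute agreement, not consistency
  off_a <- icc_two_way_mixed_single(cbind(x, y + 0.08), "agreement")$icc
  off_c <- icc_two_way_mixed_single(cbind(x, y + 0.08), "consistency")$icc
  cons <- icc_two_way_mixed_single(cbind(x, y), "consistency")$icc
  expect_lt(off_a, base_a)
  expect_equal(off_c, cons, tolerance = 1e-12)
})

test_that("ICC confidence intervals cover the estimate in simulation", {
  # test-retest regime at the study scale: between-subject sd 0.09,
  # within-subject sd 0.02
  set.seed(26)
  hits <- 0
  n_rep <- 500
  true_icc <- 0.09^2 / (0.09^2 + 0.02^2)
  for (i in seq_len(n_rep)) {
    subj <- rnorm(20, 0.8, 0.09)
    m <- cbind(subj + rnorm(20, 0, 0.02), subj + rnorm(20, 0, 0.02))
    r <- icc_two_way_mixed_single(m)
    if (true_icc >= r$ci95[1] && true_icc <= r$ci95[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("Wilcoxon signed rank handles symmetry, ties and zeros", {
  sym <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3, 4, -4))
  expect_equal(sym$p_value, 1)

  allpos <- wilcoxon_signed_rank(1:6)
  expect_equal(allpos$p_one_sided, 1 / 64)
  expect_equal(allpos$p_value, 1 / 32)

  zeros <- wilcoxon_signed_rank(rep(0, 8))
  expect_equal(zeros$p_value, 1)
  expect_equal(zeros$n_zero, 8)

  # tie-free case matches the base R exact distribution
  set.seed(27)
  d <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("Wilcoxon exact distribution matches full 2^n enumeration", {
  enumerate_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    p_ge <- mean(v_all >= v_obs - 1e-9)
    p_le <- mean(v_all <= v_obs + 1e-9)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(28)
  cases <- list(rnorm(7), round(rnorm(9), 1),           # with ties
                c(0.5, 0.5, -0.5, 1, 2, 2, -2, 3),      # heavy ties
                rnorm(12))
  for (d in cases) {
    expect_equal(wilcoxon_signed_rank(d)$p_value, enumerate_p(d),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon approximation agrees with exact at the switch point", {
  set.seed(29)
  for (i in 1:20) {
    d <- rnorm(20, 0.1)
    pe <- wilcoxon_signed_rank(d, exact_max = 25)$p_value
    pa <- wilcoxon_signed_rank(d, exact_max = 5)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("summarize_table builds the study report", {
  set.seed(30)
  n <- 10
  grid <- expand.grid(specimen = 1:n, technique = c("B", "S1"),
                      timepoint = c("t0", "t1"),
                      method = c("manual", "semiautomatic"))
  truthv <- c(B = 0.35, S1 = 0.76)
  grid$volume_cm3 <- truthv[as.character(grid$technique)] +
    rnorm(nrow(grid), 0, 0.05)
  rep <- summarize_table(grid, margin = 0.15)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$n_pairs == n))
  expect_true(all(c("mean_difference", "ci90_lower", "tost_p", "nhst_p") %in%
                    names(rep)))

  one <- summarize_table(grid[grid$technique == "B" &
                                grid$timepoint == "t0", ])
  expect_equal(nrow(one), 1)

  expect_error(summarize_table(data.frame()), "must contain")

  # time comparison variant uses the signed-rank test
  tgrid <- expand.grid(specimen = 1:n, technique = "B",
                       method = c("manual", "semiautomatic"))
  tgrid$time_s <- rnorm(nrow(tgrid), 290, 60)
  trep <- summarize_table(tgrid, value = "time_s")
  expect_true("wilcoxon_p" %in% names(trep))
  expect_equal(nrow(trep), 1)
})
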