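#' Paired measurements of two methods
#'
#' Pairs with a missing side are excluded from analysis and counted, mirroring
#' complete-case handling when one specimen cannot be measured by one method.
#'
#' @param method_a,method_b numeric vectors (same length), one value per
#'   specimen; `NA` for a missing measurement.
#' @param specimen optional specimen ids.
#' @return a `paired_measurements` data frame with attribute `n_excluded`.
#' @export
paired_measurements <- function(method_a, method_b, specimen = NULL) {
  stopifnot(length(method_a) == length(method_b))
  if (is.null(specimen)) specimen <- seq_along(method_a)
  df <- data.frame(specimen = specimen, method_a = method_a,
                   method_b = method_b)
  complete <- stats::complete.cases(df$method_a, df$method_b)
  out <- df[complete, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!complete)
  class(out) <- c("paired_measurements", "data.frame")
  out
}

#' Paired TOST equivalence test
#'
#' Two one-sided t tests of the paired differences `d = method_a - method_b`
#' against the margins `-margin` and `+margin`. Equivalence is declared when
#' both one-sided tests reject, equivalently when the `(1 - 2 alpha)`
#' confidence interval of the mean difference lies entirely inside
#' `(-margin, +margin)`. The standard paired NHST t test against zero is
#' reported alongside.
#'
#' @param pairs a [paired_measurements()], or a numeric vector of differences.
#' @param margin equivalence margin (same units as the data; the study margin
#'   for volumes is 0.15 cm^3).
#' @param alpha significance level (default 0.05; the reported equivalence CI
#'   is then the 90% CI).
#' @return an `equivalence_result`: mean difference, `ci90`, `ci95`, `tost_p`
#'   (max of the two one-sided p values), `nhst_p`, `bounds`, `equivalent`,
#'   `different_from_zero`, `n`, `n_excluded`.
#' @export
tost_paired <- function(pairs, margin = 0.15, alpha = 0.05) {
  stopifnot(margin > 0, alpha > 0, alpha < 0.5)
  if (inherits(pairs, "paired_measurements")) {
    d <- pairs$method_a - pairs$method_b
    n_excluded <- attr(pairs, "n_excluded")
  } else {
    d <- as.numeric(pairs)
    n_excluded <- sum(is.na(d))
    d <- d[!is.na(d)]
  }
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    # degenerate: zero-width CI, decide by position of the mean
    inside <- abs(m) < margin
    res <- list(mean_difference = m, ci90 = c(m, m), ci95 = c(m, m),
                tost_p = if (inside) 0 else 1,
                nhst_p = if (m == 0) 1 else 0,
                bounds = c(-margin, margin),
                equivalent = inside, different_from_zero = m != 0,
                n = n, n_excluded = n_excluded, degenerate = TRUE)
    class(res) <- "equivalence_result"
    return(res)
  }
  se <- s / sqrt(n)
  t_lower <- (m + margin) / se          # H0: mu <= -margin
  t_upper <- (m - margin) / se          # H0: mu >= +margin
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  tost_p <- max(p_lower, p_upper)
  ci90 <- m + c(-1, 1) * stats::qt(1 - alpha, df) * se
  ci95 <- m + c(-1, 1) * stats::qt(1 - alpha / 2, df) * se
  t0 <- m / se
  nhst_p <- 2 * stats::pt(-abs(t0), df)
  res <- list(mean_difference = m, ci90 = ci90, ci95 = ci95,
              tost_p = tost_p, nhst_p = nhst_p,
              bounds = c(-margin, margin),
              equivalent = tost_p < alpha,
              different_from_zero = nhst_p < alpha,
              n = n, n_excluded = n_excluded, degenerate = FALSE)
  class(res) <- "equivalence_result"
  res
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "mean difference %.4f [90%% CI %.4f, %.4f], bounds +/-%.3f\n",
    x$mean_difference, x$ci90[1], x$ci90[2], x$bounds[2]))
  cat(sprintf("TOST p = %.4g (%sequivalent), NHST p = %.4g (%sdifferent from 0), n = %d\n",
              x$tost_p, if (x$equivalent) "" else "not ",
              x$nhst_p, if (x$different_from_zero) "" else "not ", x$n))
  invisible(x)
}

#' Two-way mixed-effects single-measure intraclass correlation
#'
#' Test-retest (intra-rater) reliability of repeated measurements: a two-way
#' ANOVA decomposition (subjects x measurements) with the single-measure
#' absolute-agreement coefficient ICC(A,1) by default (consistency ICC(C,1)
#' via `type`). The 95% CI uses the F-distribution method, and the point
#' estimate is interpreted on the conventional bands
#' (< 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, >= 0.9 excellent).
#'
#' @param ratings numeric matrix, one row per subject, one column per
#'   measurement occasion (at least 5 subjects, 2 or more occasions, no
#'   missing values).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level confidence level (default 0.95).
#' @return an `icc_result`: `icc`, `ci95`, `model`, `interpretation`, and the
#'   mean squares (`ms_rows`, `ms_cols`, `ms_error`).
#' @export
icc_two_way_mixed_single <- function(ratings, type = c("agreement",
                                                       "consistency"),
                                     conf_level = 0.95) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 measurements per subject", call. = FALSE)
  if (anyNA(ratings))
    stop("incomplete design: every subject needs all measurements",
         call. = FALSE)
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  ss_rows <- k * sum((rm_ - gm)^2)
  ss_cols <- n * sum((cm - gm)^2)
  ss_tot <- sum((ratings - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level

  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    # McGraw & Wong F-method with Satterthwaite df
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    f_l <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  }
  interp <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
            else if (icc < 0.9) "good" else "excellent"
  res <- list(icc = icc, ci95 = c(lower, upper),
              model = sprintf("two-way mixed effects, single measures, %s",
                              if (type == "agreement") "absolute agreement"
                              else "consistency"),
              interpretation = interp,
              ms_rows = msr, ms_cols = msc, ms_error = mse, n = n, k = k)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f [%.3f, %.3f] (%s; %s)\n", x$icc, x$ci95[1],
              x$ci95[2], x$model, x$interpretation))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired data
#'
#' One-sample signed-rank test on the paired differences: zeros are dropped
#' (and counted), tied absolute differences receive mid-ranks, and the null
#' distribution of the positive-rank sum is computed exactly (permutation
#' distribution conditional on the observed ranks, via a generating-function
#' convolution that remains exact under ties) for up to 25 non-zero pairs,
#' with a tie-corrected normal approximation with continuity correction
#' beyond that.
#'
#' @param pairs a [paired_measurements()], or a numeric vector of differences.
#' @param exact_max use the exact distribution for up to this many non-zero
#'   differences (default 25).
#' @return a `signed_rank_result`: statistic `V` (positive-rank sum),
#'   `p_value` (two-sided), `p_one_sided` (greater), `n_nonzero`, `n_zero`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(pairs, exact_max = 25) {
  d <- if (inherits(pairs, "paired_measurements"))
    pairs$method_a - pairs$method_b else as.numeric(pairs)
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    res <- list(V = 0, p_value = 1, p_one_sided = 1, n_nonzero = 0,
                n_zero = n_zero, method = "degenerate (all zero)")
    class(res) <- "signed_rank_result"
    return(res)
  }
  r <- rank(abs(d))             # mid-ranks under ties
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact permutation distribution over the 2^n sign assignments via
    # convolution on doubled ranks (mid-ranks are multiples of 1/2)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1)
    dist[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(total + 1 - ri)])
      dist <- (dist + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p_ge <- sum(dist[(v2 + 1):(total + 1)])
    p_le <- sum(dist[1:(v2 + 1)])
    p_one <- p_ge
    p_two <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z_two <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p_two <- min(1, 2 * stats::pnorm(-abs(z_two)))
    z_one <- (V - mu - 0.5) / sqrt(sigma2)
    p_one <- stats::pnorm(z_one, lower.tail = FALSE)
    method <- "normal approximation with continuity correction"
  }
  res <- list(V = V, p_value = p_two, p_one_sided = p_one,
              n_nonzero = n, n_zero = n_zero, method = method)
  class(res) <- "signed_rank_result"
  res
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: V = %.1f, two-sided p = %.4g (%s), n = %d\n",
              x$V, x$p_value, x$method, x$n_nonzero))
  invisible(x)
}

#' Summary table of a volume (or time) study
#'
#' The machine twin of the study report: per technique and timepoint, mean
#' +/- SD per method, the mean paired difference with its 90% CI, and the
#' TOST and NHST p values; with `value = "time_s"` a per-technique Wilcoxon
#' signed-rank comparison of measurement times is produced instead.
#'
#' @param data tidy data frame with columns `specimen`, `technique`, `method`
#'   (exactly two levels), `timepoint` (optional), and the value column.
#' @param value name of the value column (default `"volume_cm3"`).
#' @param margin,alpha TOST settings (volumes).
#' @return a data frame, one row per technique x timepoint.
#' @export
summarize_table <- function(data, value = "volume_cm3", margin = 0.15,
                            alpha = 0.05) {
  need <- c("specimen", "technique", "method", value)
  if (!is.data.frame(data) || nrow(data) == 0 || !all(need %in% names(data)))
    stop("input must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  methods <- sort(unique(as.character(data$method)))
  if (length(methods) != 2)
    stop("exactly two methods are required, got: ",
         paste(methods, collapse = ", "), call. = FALSE)
  if (!"timepoint" %in% names(data)) data$timepoint <- "t0"
  is_time <- value == "time_s"
  out <- list()
  for (tech in unique(as.character(data$technique))) {
    for (tp in unique(as.character(data$timepoint))) {
      sub <- data[data$technique == tech & data$timepoint == tp, ]
      if (nrow(sub) == 0) next
      wide <- merge(sub[sub$method == methods[1], c("specimen", value)],
                    sub[sub$method == methods[2], c("specimen", value)],
                    by = "specimen", all = TRUE)
      a <- wide[[2]]; b <- wide[[3]]
      pm <- paired_measurements(a, b, wide$specimen)
      row <- data.frame(
        technique = tech, timepoint = tp,
        n_a = sum(!is.na(a)), n_b = sum(!is.na(b)), n_pairs = nrow(pm),
        mean_a = mean(a, na.rm = TRUE), sd_a = stats::sd(a, na.rm = TRUE),
        mean_b = mean(b, na.rm = TRUE), sd_b = stats::sd(b, na.rm = TRUE),
        mean_total = mean(c(a, b), na.rm = TRUE),
        sd_total = stats::sd(c(a, b), na.rm = TRUE))
      if (is_time) {
        w <- wilcoxon_signed_rank(pm)
        row$wilcoxon_p <- w$p_value
      } else {
        eq <- tost_paired(pm, margin = margin, alpha = alpha)
        row$mean_difference <- eq$mean_difference
        row$ci90_lower <- eq$ci90[1]
        row$ci90_upper <- eq$ci90[2]
        row$tost_p <- eq$tost_p
        row$nhst_p <- eq$nhst_p
        row$equivalent <- eq$equivalent
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  attr(res, "methods") <- methods
  res
}
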