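test_that("Anderson-Darling matches the reference implementation", {
  set.seed(13)
  for (i in 1:10) {
    x <- switch(i %% 3 + 1, rnorm(100), rexp(150), rnorm(60, 5, 2)^2)
    mine <- anderson_darling(x)
    ref <- nortest::ad.test(x)
    # nortest reports the unadjusted statistic but derives p from the
    # adjusted one, so the p values must agree exactly
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Anderson-Darling calibrates: ~5% type I, full power against exponential", {
  verdicts <- vapply(1:100, function(s) {
    set.seed(s)
    anderson_darling(rnorm(200))$normal
  }, logical(1))
  expect_gte(sum(verdicts), 90)
  rejections <- vapply(1:100, function(s) {
    set.seed(s + 5000)
    !anderson_darling(rexp(200))$normal
  }, logical(1))
  expect_gte(sum(rejections), 99)
})

test_that("a heavy right-skewed intensity-like sample is flagged at the strongest band", {
  set.seed(14)
  x <- exp(rnorm(200, sd = 1.2))   # lognormal: strong right skew
  v <- anderson_darling(x)
  expect_false(v$normal)
  expect_equal(v$p_band, "<0.0005")
})

test_that("the AD verdict is invariant under affine transforms", {
  set.seed(15)
  x <- rnorm(120)
  base <- anderson_darling(x)
  shifted <- anderson_darling(3.7 * x - 11)
  expect_equal(base$A2, shifted$A2, tolerance = 1e-9)
  expect_equal(base$normal, shifted$normal)
  expect_error(anderson_darling(rep(1, 50)), class = "ffa_degenerate_sample_error")
  expect_error(anderson_darling(rnorm(5)), class = "ffa_sample_size_error")
})

test_that("exact Wilcoxon p equals the full sign-enumeration oracle", {
  # spec toy case
  expect_equal(wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))$p, 0.25)
  expect_equal(wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))$statistic, 6)
  set.seed(16)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, mean = 0.4)
    if (rep %% 3 == 0) y <- x + sample(c(-2, -1, 1, 2), n, replace = TRUE) / 2  # ties
    d <- y - x
    d <- d[d != 0]
    if (length(d) < 3) next
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    Ws <- as.vector(signs %*% r)
    p_oracle <- min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
    expect_equal(wilcoxon_signed_rank(x, y)$p, p_oracle, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with wilcox.test when no ties are present", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(8:20, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0.3)
    mine <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
  expect_error(wilcoxon_signed_rank(1:4, 1:4), class = "ffa_no_information_error")
})

test_that("paired t matches the closed-form toy example and rejects degenerate input", {
  res <- paired_t(c(0, 0, 0, 0), c(2, 4, 6, 8))
  expect_equal(res$statistic, 5 / (2.581989 / 2), tolerance = 1e-3)
  expect_error(paired_t(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               class = "ffa_degenerate_sample_error")
})

test_that("paired t p values are uniform under the null", {
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    d <- rnorm(12)
    paired_t(rep(0, 12), d)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Sidak adjustment matches its closed form and preserves order", {
  expect_equal(sidak_adjust(0.05, m = 1), 0.05)
  expect_equal(sidak_adjust(0.01, m = 6), 1 - 0.99^6, tolerance = 1e-10)
  expect_equal(sidak_adjust(1, m = 3), 1)
  p <- c(0.001, 0.04, 0.2, 0.9)
  expect_equal(order(sidak_adjust(p)), order(p))
  expect_error(sidak_adjust(c(0.5, 1.2)), class = "ffa_parameter_error")
})

test_that("normality gating dispatches to the matching paired test", {
  set.seed(18)
  base <- rnorm(30, 10)
  gauss <- compare_paired(base, base + rnorm(30, 0.5, 0.5))
  expect_equal(gauss$test, "paired_t")
  expect_true(gauss$normal)
  skewed <- compare_paired(base, base + exp(rnorm(30, 0, 1.5)))
  expect_equal(skewed$test, "wilcoxon_signed_rank")
  expect_false(skewed$normal)
  # dispatch is deterministic: identical data, identical choice
  expect_identical(compare_paired(base, base + rnorm(30) * 0 + 1)$test,
                   compare_paired(base, base + 1)$test)
})

test_that("compare_paired holds its size on null cohorts", {
  rejections <- vapply(1:1000, function(s) {
    set.seed(s)
    baseline <- exp(rnorm(15, 0, 0.3))
    am <- baseline * exp(rnorm(15, 0, 0.1))
    pm <- baseline * exp(rnorm(15, 0, 0.1))
    compare_paired(am, pm)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("comparison families carry Sidak-adjusted p values and tidy/glance work", {
  set.seed(19)
  vals <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12),
                             region = c("fovea", "parafovea"),
                             session = c("AM", "PM"))
  vals$value <- exp(rnorm(nrow(vals), 0, 0.2)) +
    ifelse(vals$session == "PM", 0.3, 0)
  fam <- compare_family(vals)
  expect_equal(nrow(fam), 2)
  expect_true(all(fam$p_adj >= fam$p))
  expect_s3_class(tidy(fam), "tbl_df")
  gl <- glance(fam)
  expect_equal(gl$n_comparisons, 2L)
})

test_that("mixed-effects comparison recovers a programmed session effect", {
  ests <- vapply(1:30, function(s) {
    set.seed(s)
    subj_eff <- rnorm(6, 0, 0.05)
    df <- tidyr::expand_grid(subject = 1:6, eye = c("OS", "OD"),
                             session = c("AM", "PM"))
    df$value <- 0.5 + subj_eff[df$subject] +
      ifelse(df$session == "PM", 0.1, 0) + rnorm(nrow(df), 0, 0.02)
    mixed_effects_compare(df)$session_estimate
  }, numeric(1))
  expect_lt(abs(median(ests) - 0.1), 0.01)
  expect_true(all(ests > 0.07 & ests < 0.13))
})

test_that("mixed-effects null estimates centre on zero", {
  ests <- vapply(1:30, function(s) {
    set.seed(s + 300)
    subj_eff <- rnorm(6, 0, 0.05)
    df <- tidyr::expand_grid(subject = 1:6, eye = c("OS", "OD"),
                             session = c("AM", "PM"))
    df$value <- 0.5 + subj_eff[df$subject] + rnorm(nrow(df), 0, 0.02)
    mixed_effects_compare(df)$session_estimate
  }, numeric(1))
  expect_lt(abs(median(ests)), 0.01)
})

test_that("duplicated eyes collapse to the per-subject means analysis", {
  set.seed(21)
  df1 <- tidyr::expand_grid(subject = 1:8, session = c("AM", "PM"))
  df1$value <- 0.4 + rnorm(8, 0, 0.05)[df1$subject] +
    ifelse(df1$session == "PM", 0.08, 0) + rnorm(nrow(df1), 0, 0.01)
  df2 <- dplyr::bind_rows(dplyr::mutate(df1, eye = "OS"),
                          dplyr::mutate(df1, eye = "OD"))
  m <- mixed_effects_compare(df2)
  per_subject <- df1 |>
    tidyr::pivot_wider(names_from = "session", values_from = "value") |>
    dplyr::mutate(d = .data$PM - .data$AM)
  expect_equal(m$session_estimate, mean(per_subject$d), tolerance = 1e-6)
})

test_that("two-way mixed models report group-wise session contrasts", {
  set.seed(22)
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:12),
                           session = c("AM", "PM"))
  df$group <- ifelse(df$subject %in% sprintf("s%d", 1:6), "young", "old")
  eff <- ifelse(df$group == "young" & df$session == "PM", 0.2,
                ifelse(df$session == "PM", 0.02, 0))
  df$value <- 0.5 + rnorm(12, 0, 0.04)[match(df$subject, unique(df$subject))] +
    eff + rnorm(nrow(df), 0, 0.02)
  m <- mixed_effects_compare(df)
  expect_true(m$two_way)
  expect_s3_class(m$pairwise, "tbl_df")
  expect_equal(nrow(m$pairwise), 2)
  expect_s3_class(tidy(m), "tbl_df")
})

test_that("singular fits fall back to the fixed-effects analogue with a note", {
  set.seed(23)
  df <- tidyr::expand_grid(subject = 1:6, eye = c("OS", "OD"),
                           session = c("AM", "PM"))
  df$value <- 0.5 + ifelse(df$session == "PM", 0.1, 0) +
    rnorm(nrow(df), 0, 0.01)   # no subject effect at all
  expect_message(m <- mixed_effects_compare(df), "ingular")
  expect_true(m$singular)
  expect_lt(abs(m$session_estimate - 0.1), 0.01)
})
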