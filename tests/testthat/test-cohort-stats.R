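feature_frame <- function(values, group = "A", arm = "GT", fov = "3mm") {
  tibble::tibble(subject_id = paste0("s", seq_along(values)), group = group,
                 arm = arm, fov = fov, bvd = values, bvc = values,
                 bvt = values, vpi = values)
}

test_that("summarize_features: hand arithmetic, flags and order invariance", {
  f <- feature_frame(c(1, 2, 3))
  s <- summarize_features(f)
  expect_equal(unique(s$mean), 2)
  expect_equal(unique(s$sd), 1)
  expect_equal(unique(s$n), 3L)

  single <- summarize_features(feature_frame(5))
  expect_true(all(is.na(single$sd)))
  expect_true(all(single$flagged))

  shuffled <- summarize_features(f[c(3, 1, 2), ])
  expect_identical(s, shuffled)

  with_nan <- summarize_features(feature_frame(c(1, 2, 3, NaN)))
  expect_equal(unique(with_nan$n_excluded), 1L)
  expect_equal(unique(with_nan$mean), 2)
})

test_that("identical arms give t = 0, p = 1 in both modes", {
  x <- c(1, 2, 3, 4, 5)
  paired <- ttest_tr_vs_gt(x, x, paired = TRUE)
  expect_equal(paired$t, 0)
  expect_equal(paired$p, 1)
  unpaired <- ttest_tr_vs_gt(x, x, paired = FALSE)
  expect_equal(unpaired$t, 0)
  expect_equal(unpaired$p, 1)
})

test_that("Welch test matches a hand-coded Welch-Satterthwaite oracle", {
  welch_oracle <- function(a, b) {
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
  }
  cases <- list(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                list(a = c(0.1, 0.5, 0.9, 1.4), b = c(2, 2.2)),
                list(a = rnorm(10), b = rnorm(12, 0.5, 2)))
  withr::with_seed(31, cases[[3]] <- list(a = rnorm(10), b = rnorm(12, 0.5, 2)))
  for (cs in cases) {
    got <- ttest_tr_vs_gt(cs$a, cs$b)
    want <- welch_oracle(cs$a, cs$b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("degenerate and undersized inputs follow the contract", {
  expect_error(ttest_tr_vs_gt(1, c(1, 2)), "at least 2")
  z <- ttest_tr_vs_gt(c(2, 2, 2), c(2, 2, 2))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  shifted <- ttest_tr_vs_gt(c(3, 3, 3), c(2, 2, 2))
  expect_equal(shifted$p, 0)
})

test_that("build_report: pairing, exclusions, both test flavours", {
  m <- make_cohort(list(A = list(n = 5)), master_seed = 8,
                   network = list(image_size = 64L, n_seeds = 2L),
                   degrade = list(noise_sd = 0.05))
  f <- quantify_cohort(m)
  rep0 <- build_report(m, f)
  expect_s3_class(rep0, "octa_report")
  expect_equal(nrow(rep0$exclusions), 0L)
  expect_setequal(unique(rep0$tests$method), c("welch", "paired"))
  expect_true(all(rep0$tests$p >= 0 & rep0$tests$p <= 1, na.rm = TRUE))
  expect_identical(rep0$tests$significant_at_0_05, rep0$tests$p < 0.05)

  # dropping one TR row yields exactly one logged exclusion
  m2 <- m[!(m$subject_id == m$subject_id[1] & m$arm == "TR"), ]
  f2 <- quantify_cohort(m2)
  rep2 <- build_report(m2, f2)
  expect_equal(nrow(rep2$exclusions), 1L)
  expect_equal(rep2$exclusions$reason, "missing TR arm")

  td <- tidy(rep0)
  expect_identical(td, rep0$tests)
  gl <- glance(rep0)
  expect_equal(gl$n_tests, 4L)
  expect_equal(gl$n_exclusions, 0L)
})

test_that("identity-degradation cohort gives p = 1 for every feature", {
  m <- make_cohort(list(A = list(n = 5)), master_seed = 12,
                   network = list(image_size = 64L, n_seeds = 2L),
                   degrade = list())
  f <- quantify_cohort(m)
  rep <- build_report(m, f)
  paired <- rep$tests[rep$tests$method == "paired", ]
  expect_true(all(paired$p == 1))
})

test_that("a biased-down caliber degradation is detected as thinner TR", {
  m <- make_cohort(list(A = list(n = 12)), master_seed = 4,
                   network = list(image_size = 96L, n_seeds = 3L,
                                  caliber_root_px = 2.5),
                   degrade = list(caliber_scale = 0.7))
  f <- quantify_cohort(m)
  bvc_gt <- f$bvc[f$arm == "GT"]
  bvc_tr <- f$bvc[f$arm == "TR"]
  expect_lt(mean(bvc_tr, na.rm = TRUE), mean(bvc_gt, na.rm = TRUE))
  tt <- ttest_tr_vs_gt(bvc_tr, bvc_gt, paired = TRUE)
  expect_lt(tt$p, 0.05)
})

test_that("autoplot methods return ggplot objects", {
  m <- make_cohort(list(A = list(n = 3), B = list(n = 2)), master_seed = 6,
                   network = list(image_size = 64L, n_seeds = 2L))
  f <- quantify_cohort(m)
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(build_report(m, f)), "ggplot")
  expect_s3_class(plot_map(matrix(0.5, 64, 64)), "ggplot")
})
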