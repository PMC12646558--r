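test_that("spearman_rho handles monotone, reversed, tied and constant input", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  # rank invariance under a monotone transform
  set.seed(1)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(x, y^3 + y)$rho)
  expect_warning(out <- spearman_rho(rep(2, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_rho(1:3, 1:4), class = "emgrehab_data_error")
})

test_that("spearman rho matches the average-rank oracle, bounded in [-1,1]", {
  set.seed(3)
  for (rep in 1:300) {
    n <- sample(3:6, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- suppressWarnings(spearman_rho(x, y))
    expect_equal(got$rho, naive_spearman(x, y)$rho, tolerance = 1e-12)
    expect_true(got$rho >= -1 && got$rho <= 1)
  }
  # exact permutation p for small untied samples
  set.seed(4)
  for (rep in 1:10) {
    x <- sample(1:7)[1:6]
    y <- sample(1:9)[1:6]
    got <- spearman_rho(x, y)
    want <- naive_spearman(x, y, exact_p = TRUE)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("mann_whitney matches enumeration and symmetry conventions", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)            # every y exceeds every x
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)  # 2 of the 6 pairings as extreme

  x <- c(1.2, 3.4, 2.2)
  y <- c(0.5, 4.1, 5.3)
  expect_equal(mann_whitney(x, y)$p, naive_mw_exact(x, y), tolerance = 1e-12)

  set.seed(6)
  z <- rnorm(6)
  rz <- mann_whitney(z, z)
  expect_equal(rz$U, length(z)^2 / 2)
  expect_gt(rz$p, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), class = "emgrehab_data_error")
})

test_that("normality check flags degenerate input and detects skew", {
  expect_warning(out <- normality_check(rep(1, 10)), "constant")
  expect_true(out$degenerate)
  expect_error(normality_check(1:2), class = "emgrehab_data_error")
  set.seed(8)
  rej <- mean(replicate(100, normality_check(rexp(500))$p < 0.05))
  expect_gt(rej, 0.9)  # power against exponential data at n = 500
  ps <- replicate(200, normality_check(rnorm(500))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)  # null p-values uniform
})

test_that("patient feature summaries aggregate as documented", {
  tab <- data.frame(patient_id = "P1", group = "experimental", week = 0,
                    movement = "flexion", repetition = 1, window_idx = 1,
                    rms_ch1 = 4)
  class(tab) <- c("feature_table", "data.frame")
  s <- summarize_patient_features(tab, 0, features = "rms")
  expect_equal(s$rms, 4)  # single cell identity

  tab2 <- data.frame(patient_id = rep(c("P1", "P2"), each = 2),
                     group = "experimental", week = 0, movement = "flexion",
                     repetition = 1, window_idx = rep(1:2, 2),
                     rms_ch1 = c(1, 3, 5, 9), rms_ch2 = c(2, 4, 6, 10))
  class(tab2) <- c("feature_table", "data.frame")
  s2 <- summarize_patient_features(tab2, 0, features = "rms")
  expect_equal(s2$rms, c(mean(c(1, 3, 2, 4)), mean(c(5, 9, 6, 10))))

  dup <- rbind(tab2, tab2)
  class(dup) <- class(tab2)
  expect_equal(summarize_patient_features(dup, 0, features = "rms")$rms,
               s2$rms)  # mean invariant under duplication

  pc <- summarize_patient_features(tab2, 0, features = "rms",
                                   per_channel = TRUE)
  expect_equal(pc$rms_ch2, c(3, 8))
  expect_error(summarize_patient_features(tab2, 4),
               class = "emgrehab_data_error")
})

test_that("correlation table is null-calibrated and labels strengths", {
  # direct null: feature summaries independent of clinical scores
  set.seed(12)
  hits <- replicate(400, {
    spearman_rho(rnorm(20), rnorm(20))$p < 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)

  expect_equal(strength_labels <- emgrehab:::strength_label(
    c(0.1, -0.45, 0.85, NA), c(0.3, 0.6)),
    c("weak", "moderate", "strong", NA))
})

test_that("difference-in-differences and MCID logic match the trial rules", {
  m <- read.csv(trial_summary_path("clinical_means.csv"))
  did <- sapply(split(m, m$instrument), function(d) {
    diff_in_diff(d$experimental_mean[d$timepoint == "pre"],
                 d$experimental_mean[d$timepoint == "post"],
                 d$control_mean[d$timepoint == "pre"],
                 d$control_mean[d$timepoint == "post"])
  })
  expect_equal(did[["fma_ue"]], 9.46, tolerance = 1e-9)
  expect_equal(did[["arat"]], 8.96, tolerance = 1e-9)
  expect_equal(did[["bbt"]], 20.46, tolerance = 1e-9)
  thr <- mcid_thresholds()
  expect_true(all(did > unlist(thr)[names(did)]))

  # linearity: shifting every score leaves the contrast unchanged
  expect_equal(diff_in_diff(10, 25, 12, 15), diff_in_diff(110, 125, 112, 115))
  # strict boundary: equal to the threshold does not count as exceeding
  clin <- data.frame(patient_id = rep(1:8, 2),
                     group = rep(rep(c("experimental", "control"), each = 4), 2),
                     week = rep(c(0, 9), each = 8),
                     fma_ue = c(rep(30, 8), rep(c(39, 30), each = 4)),
                     arat = 20, bbt = 10)
  out <- outcome_summary(clin)
  fm <- out[out$instrument == "fma_ue", ]
  expect_equal(fm$diff_in_diff, 9)
  expect_false(fm$exceeds_mcid)  # 9 > 9 is false
  expect_equal(fm$margin, 0)
  expect_equal(out$diff_in_diff[out$instrument == "arat"], 0)
  expect_false(out$exceeds_mcid[out$instrument == "arat"])
})
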