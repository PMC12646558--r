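# Classification tests run on a shortened acquisition protocol (1 s rest,
# 2 s contraction) to keep simulation time modest; the windowing and
# feature machinery is identical to the full-length protocol.

test_that("fully separable noiseless patient is classified almost perfectly", {
  # full-length protocol: the separability bound is a property of the
  # study conditions, and KNN needs the full window count to saturate
  proto <- acquisition_protocol()
  p <- make_profile(lambda = 1, jitter0 = 0, clean = TRUE, protocol = proto)
  ft <- patient_week_features(p, 0, proto)
  for (kind in c("knn", "random_forest", "svm")) {
    r <- crossval_accuracy(ft, classifier_spec(kind), cv_spec(folds = 3))
    expect_gte(r$accuracy, 0.99)
  }
})

test_that("permuted labels fall to chance; confusion matrix is consistent", {
  p <- make_profile(lambda = 0.8, clean = FALSE, seed = 2)
  ft <- patient_week_features(p, 0, fast_protocol())
  set.seed(9)
  ft$movement <- sample(ft$movement)
  # repetition grouping no longer applies after permutation; window folds
  r <- crossval_accuracy(ft, classifier_spec("knn"),
                         cv_spec(folds = 3, grouping = "window"))
  n <- sum(r$confusion)
  expect_equal(n, nrow(ft))
  band <- qbinom(c(0.005, 0.995), n, 1 / 7) / n
  expect_gte(r$accuracy, band[1])
  expect_lte(r$accuracy, band[2])
  expect_true(all(r$confusion >= 0))
  expect_equal(sum(diag(r$confusion)) / n, mean(r$fold_accuracies),
               tolerance = 0.05)
  expect_true(all(r$fold_accuracies >= 0 & r$fold_accuracies <= 1))
})

test_that("reports are deterministic and duplication-invariant under k=1", {
  p <- make_profile(lambda = 0.7, clean = FALSE, seed = 3)
  ft <- patient_week_features(p, 0, fast_protocol())
  clf <- classifier_spec("knn", knn_k = 1)
  r1 <- crossval_accuracy(ft, clf, cv_spec(folds = 3))
  r2 <- crossval_accuracy(ft, clf, cv_spec(folds = 3))
  expect_identical(r1, r2)
  dup <- rbind(ft, ft)
  class(dup) <- class(ft)
  r3 <- crossval_accuracy(dup, clf, cv_spec(folds = 3))
  expect_equal(r3$accuracy, r1$accuracy)
})

test_that("degenerate fold configurations are refused with clear errors", {
  p <- make_profile(lambda = 0.7, clean = FALSE)
  ft <- patient_week_features(p, 0, fast_protocol())
  expect_error(crossval_accuracy(ft, classifier_spec("knn"),
                                 cv_spec(folds = 5)),
               class = "emgrehab_config_error")  # only 3 repetitions
  sub <- ft[ft$movement != "pinch", ]
  class(sub) <- class(ft)
  expect_error(crossval_accuracy(sub, classifier_spec("knn"),
                                 cv_spec(folds = 3),
                                 classes = fast_protocol()$movements),
               class = "emgrehab_data_error")
})

test_that("accuracy rises with latent separability and beats chance from 0.4", {
  lams <- c(0.1, 0.4, 0.7, 1.0)
  accs <- sapply(1:3, function(s) {
    sapply(lams, function(l) {
      p <- make_profile(lambda = l, clean = FALSE, seed = s)
      ft <- patient_week_features(p, 0, fast_protocol())
      crossval_accuracy(ft, classifier_spec("knn"), cv_spec(folds = 3))$accuracy
    })
  })
  m <- rowMeans(accs)
  # non-decreasing allowing one inversion within Monte-Carlo noise
  expect_true(all(diff(m) > -0.02))
  expect_gt(m[4], m[1])
  # learning signal: clearly above the chance band whenever lambda >= 0.4
  n <- 231 * 7  # windows per patient-week on the short protocol
  chance_hi <- qbinom(0.995, n, 1 / 7) / n
  expect_true(all(accs[2:4, ] > chance_hi))
})

test_that("progression table reproduces published group-mean arithmetic", {
  acc <- read.csv(trial_summary_path("classifier_accuracies.csv"))
  acc$patient_id <- acc$group  # one group-level unit per arm
  prog <- progression_table(acc)
  knn <- prog[prog$classifier == "knn", ]
  cell <- function(w0, w1) knn$mean_diff[knn$from_week == w0 &
                                           knn$to_week == w1]
  expect_equal(cell(0, 4), 15.93, tolerance = 0.011)   # mean(17.07, 14.80)
  expect_equal(cell(0, 9), 42.14, tolerance = 0.011)   # mean(44.70, 39.59)
  # telescoping: consecutive differences sum to follow-up minus baseline
  expect_equal(cell(0, 4) + cell(4, 6) + cell(6, 9), cell(0, 9),
               tolerance = 1e-12)
})

test_that("progression statistics behave under symmetric trajectories", {
  set.seed(5)
  base <- data.frame(patient_id = rep(sprintf("P%02d", 1:12), each = 2),
                     group = rep(c("experimental", "control"), each = 12),
                     week = rep(c(0, 9), 12), classifier = "knn")
  base$accuracy <- 0.4 + 0.04 * (base$week == 9) + rnorm(24, 0, 0.01)
  prog <- progression_table(base)
  expect_gt(prog$p_between, 0.05)  # identical generative trajectories
  expect_equal(nrow(prog), 1)
  missing <- base[!(base$patient_id == "P03" & base$week == 9), ]
  expect_error(progression_table(missing), class = "emgrehab_data_error")
})

test_that("classifier mean summary matches published values and edge cases", {
  acc <- read.csv(trial_summary_path("classifier_accuracies.csv"))
  acc$patient_id <- acc$group
  s <- classifier_mean_summary(acc)
  g <- function(gr, w) s[s$group == gr & s$week == w, ]
  expect_equal(g("experimental", 9)$mean_acc, 83.59, tolerance = 0.011)
  expect_equal(g("experimental", 9)$sd_acc, 1.1, tolerance = 0.05)
  expect_equal(g("control", 0)$mean_acc, 37.49, tolerance = 0.011)

  eq <- data.frame(patient_id = "x", group = "experimental", week = 0,
                   classifier = c("knn", "random_forest", "svm"),
                   accuracy = 0.5)
  se <- classifier_mean_summary(eq)
  expect_equal(se$mean_acc, 0.5)
  expect_equal(se$sd_acc, 0)

  expect_error(classifier_mean_summary(eq[1:2, ],
                                       classifiers = c("knn", "svm",
                                                       "random_forest")),
               class = "emgrehab_data_error")
})
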