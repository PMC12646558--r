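#' Movement classifier specification
#'
#' The three classifiers mirror standard myoelectric practice: k-nearest
#' neighbours (Euclidean), random forest, and a radial-basis SVM.
#' Hyperparameters are fixed defaults with no tuning (tuning would change
#' the measurand being tracked over weeks).
#'
#' @param kind `"knn"`, `"random_forest"` or `"svm"`.
#' @param knn_k Neighbours for KNN.
#' @param rf_trees Trees for the random forest.
#' @param svm_cost Regularisation constant for the SVM.
#' @param svm_kernel SVM kernel (default radial basis).
#' @param standardize Standardise features using training-fold statistics.
#' @param seed Seed recorded in every report and used per fold.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "random_forest", "svm"),
                            knn_k = 5, rf_trees = 100, svm_cost = 1,
                            svm_kernel = "radial", standardize = TRUE,
                            seed = 1) {
  if (knn_k <= 0 || rf_trees <= 0 || svm_cost <= 0)
    stop_config("classifier hyperparameters must be positive")
  structure(list(kind = match.arg(kind), knn_k = knn_k, rf_trees = rf_trees,
                 svm_cost = svm_cost, svm_kernel = svm_kernel,
                 standardize = standardize, seed = seed),
            class = "classifier_spec")
}

#' Cross-validation specification
#'
#' Folds are stratified by movement. The default grouping unit is the
#' repetition: overlapping windows cut from one contraction share signal,
#' so splitting them across train and test would leak. A window-level mode
#' is available for sensitivity analysis.
#'
#' @param folds Number of folds (>= 2).
#' @param grouping `"repetition"` (leakage-safe default) or `"window"`.
#' @param seed Seed for fold assignment.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(folds = 5, grouping = c("repetition", "window"),
                    seed = 1) {
  if (folds < 2) stop_config("folds must be >= 2")
  structure(list(folds = folds, grouping = match.arg(grouping), seed = seed),
            class = "cv_spec")
}

fit_predict <- function(train_x, train_y, test_x, clf) {
  switch(clf$kind,
    knn = as.character(class::knn(train_x, test_x, train_y, k = clf$knn_k)),
    random_forest = {
      fit <- randomForest::randomForest(x = train_x, y = factor(train_y),
                                        ntree = clf$rf_trees)
      as.character(predict(fit, test_x))
    },
    svm = {
      fit <- e1071::svm(x = train_x, y = factor(train_y),
                        kernel = clf$svm_kernel, cost = clf$svm_cost,
                        scale = FALSE)
      as.character(predict(fit, test_x))
    })
}

#' Cross-validated movement classification for one patient-week
#'
#' Builds movement-stratified folds (grouped by repetition by default),
#' fits the classifier per fold with standardisation statistics estimated
#' on the training fold only, and reports the mean fold accuracy plus the
#' pooled confusion matrix.
#'
#' @param table A `feature_table` restricted to one patient-week.
#' @param clf A [classifier_spec()].
#' @param cv A [cv_spec()].
#' @param classes Expected movement classes (default: those present).
#' @return An object of class `classifier_report`: patient_id, week, kind,
#'   `accuracy` (mean over folds), `fold_accuracies`, and `confusion`
#'   (true x predicted, summed over folds).
#' @export
crossval_accuracy <- function(table, clf, cv = cv_spec(),
                              classes = sort(unique(table$movement))) {
  if (length(unique(table$patient_id)) != 1 ||
      length(unique(table$week)) != 1)
    stop_data("feature table must cover exactly one patient-week")
  missing_cls <- setdiff(classes, unique(table$movement))
  if (length(missing_cls))
    stop_data("movement class(es) absent from table: ",
              paste(missing_cls, collapse = ", "))
  fcols <- feature_columns(table)
  y <- as.character(table$movement)

  set.seed(cv$seed)
  if (cv$grouping == "repetition") {
    fold_of <- integer(nrow(table))
    for (m in classes) {
      reps <- unique(table$repetition[table$movement == m])
      if (length(reps) < cv$folds)
        stop_config("patient ", table$patient_id[1], ": only ", length(reps),
                    " repetitions of '", m, "' for ", cv$folds, " folds")
      shuffled <- sample(reps)
      assign <- rep_len(seq_len(cv$folds), length(shuffled))
      for (i in seq_along(shuffled))
        fold_of[table$movement == m &
                  table$repetition == shuffled[i]] <- assign[i]
    }
  } else {
    fold_of <- integer(nrow(table))
    for (m in classes) {
      idx <- which(table$movement == m)
      fold_of[idx] <- sample(rep_len(seq_len(cv$folds), length(idx)))
    }
  }

  X <- as.matrix(table[, fcols, drop = FALSE])
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(cv$folds)
  for (f in seq_len(cv$folds)) {
    tr <- fold_of != f
    te <- !tr
    if (length(setdiff(classes, unique(y[tr]))))
      stop_data("fold ", f, " training set is missing a class")
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (clf$standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    }
    set.seed(clf$seed + f)
    pred <- fit_predict(Xtr, y[tr], Xte, clf)
    fold_acc[f] <- mean(pred == y[te])
    confusion <- confusion + base::table(factor(y[te], classes),
                                         factor(pred, classes))
  }
  structure(list(patient_id = table$patient_id[1], week = table$week[1],
                 group = table$group[1], kind = clf$kind,
                 accuracy = mean(fold_acc), fold_accuracies = fold_acc,
                 confusion = confusion, seed = clf$seed, cv_seed = cv$seed),
            class = "classifier_report")
}

#' Flatten classifier reports to a data.frame
#' @param reports List of `classifier_report` objects.
#' @return data.frame: patient_id, group, week, classifier, accuracy.
#' @export
reports_df <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(patient_id = r$patient_id, group = r$group, week = r$week,
               classifier = r$kind, accuracy = r$accuracy)))
}

week_pairs <- function(weeks) {
  weeks <- sort(unique(weeks))
  p <- cbind(weeks[-length(weeks)], weeks[-1])
  if (length(weeks) > 2)  # consecutive pairs + follow-up vs baseline
    p <- rbind(p, c(weeks[1], weeks[length(weeks)]))
  p
}

#' Longitudinal progression of classification accuracy
#'
#' For every classifier and week pair (each consecutive pair plus
#' follow-up minus baseline): computes the per-patient accuracy difference,
#' averages within each group, then averages the two group means (with
#' equal group sizes this equals the pooled mean). Attaches the per-group
#' paired two-tailed t p-value, a one-way between-group ANOVA p on the
#' per-patient difference scores, and a Shapiro-Wilk p on the pooled
#' differences. Accuracies keep whatever scale they come in (proportions
#' or percentage points).
#'
#' @param acc A data.frame as from [reports_df()]; any unit with one row
#'   per (patient_id, week, classifier) works, including group-level means.
#' @param weeks Weeks to include (default: all present).
#' @param groups The two group labels.
#' @return data.frame of class `progression_table`: classifier, from_week,
#'   to_week, mean_diff, sd_diff, p_paired_experimental, p_paired_control,
#'   p_between, shapiro_p.
#' @export
progression_table <- function(acc, weeks = sort(unique(acc$week)),
                              groups = c("experimental", "control")) {
  acc <- acc[acc$week %in% weeks, , drop = FALSE]
  cover <- tapply(acc$week, acc$patient_id,
                  function(w) all(weeks %in% w))
  if (!all(cover))
    stop_data("patients missing assessment weeks: ",
              paste(names(cover)[!cover], collapse = ", "))
  pairs <- week_pairs(weeks)
  out <- list()
  for (k in unique(acc$classifier)) {
    a <- acc[acc$classifier == k, ]
    wide <- split(a, a$patient_id)
    for (i in seq_len(nrow(pairs))) {
      w0 <- pairs[i, 1]; w1 <- pairs[i, 2]
      d <- vapply(wide, function(p)
        p$accuracy[p$week == w1] - p$accuracy[p$week == w0], numeric(1))
      grp <- vapply(wide, function(p) p$group[1], character(1))
      gm <- tapply(d, grp, mean)
      pp <- setNames(rep(NA_real_, 2), groups)
      for (g in groups) {
        dg <- d[grp == g]
        if (length(dg) >= 2 && sd(dg) > 0)
          pp[g] <- t.test(dg)$p.value  # paired t on per-patient differences
      }
      p_bet <- if (length(unique(grp)) == 2 && min(table(grp)) >= 2 &&
                   sd(d) > 0)
        summary(aov(d ~ factor(grp)))[[1]][["Pr(>F)"]][1] else NA_real_
      sh <- if (length(d) >= 3 && sd(d) > 0) shapiro.test(d)$p.value
            else NA_real_
      out[[length(out) + 1]] <- data.frame(
        classifier = k, from_week = w0, to_week = w1,
        mean_diff = mean(gm[intersect(groups, names(gm))]),
        sd_diff = if (length(d) >= 2) sd(d) else NA_real_,
        p_paired_experimental = pp[[1]], p_paired_control = pp[[2]],
        p_between = p_bet, shapiro_p = sh)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("progression_table", "data.frame")
  res
}

#' Mean and SD across classifiers of group-level accuracies
#'
#' Averages accuracy over patients within (group, week, classifier), then
#' reports the arithmetic mean and SD across the classifiers for each
#' (group, week).
#'
#' @param acc data.frame as from [reports_df()].
#' @param classifiers Required classifier kinds (error if one is missing).
#' @return data.frame: group, week, mean_acc, sd_acc, n_classifiers.
#' @export
classifier_mean_summary <- function(acc,
                                    classifiers = unique(acc$classifier)) {
  out <- list()
  for (g in unique(acc$group)) for (w in sort(unique(acc$week))) {
    cell <- acc[acc$group == g & acc$week == w, ]
    miss <- setdiff(classifiers, unique(cell$classifier))
    if (length(miss))
      stop_data("missing classifier(s) for ", g, " week ", w, ": ",
                paste(miss, collapse = ", "))
    by_clf <- tapply(cell$accuracy, cell$classifier, mean)[classifiers]
    out[[length(out) + 1]] <- data.frame(
      group = g, week = w, mean_acc = mean(by_clf), sd_acc = sd(by_clf),
      n_classifiers = length(by_clf))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
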