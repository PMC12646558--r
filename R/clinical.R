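#' Minimal clinically important differences
#'
#' Default thresholds for the three instruments in subacute stroke:
#' 9 points (FMA-UE), 6 points (ARAT), 6 blocks (BBT).
#'
#' @param fma_ue,arat,bbt Positive thresholds.
#' @return Named list of class `mcid_thresholds`.
#' @export
mcid_thresholds <- function(fma_ue = 9, arat = 6, bbt = 6) {
  if (fma_ue <= 0 || arat <= 0 || bbt <= 0)
    stop_config("MCID thresholds must be positive")
  structure(list(fma_ue = fma_ue, arat = arat, bbt = bbt),
            class = "mcid_thresholds")
}

#' Statistical analysis configuration
#'
#' @param alpha Significance level.
#' @param cutoffs Correlation-strength cutoffs on `|rho|`:
#'   weak < cutoffs\[1\] <= moderate < cutoffs\[2\] <= strong.
#' @param p_adjust `"none"` (raw p-values, replication mode) or `"BH"`.
#' @return Object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, cutoffs = c(0.3, 0.6),
                         p_adjust = c("none", "BH")) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (length(cutoffs) != 2 || any(diff(cutoffs) <= 0) ||
      any(cutoffs <= 0) || any(cutoffs >= 1))
    stop_config("cutoffs must be two increasing values in (0, 1)")
  structure(list(alpha = alpha, cutoffs = cutoffs,
                 p_adjust = match.arg(p_adjust)),
            class = "stats_config")
}

strength_label <- function(rho, cutoffs) {
  ifelse(is.na(rho), NA_character_,
         ifelse(abs(rho) < cutoffs[1], "weak",
                ifelse(abs(rho) < cutoffs[2], "moderate", "strong")))
}

#' Spearman rank correlation with tie handling
#'
#' Average-rank tie handling; exact permutation p for n <= 8 without ties,
#' two-sided t approximation otherwise.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List with `rho` and `p`; `rho` is NA with a warning when either
#'   vector is constant.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop_data("need equal-length vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n <= 8 && !ties))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact distribution for small samples (m + n <= 12, no ties), normal
#' approximation with tie and continuity correction otherwise. `U` is the
#' number of (x, y) pairs with x > y (plus half the ties).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_data("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = (length(x) + length(y) <= 12) && !ties,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with `W`, `p`, and `degenerate` (TRUE for a constant
#'   sample, where the statistic is undefined).
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop_data("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) {
    warning("constant sample: Shapiro-Wilk undefined", call. = FALSE)
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value, degenerate = FALSE)
}

#' Per-patient scalar summaries of EMG features
#'
#' Collapses a feature table at one week to one scalar per patient per
#' feature: by default the mean over windows, repetitions and movements,
#' then the mean over channels (the grand mean over all cells). A median
#' aggregation and a per-channel mode are available.
#'
#' @param tab A `feature_table`.
#' @param week Assessment week to summarise.
#' @param features Base feature names (default: all 16).
#' @param agg `"mean"` or `"median"` over windows.
#' @param per_channel Keep channels separate (columns `<feature>_ch<i>`).
#' @return data.frame: patient_id, group, then one column per feature.
#' @export
summarize_patient_features <- function(tab, week, features = feature_names(),
                                       agg = c("mean", "median"),
                                       per_channel = FALSE) {
  agg <- match.arg(agg)
  aggf <- if (agg == "mean") mean else median
  tw <- tab[tab$week == week, , drop = FALSE]
  if (!nrow(tw)) stop_data("no feature rows at week ", week)
  fcols <- feature_columns(tab)
  out <- lapply(split(tw, tw$patient_id), function(p) {
    per_col <- vapply(p[fcols], aggf, numeric(1))
    row <- data.frame(patient_id = p$patient_id[1], group = p$group[1])
    for (f in features) {
      cols <- grep(paste0("^", f, "_ch"), fcols, value = TRUE)
      if (per_channel) row[cols] <- per_col[cols]
      else row[[f]] <- mean(per_col[cols])
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' EMG-clinical Spearman correlation tables
#'
#' For each group, week, clinical instrument and EMG feature: the Spearman
#' rho between per-patient feature summaries and clinical scores, its
#' p-value, a strength label on `|rho|`, and a significance flag. Cells
#' with fewer than `min_n` patients are marked unavailable (NA).
#'
#' @param tab A `feature_table` covering the weeks.
#' @param clinical Clinical score table
#'   (patient_id, group, week, fma_ue, arat, bbt).
#' @param weeks Weeks to analyse.
#' @param features Base feature names to correlate.
#' @param instruments Clinical instrument columns.
#' @param cfg A [stats_config()].
#' @param min_n Minimum patients per group-week cell.
#' @return data.frame: group, week, instrument, feature, n, rho, p,
#'   strength, significant.
#' @export
correlation_table <- function(tab, clinical, weeks = c(0, 6, 9),
                              features = c("rms", "mav", "iemg", "ssc",
                                           "zc", "aac"),
                              instruments = c("fma_ue", "arat", "bbt"),
                              cfg = stats_config(), min_n = 4) {
  out <- list()
  for (w in weeks) {
    summ <- summarize_patient_features(tab, w, features)
    cl <- clinical[clinical$week == w, ]
    merged <- merge(summ, cl[, c("patient_id", instruments)],
                    by = "patient_id")
    for (g in unique(merged$group)) {
      mg <- merged[merged$group == g, ]
      for (ins in instruments) for (f in features) {
        if (nrow(mg) < min_n || sd(mg[[f]]) == 0 || sd(mg[[ins]]) == 0) {
          rho <- p <- NA_real_
        } else {
          sr <- spearman_rho(mg[[f]], mg[[ins]])
          rho <- sr$rho; p <- sr$p
        }
        out[[length(out) + 1]] <- data.frame(
          group = g, week = w, instrument = ins, feature = f, n = nrow(mg),
          rho = rho, p = p)
      }
    }
  }
  res <- do.call(rbind, out)
  if (cfg$p_adjust != "none") res$p <- stats::p.adjust(res$p, cfg$p_adjust)
  res$strength <- strength_label(res$rho, cfg$cutoffs)
  res$significant <- !is.na(res$p) & res$p < cfg$alpha
  rownames(res) <- NULL
  res
}

#' Between-group difference in change scores
#'
#' `(exp_post - exp_pre) - (ctrl_post - ctrl_pre)`, the construction that
#' is compared against an MCID in a two-arm trial.
#'
#' @param exp_pre,exp_post,ctrl_pre,ctrl_post Group means.
#' @return The difference-in-differences.
#' @export
diff_in_diff <- function(exp_pre, exp_post, ctrl_pre, ctrl_post) {
  (exp_post - exp_pre) - (ctrl_post - ctrl_pre)
}

#' Clinical outcome summary with MCID comparison
#'
#' Per instrument: group means and SDs at the pre and post timepoints, the
#' between-group Mann-Whitney p at each timepoint, the
#' difference-in-differences of the group means, and the MCID flag
#' (strictly greater than the threshold) with its margin.
#'
#' @param clinical Clinical score table.
#' @param thresholds An [mcid_thresholds()].
#' @param cfg A [stats_config()].
#' @param pre_week,post_week Timepoints (default first/last week present).
#' @return data.frame: instrument, exp_pre/exp_post/ctrl_pre/ctrl_post
#'   means and SDs, p_pre, p_post, diff_in_diff, mcid, exceeds_mcid,
#'   margin.
#' @export
outcome_summary <- function(clinical, thresholds = mcid_thresholds(),
                            cfg = stats_config(),
                            pre_week = min(clinical$week),
                            post_week = max(clinical$week)) {
  for (w in c(pre_week, post_week)) for (g in c("experimental", "control"))
    if (!any(clinical$week == w & clinical$group == g))
      stop_data("no ", g, " records at week ", w)
  out <- list()
  for (ins in names(thresholds)) {
    grab <- function(g, w) clinical[[ins]][clinical$group == g &
                                             clinical$week == w]
    ep <- grab("experimental", pre_week); eq <- grab("experimental", post_week)
    cp <- grab("control", pre_week); cq <- grab("control", post_week)
    did <- diff_in_diff(mean(ep), mean(eq), mean(cp), mean(cq))
    out[[length(out) + 1]] <- data.frame(
      instrument = ins,
      exp_pre = mean(ep), exp_pre_sd = sd(ep),
      exp_post = mean(eq), exp_post_sd = sd(eq),
      ctrl_pre = mean(cp), ctrl_pre_sd = sd(cp),
      ctrl_post = mean(cq), ctrl_post_sd = sd(cq),
      p_pre = mann_whitney(ep, cp)$p, p_post = mann_whitney(eq, cq)$p,
      diff_in_diff = did, mcid = thresholds[[ins]],
      exceeds_mcid = did > thresholds[[ins]],
      margin = did - thresholds[[ins]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
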