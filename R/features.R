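#' Feature bank specification
#'
#' Controls the conventions behind the 16-feature bank (14 time-domain +
#' 2 frequency-domain). The feature *names* are standard in myoelectric
#' control; their exact definitions vary across labs, so every convention
#' is pinned here: zero-crossing / slope-sign-change deadbands (default 0),
#' the cardinality merge tolerance (as a fraction of the window SD),
#' the IQR quantile type, the kurtosis convention (Fisher excess by
#' default), and the PSD estimator behind MNF/MDF (Welch by default,
#' periodogram available for oracle checks).
#'
#' @param zc_threshold Amplitude deadband for zero crossings (>= 0).
#' @param ssc_threshold Slope-product deadband for slope sign changes.
#' @param cardinality_tol Merge tolerance for CARD, as a fraction of the
#'   window's sample SD.
#' @param iqr_type Quantile algorithm type passed to [stats::quantile()].
#' @param kurtosis `"fisher"` (excess; normal -> 0) or `"pearson"`.
#' @param psd_method `"welch"` or `"periodogram"`.
#' @param psd_segment Welch segment length (samples).
#' @param psd_overlap Welch fractional segment overlap.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(zc_threshold = 0, ssc_threshold = 0,
                         cardinality_tol = 1e-4, iqr_type = 7,
                         kurtosis = c("fisher", "pearson"),
                         psd_method = c("welch", "periodogram"),
                         psd_segment = 256, psd_overlap = 0.5) {
  if (zc_threshold < 0 || ssc_threshold < 0 || cardinality_tol < 0)
    stop_config("feature thresholds must be >= 0")
  structure(list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold,
                 cardinality_tol = cardinality_tol, iqr_type = iqr_type,
                 kurtosis = match.arg(kurtosis),
                 psd_method = match.arg(psd_method),
                 psd_segment = psd_segment, psd_overlap = psd_overlap),
            class = "feature_spec")
}

#' Canonical feature order
#' @return Character vector of the 16 feature names in column order.
#' @export
feature_names <- function() {
  c("rms", "mav", "iemg", "ssc", "zc", "ptp", "var", "sd", "wl", "card",
    "iqr", "kurt", "aeng", "aac", "mnf", "mdf")
}

# Vectorised 14 time-domain features over the columns of an N x W matrix.
# Definitions (N = window length, x the window):
#   RMS  = sqrt(sum(x^2)/N)          MAV = sum(|x|)/N       IEMG = sum(|x|)
#   SSC  = #{1<i<N : (x_i-x_{i-1})(x_i-x_{i+1}) > thr}
#   ZC   = #{i : sign(x_i) != sign(x_{i+1}) and |x_i-x_{i+1}| >= thr}
#   PTP  = max-min                   VAR = sum((x-xbar)^2)/(N-1)   SD = sqrt(VAR)
#   WL   = sum|x_{i+1}-x_i|          CARD = tolerance-merged distinct count
#   IQR  = Q3-Q1                     KURT per convention
#   AENG = sum(x^2)/N                AAC = WL/(N-1)
# VAR/SD are sample statistics (N-1); AENG/RMS use N.
td_features_mat <- function(X, spec = feature_spec()) {
  N <- nrow(X)
  if (N < 4) stop_data("window length must be >= 4, got ", N)
  if (!all(is.finite(X))) stop_data("non-finite values in window")
  absX <- abs(X)
  rms <- sqrt(colMeans(X^2))
  mav <- colMeans(absX)
  iemg <- colSums(absX)
  mid <- X[2:(N - 1), , drop = FALSE]
  ssc <- colSums((mid - X[1:(N - 2), , drop = FALSE]) *
                   (mid - X[3:N, , drop = FALSE]) > spec$ssc_threshold)
  s <- sign(X)
  dX <- X[2:N, , drop = FALSE] - X[1:(N - 1), , drop = FALSE]
  zc <- colSums((s[1:(N - 1), , drop = FALSE] != s[2:N, , drop = FALSE]) &
                  (abs(dX) >= spec$zc_threshold))
  ptp <- apply(X, 2, max) - apply(X, 2, min)
  m <- colMeans(X)
  Xc <- X - rep(m, each = N)
  v <- colSums(Xc^2) / (N - 1)
  wl <- colSums(abs(dX))
  sdv <- sqrt(v)
  tol <- spec$cardinality_tol * sdv
  card <- vapply(seq_len(ncol(X)), function(j) {
    1 + sum(diff(sort(X[, j])) > tol[j])
  }, numeric(1))
  iqr <- apply(X, 2, function(x)
    diff(quantile(x, c(0.25, 0.75), type = spec$iqr_type, names = FALSE)))
  m2 <- colMeans(Xc^2)
  m4 <- colMeans(Xc^4)
  kurt <- ifelse(m2 > 0, m4 / m2^2, NA)
  if (anyNA(kurt)) {
    warning("constant window(s): kurtosis defined as 0", call. = FALSE)
    kurt[is.na(kurt)] <- if (spec$kurtosis == "fisher") 3 else 0
  }
  if (spec$kurtosis == "fisher") kurt <- kurt - 3
  cbind(rms = rms, mav = mav, iemg = iemg, ssc = ssc, zc = zc, ptp = ptp,
        var = v, sd = sdv, wl = wl, card = card, iqr = iqr, kurt = kurt,
        aeng = colMeans(X^2), aac = wl / (N - 1))
}

# One-sided power spectrum of the columns of X. Returns list(freq, power)
# with power a (bins x W) matrix. Welch: Hamming-windowed segments of
# length min(psd_segment, N) advancing by (1 - psd_overlap) of a segment,
# averaged. Periodogram: single rectangular full-length FFT.
psd_mat <- function(X, fs, spec = feature_spec()) {
  N <- nrow(X)
  if (spec$psd_method == "periodogram") {
    L <- N
    starts <- 1L
    w <- rep(1, L)
  } else {
    L <- min(spec$psd_segment, N)
    step <- max(1L, floor(L * (1 - spec$psd_overlap)))
    starts <- seq.int(1L, N - L + 1L, by = step)
    w <- 0.54 - 0.46 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  }
  nb <- floor(L / 2) + 1L
  P <- matrix(0, nb, ncol(X))
  for (s in starts) {
    Y <- mvfft(X[s:(s + L - 1L), , drop = FALSE] * w)
    P <- P + Mod(Y[1:nb, , drop = FALSE])^2
  }
  P <- P / length(starts)
  # fold the negative frequencies in (skip DC, and Nyquist when L is even)
  last <- if (L %% 2 == 0) nb - 1L else nb
  if (last >= 2) P[2:last, ] <- 2 * P[2:last, , drop = FALSE]
  list(freq = (seq_len(nb) - 1) * fs / L, power = P)
}

# MNF = sum(f P)/sum(P); MDF = frequency where cumulative power reaches
# half the total, linearly interpolated between bins.
fd_features_mat <- function(X, fs, spec = feature_spec()) {
  ps <- psd_mat(X, fs, spec)
  f <- ps$freq
  tot <- colSums(ps$power)
  zero <- tot <= 0
  if (any(zero))
    warning("all-zero window(s): MNF/MDF defined as 0", call. = FALSE)
  mnf <- ifelse(zero, 0, colSums(f * ps$power) / tot)
  mdf <- vapply(seq_len(ncol(X)), function(j) {
    if (zero[j]) return(0)
    cum <- cumsum(ps$power[, j])
    half <- tot[j] / 2
    k <- which(cum >= half)[1]
    c0 <- if (k > 1) cum[k - 1] else 0
    f0 <- if (k > 1) f[k - 1] else 0
    f0 + (f[k] - f0) * (half - c0) / (cum[k] - c0)
  }, numeric(1))
  cbind(mnf = mnf, mdf = mdf)
}

#' Time-domain features of one window channel
#'
#' Computes the 14 time-domain features of the bank for a single sample
#' vector. See [feature_spec()] for conventions; algebraic identities
#' `IEMG = N * MAV`, `AENG = RMS^2`, `VAR = SD^2` and `WL = (N-1) * AAC`
#' hold exactly.
#'
#' @param x Numeric sample vector, length >= 4, finite.
#' @param spec A [feature_spec()].
#' @return Named numeric vector of 14 features.
#' @export
td_features <- function(x, spec = feature_spec()) {
  td_features_mat(matrix(x, ncol = 1), spec)[1, ]
}

#' Frequency-domain features of one window channel
#'
#' @param x Numeric sample vector.
#' @param fs Sampling frequency (Hz).
#' @param spec A [feature_spec()].
#' @return Named numeric vector: `mnf`, `mdf` (Hz, within \[0, fs/2\]).
#' @export
fd_features <- function(x, fs, spec = feature_spec()) {
  fd_features_mat(matrix(x, ncol = 1), fs, spec)[1, ]
}

#' Build a labelled feature table from window sets
#'
#' One row per window; 16 features x channels feature columns (named
#' `<feature>_ch<i>`, channel-major) plus the label columns patient_id,
#' group, week, movement, repetition, window_idx. Rows are ordered
#' deterministically by (patient, week, movement, repetition, window).
#'
#' @param window_sets List of `window_set` objects sharing fs and channels.
#' @param spec A [feature_spec()].
#' @return data.frame of class `feature_table`.
#' @export
build_feature_table <- function(window_sets, spec = feature_spec()) {
  if (!length(window_sets)) stop_data("no window sets supplied")
  fs <- unique(vapply(window_sets, function(w) w$fs, numeric(1)))
  nch <- unique(vapply(window_sets, function(w) length(w$channels),
                       numeric(1)))
  if (length(fs) != 1 || length(nch) != 1)
    stop_config("window sets have heterogeneous fs or channel count")
  rows <- lapply(window_sets, function(ws) {
    idx <- outer(seq_len(ws$window_samples), ws$starts, `+`)
    feats <- do.call(cbind, lapply(seq_len(nch), function(ch) {
      Xch <- matrix(ws$signal[, ch][idx], nrow = ws$window_samples)
      fc <- cbind(td_features_mat(Xch, spec), fd_features_mat(Xch, fs, spec))
      colnames(fc) <- paste0(colnames(fc), "_ch", ch)
      fc
    }))
    data.frame(patient_id = ws$patient_id, group = ws$group, week = ws$week,
               movement = ws$movement, repetition = ws$repetition,
               window_idx = seq_len(ws$n_windows), feats,
               check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$patient_id, tab$week, tab$movement, tab$repetition,
                   tab$window_idx), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Feature column names of a feature table
#' @param tab A `feature_table`.
#' @return Character vector of the non-label columns.
#' @export
feature_columns <- function(tab) {
  setdiff(names(tab), c("patient_id", "group", "week", "movement",
                        "repetition", "window_idx"))
}

#' Write / read a feature table as CSV
#' @param tab A `feature_table`.
#' @param path CSV path.
#' @export
write_feature_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
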