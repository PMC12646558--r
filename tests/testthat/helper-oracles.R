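# Independent oracles and small fixtures shared across tests.
# The naive_* functions are written directly from the defining formulas,
# deliberately without reusing any package internals.

naive_td_features <- function(x, zc_thr = 0, ssc_thr = 0, card_tol_frac = 1e-4,
                              kurtosis = "fisher") {
  N <- length(x)
  rms <- sqrt(sum(x^2) / N)
  mav <- sum(abs(x)) / N
  iemg <- sum(abs(x))
  ssc <- 0
  for (i in 2:(N - 1))
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > ssc_thr) ssc <- ssc + 1
  zc <- 0
  for (i in 1:(N - 1))
    if (sign(x[i]) != sign(x[i + 1]) && abs(x[i] - x[i + 1]) >= zc_thr)
      zc <- zc + 1
  ptp <- max(x) - min(x)
  xbar <- sum(x) / N
  v <- sum((x - xbar)^2) / (N - 1)
  wl <- 0
  for (i in 1:(N - 1)) wl <- wl + abs(x[i + 1] - x[i])
  sx <- sort(x)
  tol <- card_tol_frac * sqrt(v)
  card <- 1
  for (i in 2:N) if (sx[i] - sx[i - 1] > tol) card <- card + 1
  # type-7 quantiles, written out: h = (n-1)p + 1
  q7 <- function(p) {
    h <- (N - 1) * p + 1
    lo <- floor(h)
    sx[lo] + (h - lo) * (sx[min(lo + 1, N)] - sx[lo])
  }
  iqr <- q7(0.75) - q7(0.25)
  m2 <- sum((x - xbar)^2) / N
  m4 <- sum((x - xbar)^4) / N
  kurt <- if (m2 == 0) 0 else m4 / m2^2 - if (kurtosis == "fisher") 3 else 0
  c(rms = rms, mav = mav, iemg = iemg, ssc = ssc, zc = zc, ptp = ptp,
    var = v, sd = sqrt(v), wl = wl, card = card, iqr = iqr, kurt = kurt,
    aeng = sum(x^2) / N, aac = wl / (N - 1))
}

# Spearman rho from the rank formula with average ranks; exact two-sided
# permutation p by full enumeration (small n only).
naive_spearman <- function(x, y, exact_p = FALSE) {
  rho_of <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  rho <- rho_of(x, y)
  if (!exact_p) return(list(rho = rho))
  perms <- perms_of(length(x))
  stats <- apply(perms, 1, function(p) rho_of(x, y[p]))
  list(rho = rho, p = mean(abs(stats) >= abs(rho) - 1e-12))
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1, sub))))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
naive_mw_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- m * n / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# single-frequency power via the DFT sum, independent of any PSD code
tone_power <- function(x, fs, freq) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  Mod(sum(x * exp(-2i * pi * freq * t)))^2 / n^2
}

tone_recording <- function(freq, fs = 1926, dur_s = 2, amp = 1, nch = 2) {
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- matrix(amp * sin(2 * pi * freq * t), n, nch)
  colnames(sig) <- paste0("m", seq_len(nch))
  structure(list(signal = sig, fs = fs, channels = paste0("m", seq_len(nch)),
                 patient_id = "T01", group = "experimental", week = 0,
                 movement = "flexion",
                 boundaries = data.frame(repetition = 1, start = 0, end = n),
                 filters = character(0)),
            class = "emg_recording")
}

# short-session protocol used to keep simulation-heavy tests fast
fast_protocol <- function() acquisition_protocol(rest_s = 1, contract_s = 2)

# hand-built patient profile with full control over the latent state;
# clean = TRUE switches off every noise source
make_profile <- function(lambda = 0.9, jitter0 = 0, clean = TRUE,
                         gain_per_week = 0, seed = 1,
                         protocol = fast_protocol(), group = "experimental") {
  set.seed(seed)
  n_mov <- length(protocol$movements)
  n_ch <- length(protocol$channels)
  # separable by construction: distinct binary channel codes per movement
  code <- t(sapply(seq_len(n_mov), function(m)
    as.integer(bitwAnd(m, 2^(seq_len(n_ch) - 1)) > 0)))
  act <- matrix(0.25 + 0.95 * code, nrow = n_mov,
                dimnames = list(protocol$movements, protocol$channels))
  rates <- recovery_model(lambda0 = min(lambda, 1), plateau = 1,
                          gain_per_week = gain_per_week, jitter0 = jitter0,
                          jitter_decay = 0.25)
  structure(list(
    patient_id = "P01", group = group, activation_matrix = act,
    rates = rates,
    baseline_clinical = c(fma_ue = 35, arat = 20, bbt = 12),
    noise_scale = 1,
    snr_db = if (clean) 80 else 8,
    line_amp = if (clean) 0 else 0.05,
    drift_amp = if (clean) 0 else 0.2,
    clinical_link = list(beta_fma = 1.1, beta_arat = 1.2, beta_bbt = 1.7,
                         bbt_scale = 45, eps_sd = 1.5),
    master_seed = seed
  ), class = "patient_profile")
}

# small two-arm cohort on the short protocol
fast_cohort <- function(n = 3, seed = 1, weeks = c(0, 9), ...) {
  cohort_config(n_per_group = n, weeks = weeks, seed = seed,
                protocol = fast_protocol(), ...)
}

trial_summary_path <- function(f)
  system.file("extdata", "trial_summary", f, package = "emgrehab")
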