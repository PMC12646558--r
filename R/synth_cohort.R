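#' Generate a synthetic two-arm longitudinal cohort
#'
#' Draws per-patient profiles for both arms. Each profile carries a fixed
#' 7 movements x 5 channels activation-gain matrix (drawn once, reused at
#' every week), a patient-specific copy of the arm's [recovery_model()]
#' with mild heterogeneity in `lambda0` and `gain_per_week` (so patients
#' within an arm recover at different rates — this is what makes
#' cross-sectional EMG-vs-clinical correlations recoverable), baseline
#' clinical scores with FMA-UE inside the trial inclusion band \[25, 55\],
#' and a noise-scale multiplier.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: the config plus a list of patient
#'   profiles.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_mov <- length(config$protocol$movements)
  n_ch <- length(config$protocol$channels)
  patients <- list()
  for (group in c("experimental", "control")) {
    prefix <- if (group == "experimental") "E" else "C"
    base <- config$rates[[group]]
    for (i in seq_len(config$n_per_group)) {
      pid <- sprintf("%s%02d", prefix, i)
      set.seed(hash31(config$seed, "profile", pid))
      act <- matrix(runif(n_mov * n_ch, 0.2, 1.2), nrow = n_mov,
                    dimnames = list(config$protocol$movements,
                                    config$protocol$channels))
      # normalise each patient's overall activation level so that
      # between-patient amplitude differences reflect recovery (via
      # amp_gain * lambda), not electrode/anatomy nuisance
      act <- act * 0.7 / mean(act)
      rates_i <- base
      rates_i$lambda0 <- clamp(base$lambda0 + rnorm(1, 0, 0.04), 0.05, 0.95)
      rates_i$gain_per_week <- base$gain_per_week * exp(rnorm(1, 0, 0.3))
      baseline <- c(
        fma_ue = round(clamp(rnorm(1, 31, 4), 25, 45)),
        arat = round(clamp(rnorm(1, 20, 5), 5, 40)),
        bbt = round(clamp(rnorm(1, 12, 5), 2, 35))
      )
      patients[[pid]] <- structure(list(
        patient_id = pid, group = group,
        activation_matrix = act,
        rates = rates_i,
        baseline_clinical = baseline,
        noise_scale = exp(rnorm(1, 0, 0.1)),
        snr_db = config$snr_db, line_amp = config$line_amp,
        drift_amp = config$drift_amp,
        clinical_link = config$clinical_link,
        master_seed = config$seed
      ), class = "patient_profile")
    }
  }
  structure(list(config = config, patients = patients), class = "cohort")
}

# trapezoidal contraction envelope with zero rest segments;
# ramp_s ramps at contraction onset/offset
session_envelope <- function(protocol, ramp_s = 0.25) {
  fs <- protocol$fs_hz
  n <- protocol_samples(protocol)
  env <- numeric(n)
  bounds <- protocol_boundaries(protocol)
  ramp_n <- max(1L, as.integer(round(ramp_s * fs)))
  for (r in seq_len(nrow(bounds))) {
    i0 <- bounds$start[r] + 1L  # 0-based half-open -> 1-based inclusive
    i1 <- bounds$end[r]
    len <- i1 - i0 + 1L
    e <- rep(1, len)
    k <- min(ramp_n, floor(len / 2))
    e[seq_len(k)] <- seq(0, 1, length.out = k)
    e[(len - k + 1L):len] <- seq(1, 0, length.out = k)
    env[i0:i1] <- e
  }
  env
}

# bandlimited (20-450 Hz) unit-RMS Gaussian carrier, the standard
# amplitude-modulation surrogate for interference-pattern sEMG
semg_carrier <- function(n, fs) {
  bf <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sqrt(mean(x^2))
}

#' Simulate one patient/week/movement sEMG recording
#'
#' Per channel c the clean signal is
#' `amp(lambda) * A_eff[m, c] * jitter[rep, c] * envelope(t) * carrier_c(t)`
#' where `A_eff = (1 - lambda) * Abar + lambda * A[m, ]` blends the
#' patient's movement-specific activation row `A[m, ]` with the
#' movement-averaged (confusable) pattern `Abar`, `amp(lambda) = 1 +
#' amp_gain * lambda`, and `jitter` is per-repetition, per-channel
#' multiplicative log-normal jitter with scale
#' `jitter0 * jitter_decay^lambda`. Added on top: white noise at the
#' configured SNR (relative to the mean clean contraction power), 50 Hz
#' line interference, and sub-2 Hz baseline drift. The envelope is exactly
#' zero during rest blocks.
#'
#' @param profile A patient profile from [make_cohort()].
#' @param week Assessment week.
#' @param movement Movement label; must be one of the protocol's movements.
#' @param protocol An [acquisition_protocol()].
#' @param seed RNG seed for this recording; by default derived by hashing
#'   (master seed, patient, week, movement), so any recording can be
#'   regenerated in isolation.
#' @return An object of class `emg_recording`: `signal` (samples x channels
#'   matrix, mV), `fs`, `channels`, labels, 0-based half-open contraction
#'   `boundaries`, and a `filters` log.
#' @export
simulate_emg_session <- function(profile, week, movement, protocol,
                                 seed = NULL) {
  if (!movement %in% protocol$movements)
    stop_data("unknown movement label: ", movement)
  if (is.null(seed))
    seed <- hash31(profile$master_seed, "emg", profile$patient_id, week,
                   movement)
  set.seed(seed)
  fs <- protocol$fs_hz
  n <- protocol_samples(protocol)
  n_ch <- length(protocol$channels)
  lam <- lambda_at(profile$rates, week)
  A <- profile$activation_matrix
  a_eff <- (1 - lam) * colMeans(A) + lam * A[movement, ]
  amp <- 1 + profile$rates$amp_gain * lam

  env <- session_envelope(protocol)
  bounds <- protocol_boundaries(protocol)
  jit_sd <- profile$rates$jitter0 * profile$rates$jitter_decay^lam
  jit <- matrix(exp(rnorm(protocol$repetitions * n_ch, 0, jit_sd)),
                nrow = protocol$repetitions)

  # per-repetition jittered envelope, one column per channel
  env_ch <- matrix(env, nrow = n, ncol = n_ch)
  for (r in seq_len(nrow(bounds))) {
    idx <- (bounds$start[r] + 1L):bounds$end[r]
    env_ch[idx, ] <- env_ch[idx, ] * rep(jit[r, ], each = length(idx))
  }

  clean <- matrix(0, n, n_ch)
  for (c in seq_len(n_ch))
    clean[, c] <- amp * a_eff[c] * env_ch[, c] * semg_carrier(n, fs)

  contr <- env > 0
  p_clean <- mean(clean[contr, ]^2)
  noise_sd <- sqrt(p_clean / 10^(profile$snr_db / 10)) * profile$noise_scale

  t <- (seq_len(n) - 1) / fs
  sig <- clean + matrix(rnorm(n * n_ch, 0, noise_sd), n, n_ch)
  for (c in seq_len(n_ch)) {
    sig[, c] <- sig[, c] +
      profile$line_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    for (k in 1:3)
      sig[, c] <- sig[, c] + (profile$drift_amp / 3) *
        sin(2 * pi * runif(1, 0.2, 1.8) * t + runif(1, 0, 2 * pi))
  }
  colnames(sig) <- protocol$channels

  structure(list(signal = sig, fs = fs, channels = protocol$channels,
                 patient_id = profile$patient_id, group = profile$group,
                 week = week, movement = movement, boundaries = bounds,
                 lambda = lam, seed = seed, filters = character(0)),
            class = "emg_recording")
}

#' Simulate clinical outcome scores for one patient-week
#'
#' Scores improve monotonically (in expectation) with the latent recovery:
#' `FMA-UE = clamp(round(FMA0 + beta_fma * lambda_c(w) * (66 - FMA0) + eps), 0, 66)`
#' where `lambda_c(w) = lambda0 + g * (lambda(w) - lambda0)` anchors the
#' arm's `clinical_gain` `g` on the *progress* from baseline (so both arms
#' start balanced and `g` scales only the clinical response to recovery);
#' ARAT analogously into \[0, 57\];
#' `BBT = clamp(round(BBT0 + beta_bbt * lambda_c(w) * bbt_scale + eps), 0, Inf)`.
#' `eps` is Gaussian with the configured `eps_sd`.
#'
#' @param profile A patient profile from [make_cohort()].
#' @param week Assessment week.
#' @param eps_sd Overrides the configured noise SD (e.g. 0 for a noiseless
#'   check).
#' @return A one-row data.frame: patient_id, group, week, fma_ue, arat, bbt.
#' @export
simulate_clinical_scores <- function(profile, week, eps_sd = NULL) {
  link <- profile$clinical_link
  if (is.null(eps_sd)) eps_sd <- link$eps_sd
  set.seed(hash31(profile$master_seed, "clinical", profile$patient_id, week))
  lam <- lambda_at(profile$rates, week)
  lam0 <- lambda_at(profile$rates, 0)
  lam_c <- lam0 + profile$rates$clinical_gain * (lam - lam0)
  b <- profile$baseline_clinical
  eps <- rnorm(3, 0, eps_sd)
  data.frame(
    patient_id = profile$patient_id, group = profile$group, week = week,
    fma_ue = clamp(round(b[["fma_ue"]] +
                           link$beta_fma * lam_c * (66 - b[["fma_ue"]]) +
                           eps[1]), 0, 66),
    arat = clamp(round(b[["arat"]] +
                         link$beta_arat * lam_c * (57 - b[["arat"]]) +
                         eps[2]), 0, 57),
    bbt = clamp(round(b[["bbt"]] + link$beta_bbt * lam_c * link$bbt_scale +
                        eps[3]), 0, Inf),
    row.names = NULL
  )
}

#' Clinical score table for a whole cohort
#' @param cohort A [make_cohort()] result.
#' @param weeks Weeks to simulate (default: the config's weeks).
#' @return data.frame with one row per patient-week.
#' @export
cohort_clinical_scores <- function(cohort, weeks = cohort$config$weeks) {
  do.call(rbind, lapply(cohort$patients, function(p)
    do.call(rbind, lapply(weeks, function(w) simulate_clinical_scores(p, w)))))
}

#' Write a cohort's dataset to disk
#'
#' One EMG CSV (`time_s,ch1..ch5`) plus JSON sidecar per
#' (patient, week, movement), one clinical score table, and a manifest
#' (JSON) listing every file with its MD5 checksum, the generator version
#' and the master seed. Regenerating with the same seed reproduces
#' identical checksums.
#'
#' @param cohort A [make_cohort()] result.
#' @param protocol Protocol override (default: the cohort's).
#' @param out_dir Output directory (created if absent).
#' @param weeks,movements Optional subsets for scaled-down datasets.
#' @return The manifest, invisibly written to `manifest.json`.
#' @export
generate_dataset <- function(cohort, protocol = cohort$config$protocol,
                             out_dir, weeks = cohort$config$weeks,
                             movements = protocol$movements) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_data("cannot create output directory: ", out_dir)
  emg_dir <- file.path(out_dir, "emg")
  dir.create(emg_dir, showWarnings = FALSE)
  files <- list()
  for (p in cohort$patients) for (w in weeks) for (m in movements) {
    rec <- simulate_emg_session(p, w, m, protocol)
    stem <- file.path(emg_dir, sprintf("%s_w%s_%s", p$patient_id, w, m))
    write_emg(rec, paste0(stem, ".csv"), paste0(stem, ".json"))
    files[[length(files) + 1]] <- data.frame(
      path = paste0(stem, c(".csv", ".json")), role = c("emg", "sidecar"))
  }
  clin <- cohort_clinical_scores(cohort, weeks)
  clin_path <- file.path(out_dir, "clinical_scores.csv")
  write.csv(clin, clin_path, row.names = FALSE, quote = FALSE)
  files[[length(files) + 1]] <- data.frame(path = clin_path, role = "clinical")
  ftab <- do.call(rbind, files)
  ftab$md5 <- unname(tools::md5sum(ftab$path))
  ftab$path <- basename_rel(ftab$path, out_dir)
  manifest <- list(generator = "emgrehab synthetic cohort",
                   version = as.character(utils::packageVersion("emgrehab")),
                   seed = cohort$config$seed, n_files = nrow(ftab),
                   files = ftab)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

basename_rel <- function(paths, root) {
  sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", root), "/?"), "",
      paths)
}
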