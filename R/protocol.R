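#' Acquisition protocol for a recording session
#'
#' Describes the cue-based sEMG acquisition protocol: each movement is
#' recorded as alternating rest and contraction blocks, repeated a fixed
#' number of times, on a fixed set of forearm channels. The defaults match
#' a wireless surface-EMG setup sampling at 1926 Hz with five forearm
#' muscles and seven functional hand movements, using a 5 s rest / 5 s
#' contraction block repeated three times.
#'
#' @param fs_hz Sampling frequency in Hz.
#' @param rest_s Rest block duration in seconds.
#' @param contract_s Contraction block duration in seconds.
#' @param repetitions Number of rest+contraction repetitions per movement.
#' @param movements Character vector of movement class labels.
#' @param channels Character vector of muscle/channel names.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(fs_hz = 1926,
                                 rest_s = 5,
                                 contract_s = 5,
                                 repetitions = 3,
                                 movements = c("flexion", "extension", "opening",
                                               "closing", "pinch", "pronation",
                                               "supination"),
                                 channels = c("extensor_digitorum_communis",
                                              "flexor_digitorum_superficialis",
                                              "supinator", "pronator_teres",
                                              "dorsal_interossei")) {
  if (fs_hz <= 0 || rest_s <= 0 || contract_s <= 0 || repetitions <= 0)
    stop_config("protocol fields must be positive")
  if (anyDuplicated(movements) || anyDuplicated(channels))
    stop_config("movement and channel labels must be unique")
  structure(list(fs_hz = fs_hz, rest_s = rest_s, contract_s = contract_s,
                 repetitions = repetitions, movements = movements,
                 channels = channels),
            class = "acquisition_protocol")
}

#' Total samples in one session of a protocol
#' @param protocol An [acquisition_protocol()].
#' @return Integer sample count: `repetitions * (rest_s + contract_s) * fs_hz`.
#' @export
protocol_samples <- function(protocol) {
  as.integer(round(protocol$repetitions *
                     (protocol$rest_s + protocol$contract_s) * protocol$fs_hz))
}

# 0-based half-open contraction boundaries for each repetition
protocol_boundaries <- function(protocol) {
  fs <- protocol$fs_hz
  block <- protocol$rest_s + protocol$contract_s
  data.frame(
    repetition = seq_len(protocol$repetitions),
    start = as.integer(round(((seq_len(protocol$repetitions) - 1) * block +
                                protocol$rest_s) * fs)),
    end = as.integer(round(seq_len(protocol$repetitions) * block * fs))
  )
}

#' Latent recovery model for one study arm
#'
#' Motor recovery is modelled through a single latent class-separability
#' parameter \eqn{\lambda(w) = \min(\textrm{plateau},\ \lambda_0 +
#' \textrm{gain\_per\_week} \cdot w)}, bounded in \[0, 1\]. \eqn{\lambda}
#' drives three observable aspects of the simulated sEMG: how distinct the
#' per-movement muscle activation patterns are (pattern blending), how much
#' the pattern jitters between repetitions (jitter scale
#' `jitter0 * jitter_decay^lambda`), and overall signal amplitude
#' (`1 + amp_gain * lambda`). A per-arm `clinical_gain` scales how strongly
#' \eqn{\lambda} translates into clinical score improvement, decoupling the
#' clinical contrast between arms from the EMG contrast.
#'
#' @param lambda0 Baseline separability in \[0, 1\].
#' @param gain_per_week Separability increment per week.
#' @param plateau Maximum separability (\eqn{\le} 1).
#' @param jitter0 Baseline within-class multiplicative jitter scale (log scale).
#' @param jitter_decay Multiplicative jitter reduction per unit separability,
#'   in (0, 1\].
#' @param amp_gain Fractional amplitude growth at full separability.
#' @param clinical_gain Multiplier on the latent-to-clinical-score link.
#' @return An object of class `recovery_model`.
#' @export
recovery_model <- function(lambda0 = 0.4, gain_per_week = 0.042,
                           plateau = 0.92, jitter0 = 0.35,
                           jitter_decay = 0.25, amp_gain = 1.5,
                           clinical_gain = 1) {
  if (lambda0 < 0 || lambda0 > 1 || plateau < 0 || plateau > 1)
    stop_config("lambda0 and plateau must lie in [0, 1]")
  if (gain_per_week < 0 || jitter0 < 0 || jitter_decay <= 0 || jitter_decay > 1)
    stop_config("invalid recovery model rates")
  structure(list(lambda0 = lambda0, gain_per_week = gain_per_week,
                 plateau = plateau, jitter0 = jitter0,
                 jitter_decay = jitter_decay, amp_gain = amp_gain,
                 clinical_gain = clinical_gain),
            class = "recovery_model")
}

#' Evaluate the latent separability at a given week
#' @param model A [recovery_model()].
#' @param week Assessment week (numeric, >= 0).
#' @return \eqn{\lambda(w)}, clamped to \[0, 1\].
#' @export
lambda_at <- function(model, week) {
  clamp(pmin(model$plateau, model$lambda0 + model$gain_per_week * week), 0, 1)
}

#' Configuration for a synthetic two-arm cohort
#'
#' @param n_per_group Patients per arm (>= 2).
#' @param weeks Strictly increasing assessment weeks.
#' @param seed Master seed; all per-recording streams derive from it.
#' @param snr_db Contraction-signal-to-white-noise ratio in dB.
#' @param line_amp Amplitude of 50 Hz line interference (mV).
#' @param drift_amp Amplitude of low-frequency (< 2 Hz) baseline drift (mV).
#' @param rates Named list of [recovery_model()]s for `experimental` and
#'   `control`; the experimental arm recovers faster by default.
#' @param clinical_link List of coefficients mapping the latent recovery to
#'   FMA-UE / ARAT / BBT improvements (see [simulate_clinical_scores()]).
#' @param protocol An [acquisition_protocol()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 26,
                          weeks = c(0, 4, 6, 9),
                          seed = 1,
                          snr_db = 8,
                          line_amp = 0.05,
                          drift_amp = 0.2,
                          rates = list(
                            experimental = recovery_model(gain_per_week = 0.042,
                                                          clinical_gain = 1),
                            control = recovery_model(gain_per_week = 0.028,
                                                     clinical_gain = 0.3)
                          ),
                          clinical_link = list(beta_fma = 1.1, beta_arat = 1.2,
                                               beta_bbt = 1.7, bbt_scale = 45,
                                               eps_sd = 1.5),
                          protocol = acquisition_protocol()) {
  if (n_per_group < 2) stop_config("n_per_group must be >= 2")
  if (length(weeks) < 1 || any(diff(weeks) <= 0))
    stop_config("weeks must be strictly increasing")
  if (!all(c("experimental", "control") %in% names(rates)))
    stop_config("rates must name 'experimental' and 'control'")
  structure(list(n_per_group = n_per_group, weeks = weeks, seed = seed,
                 snr_db = snr_db, line_amp = line_amp, drift_amp = drift_amp,
                 rates = rates, clinical_link = clinical_link,
                 protocol = protocol),
            class = "cohort_config")
}
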