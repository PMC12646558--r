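test_that("notch attenuates 50 Hz by >= 20 dB and spares neighbours", {
  r50 <- tone_recording(50)
  out <- apply_notch(r50)
  expect_equal(dim(out$signal), dim(r50$signal))
  att_db <- 10 * log10(tone_power(r50$signal[, 1], 1926, 50) /
                         tone_power(out$signal[, 1], 1926, 50))
  expect_gte(att_db, 20)

  r100 <- tone_recording(100)
  out100 <- apply_notch(r100)
  ratio <- sqrt(tone_power(out100$signal[, 1], 1926, 100) /
                  tone_power(r100$signal[, 1], 1926, 100))
  expect_lt(abs(ratio - 1), 0.05)  # amplitude preserved within 5%

  rz <- tone_recording(50, amp = 0)
  expect_equal(max(abs(apply_notch(rz)$signal)), 0)
})

test_that("bandpass rejects out-of-band tones and DC, passes 150 Hz", {
  r5 <- tone_recording(5)
  out5 <- apply_bandpass(r5)
  att_db <- 10 * log10(tone_power(r5$signal[, 1], 1926, 5) /
                         tone_power(out5$signal[, 1], 1926, 5))
  expect_gte(att_db, 20)

  r150 <- tone_recording(150)
  out150 <- apply_bandpass(r150)
  ratio <- sqrt(tone_power(out150$signal[, 1], 1926, 150) /
                  tone_power(r150$signal[, 1], 1926, 150))
  expect_lt(abs(ratio - 1), 0.05)

  rdc <- tone_recording(100)
  rdc$signal <- rdc$signal + 3  # DC offset sits outside the passband
  expect_lt(abs(mean(apply_bandpass(rdc)$signal[, 1])), 0.01)

  bad <- preprocess_config(band_hi_hz = 1000)
  expect_error(apply_bandpass(r5, bad), class = "emgrehab_config_error")
})

test_that("filters preserve length and channel order; reject non-finite data", {
  set.seed(4)
  rec <- tone_recording(80)
  rec$signal <- matrix(rnorm(length(rec$signal)), nrow(rec$signal))
  rec$signal[, 2] <- rec$signal[, 2] + 100  # marker offset on channel 2
  colnames(rec$signal) <- rec$channels
  out <- apply_bandpass(apply_notch(rec))
  expect_equal(dim(out$signal), dim(rec$signal))
  expect_equal(colnames(out$signal), rec$channels)
  expect_equal(out$filters, c("notch50_q30", "bandpass20-450_o4"))

  bad <- rec
  bad$signal[17, 2] <- NaN
  err <- tryCatch(apply_notch(bad), error = function(e) conditionMessage(e))
  expect_match(err, "m2")   # names the channel
  expect_match(err, "16")   # and the 0-based index
})

test_that("notch and bandpass nearly commute on synthetic EMG", {
  p <- make_profile(lambda = 0.7, clean = FALSE)
  rec <- simulate_emg_session(p, 0, "flexion", fast_protocol())
  a <- apply_bandpass(apply_notch(rec))
  b <- apply_notch(apply_bandpass(rec))
  for (ep_pair in seq_len(3)) {
    ea <- extract_epochs(a, fast_protocol())[[ep_pair]]
    eb <- extract_epochs(b, fast_protocol())[[ep_pair]]
    wa <- make_windows(ea)
    rms_a <- sqrt(colMeans(sapply(seq_len(wa$n_windows),
                                  function(i) get_window(wa, i)[, 1])^2))
    wb <- make_windows(eb)
    rms_b <- sqrt(colMeans(sapply(seq_len(wb$n_windows),
                                  function(i) get_window(wb, i)[, 1])^2))
    expect_lt(max(abs(rms_a - rms_b) / rms_a), 0.01)
  }
})

test_that("epoch extraction is cue-based with floor guard arithmetic", {
  proto <- acquisition_protocol()
  p <- make_profile(lambda = 0.5, protocol = proto)
  rec <- simulate_emg_session(p, 0, "flexion", proto)
  eps0 <- extract_epochs(rec, proto, guard_ms = 0)
  expect_length(eps0, 3)
  expect_equal(nrow(eps0[[1]]$signal), 5 * 1926)        # 9,630
  eps <- extract_epochs(rec, proto, guard_ms = 250)
  expect_equal(nrow(eps[[1]]$signal), 9630 - 2 * 481)   # floor(0.25*1926)=481
  # epochs ordered and non-overlapping
  starts <- vapply(eps, function(e) e$start, numeric(1))
  ends <- vapply(eps, function(e) e$end, numeric(1))
  expect_true(all(diff(starts) > 0) && all(ends[-3] <= starts[-1]))

  no_sidecar <- rec
  no_sidecar$boundaries <- NULL
  expect_error(extract_epochs(no_sidecar, proto),
               class = "emgrehab_data_error")
  outside <- rec
  outside$boundaries$end[3] <- nrow(rec$signal) + 10
  expect_error(extract_epochs(outside, proto),
               class = "emgrehab_data_error")
})

test_that("overlap windowing follows the floor arithmetic exactly", {
  mk_epoch <- function(L) structure(
    list(signal = matrix(rnorm(L * 2), L, 2), start = 0, end = L,
         repetition = 1, patient_id = "P", group = "g", week = 0,
         movement = "flexion", fs = 1926, channels = c("a", "b")),
    class = "contraction_epoch")
  ws <- make_windows(mk_epoch(9630))
  expect_equal(ws$window_samples, 481)
  expect_equal(ws$step_samples, 240)
  expect_equal(ws$n_windows, floor((9630 - 481) / 240) + 1)  # 39
  expect_equal(ws$n_windows, 39)
  expect_equal(unique(diff(ws$starts)), 240)                  # arithmetic
  expect_lte(max(ws$starts) + 481, 9630)                      # inside epoch
  # coverage: windows at 50% overlap span all but the trailing remainder
  covered <- max(ws$starts) + 481
  expect_gte(covered / 9630, (9630 - 481 + 1) / 9630)

  ws0 <- make_windows(mk_epoch(962), preprocess_config(overlap_frac = 0))
  expect_equal(ws0$n_windows, 2)
  expect_equal(ws0$starts, c(0, 481))  # disjoint

  expect_error(make_windows(mk_epoch(480)), class = "emgrehab_data_error")
})
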