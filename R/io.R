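#' Write an EMG recording as CSV + JSON sidecar
#'
#' CSV header is `time_s,ch1..ch<k>`, one row per sample, fixed 6-decimal
#' formatting (so regeneration under the same seed is byte-identical). The
#' sidecar records fs, labels and the 0-based half-open contraction
#' repetition boundaries.
#'
#' @param rec An `emg_recording`.
#' @param path CSV output path.
#' @param sidecar_path JSON sidecar path.
#' @export
write_emg <- function(rec, path, sidecar_path) {
  n <- nrow(rec$signal)
  k <- ncol(rec$signal)
  t <- (seq_len(n) - 1) / rec$fs
  m <- cbind(sprintf("%.6f", t),
             matrix(sprintf("%.6f", rec$signal), n, k))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time_s", paste0("ch", seq_len(k))), collapse = ","), con)
  writeLines(do.call(paste, c(split(m, col(m)), sep = ",")), con)
  jsonlite::write_json(list(
    fs_hz = rec$fs, patient_id = rec$patient_id, group = rec$group,
    week = rec$week, movement = rec$movement, channels = rec$channels,
    n_samples = n, seed = rec$seed, filters = rec$filters,
    boundaries = rec$boundaries
  ), sidecar_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an EMG recording from CSV + JSON sidecar
#'
#' Validates the header, time monotonicity, completeness, and that the
#' sidecar's sampling frequency matches the time-column spacing within
#' 1 ppm.
#'
#' @param path CSV path (`time_s,ch1..`).
#' @param sidecar_path JSON sidecar path.
#' @return An `emg_recording`.
#' @export
read_emg <- function(path, sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  d <- read.csv(path, check.names = FALSE)
  k <- length(meta$channels)
  want <- c("time_s", paste0("ch", seq_len(k)))
  if (!identical(names(d), want))
    stop_data("bad EMG header in ", path, ": got [",
              paste(names(d), collapse = ","), "]")
  if (anyNA(d))
    stop_data("incomplete/truncated EMG file ", path, " at row ",
              which(!complete.cases(d))[1])
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop_data("non-monotone time column in ", path)
  # span-based estimate: robust to the fixed-decimal quantisation of time_s
  fs_obs <- (nrow(d) - 1) / (d$time_s[nrow(d)] - d$time_s[1])
  if (abs(fs_obs - meta$fs_hz) / meta$fs_hz > 1e-6 + 2e-6 * meta$fs_hz / nrow(d))
    stop_data("sidecar fs ", meta$fs_hz, " Hz disagrees with time spacing (",
              signif(fs_obs, 8), " Hz) in ", path)
  sig <- as.matrix(d[, -1, drop = FALSE])
  colnames(sig) <- meta$channels
  structure(list(signal = sig, fs = meta$fs_hz, channels = meta$channels,
                 patient_id = meta$patient_id, group = meta$group,
                 week = meta$week, movement = meta$movement,
                 boundaries = as.data.frame(meta$boundaries),
                 seed = meta$seed,
                 filters = as.character(unlist(meta$filters))),
            class = "emg_recording")
}

#' Read and validate a dataset manifest
#'
#' Checks that every referenced file exists and that its MD5 checksum
#' matches the manifest.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return The manifest list.
#' @export
read_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  f <- manifest$files
  paths <- file.path(dir, f$path)
  missing <- !file.exists(paths)
  if (any(missing))
    stop_data("manifest references missing file(s): ",
              paste(f$path[missing], collapse = ", "))
  md5 <- unname(tools::md5sum(paths))
  bad <- md5 != f$md5
  if (any(bad))
    stop_data("checksum mismatch for: ", paste(f$path[bad], collapse = ", "))
  manifest
}

#' Read a clinical score table
#' @param path CSV with columns patient_id,group,week,fma_ue,arat,bbt.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  d <- read.csv(path)
  need <- c("patient_id", "group", "week", "fma_ue", "arat", "bbt")
  if (!all(need %in% names(d)))
    stop_data("clinical table ", path, " missing columns: ",
              paste(setdiff(need, names(d)), collapse = ", "))
  d
}
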