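#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd quantile var median aov anova shapiro.test
#'   t.test wilcox.test cor.test fft mvfft predict complete.cases setNames
#' @importFrom utils read.csv write.csv
NULL

# Deterministic 31-bit string hash (polynomial rolling hash, FNV-style).
# Used to derive independent RNG streams for (patient, week, movement)
# triples from one master seed, so any subset of the dataset can be
# regenerated bit-identically without replaying the whole simulation.
hash31 <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\x1f")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor only touches the low byte (b < 256); keep h as a double
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, done in two
    # 16-bit halves to stay within double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# internal error helpers: configuration vs data errors are distinct
# conditions so callers (and exit-code mapping in drivers) can tell apart
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgrehab_config_error", "error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgrehab_data_error", "error")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# milliseconds to samples, floor convention (documented: 1926 Hz * 250 ms
# = 481.5 is non-integer; floor gives 481)
ms_to_samples <- function(ms, fs) floor(ms * fs / 1000)
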