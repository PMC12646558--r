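# Shared configuration for the analysis drivers.
#
# Demo cohort: 8 patients per arm, all four assessment weeks, on a
# short-contraction protocol (1 s rest / 2 s contraction x 3 repetitions)
# that keeps the full workflow at desk scale; windowing, features and
# classifiers are identical to the full-length 5 s / 5 s protocol.

library(emgrehab)

DEMO_SEED <- 20260921L %% 2147483647L
demo_protocol <- acquisition_protocol(rest_s = 1, contract_s = 2)
demo_config <- cohort_config(n_per_group = 8, weeks = c(0, 4, 6, 9),
                             seed = DEMO_SEED, protocol = demo_protocol)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
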