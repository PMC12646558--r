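Group-level summary statistics reported by the original randomized
controlled trial whose assessment methodology this package implements:
clinical outcome means/SDs (FMA-UE, ARAT, BBT) at the pre/post
timepoints per arm, and movement-classification accuracies (percent) per
classifier, arm and assessment week. These are published aggregates, not
patient data; the worked examples and the acceptance script recompute
derived quantities (difference-in-differences, classifier means,
progression cells) from them.
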