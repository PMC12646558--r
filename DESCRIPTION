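Package: emgrehab
Title: EMG-Based Longitudinal Assessment of Hand Motor Recovery After Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reusable pipeline for assessing hand motor recovery in stroke
    rehabilitation from multi-channel forearm surface electromyography (sEMG).
    Implements notch/bandpass preprocessing and overlap windowing, a
    16-feature time/frequency feature bank, per-patient movement
    classification (KNN, random forest, SVM) tracked across assessment weeks,
    Spearman correlation of EMG features with clinical outcome scores
    (FMA-UE, ARAT, BBT), and MCID-referenced clinical outcome analysis.
    Includes a synthetic two-arm longitudinal cohort generator with a latent
    class-separability recovery model, so the full analysis is testable
    end-to-end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    class,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
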