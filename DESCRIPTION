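Package: tussive
Title: Cough Sound Event Detection from Continuous Clinical Audio
Version: 0.99.0
Authors@R:
    person("Morgan", "Keller", email = "mkeller@example.org",
           role = c("aut", "cre"))
Description: Detects individual cough events in long single-channel clinical
    audio recordings. Recordings are segmented with a 0.5-second sliding
    window, each window is featurized as a 128 x 22 Mel spectrogram, and
    windows are classified by a residual convolutional-recurrent network
    trained with a class-imbalance weighted binary cross-entropy, alongside
    four classical baselines (ridge logistic regression, decision tree,
    random forest, RBF support vector machine) on a flatten-PCA-standardize
    feature track. Because clinical cough-challenge audio is private, the
    package ships a seeded synthetic generator that emits WAV recordings
    with cough bouts of declining amplitude, speech-like and throat-clear
    distractors, and Audacity-style label tracks, so the full pipeline is
    testable end to end. Includes silence trimming, an amplitude-based
    imbalance filter, MFCC / zero-crossing-rate / spectral roll-off
    features, accuracy/sensitivity/specificity and ROC/AUC evaluation, and
    a cross-environment generalization harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    rpart,
    randomForest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
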