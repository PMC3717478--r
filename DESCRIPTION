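Package: actiflux
Title: Accelerometer-Based Physical Activity and Daily Affect in Children
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested analysis chain for ambulatory studies of elementary
    school children who wear waist-mounted triaxial accelerometers and
    answer short smartphone affect items several times a day. Provides a
    synthetic-data generator for raw 30 Hz acceleration traces, labelled
    reference sessions, sleep diaries and Likert affect responses;
    non-overlapping 2.5 s frame features (per-axis mean, variance,
    inter-axis correlations and spectral energy); reference-pattern
    activity classification with individual and pooled support vector
    machine models; non-wear consolidation, wake-window restriction and
    valid-day screening; daily physical-activity and affect composites
    with descriptive statistics (intra-individual SD, intraclass
    correlation); and two-level mixed-effects models of daily affect on
    person-mean-centered daily activity fitted by restricted maximum
    likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
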