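Package: songeval
Title: Tutor Imitation Scoring, Syllable Stereotypy and Event-Aligned
    Spike-Train Statistics for Songbird Vocal Learning Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for zebra finch vocal-learning experiments:
    multitaper spectrograms and Sound-Analysis-Pro-style acoustic features
    (amplitude, frequency modulation, Wiener entropy, pitch goodness, cepstral
    pitch) at 1 ms resolution; a tutor-imitation score combining acoustic and
    sequence similarity with an imitation-capacity rescaling; syllable
    stereotypy and bout maturity indices from spectrogram cross-correlation;
    event-aligned spike-train statistics (PSTHs, paired window tests,
    circular-shift bootstrap significance, response latency and duration
    detection, motif-locked modulation, antidromic band-power tests); and
    seeded synthetic song and spike-train generators with ground truth so
    every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
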