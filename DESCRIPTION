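Package: ppafseiz
Title: Peak-to-Peak Amplitude Fluctuation Analysis for EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scalp EEG seizure analysis built around the
    Peak-to-Peak Amplitude Fluctuation (PPAF) statistic: reading and
    writing EDF+ recordings with seizure annotations, generation of
    synthetic annotated multichannel EEG (pink-noise background, alpha
    rhythm, 3 Hz spike-and-wave seizures, ocular/muscle/line artifacts),
    zero-phase FIR filtering and common-average re-referencing,
    independent component analysis with automated artifact-component
    scoring and rejection, time-locked epoch extraction and
    event-related-potential (ERP) analysis including component
    contribution envelopes and scalp interpolation grids, and a
    sliding-window PPAF threshold detector evaluated with
    leave-one-patient-out cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
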