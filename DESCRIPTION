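Package: ffrdelay
Title: Group-Delay Analysis of the Frequency Following Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the latency of the scalp-recorded frequency
    following response (FFR) from its group delay. Synthesizes alternating-
    polarity three-tone amplitude-modulated stimuli, simulates multi-source
    scalp recordings (envelope-following, fine-structure-following and
    cochlear-microphonic components mixed per electrode montage, with pink and
    white EEG noise and artifact epochs), and implements the full analysis
    chain: zero-phase Butterworth band-pass filtering, peak-amplitude artifact
    rejection, polarity addition/subtraction to separate envelope- and fine-
    structure-locked activity, exact-frequency DFT estimation with an
    F-ratio response-presence test against an off-frequency noise floor,
    transducer phase correction, and delay-bounded exhaustive phase unwrapping
    with constrained linear fitting to obtain group delay per frequency region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
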