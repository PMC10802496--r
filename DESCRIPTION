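Package: soundseekr
Title: Simulation and Analysis of Sound-Seeking Behavior in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying active sound localization ("sound-seeking")
    in freely moving mice. Generates gamma renewal-process acoustic stimulus
    streams, simulates the eight-chamber foraging task under pluggable agent
    policies, scores trials by the fraction-correct and ports-poked metrics,
    detects and classifies chamber entries from keypoint pose tracks
    (duplicate, cycling, with-poke, check), quantifies the acoustic startle
    response from video-derived movement speed, and preprocesses auditory
    brainstem response (ABR) recordings (cross-talk removal, high-pass
    filtering, outlier rejection, polarity-corrected averaging). A synthetic
    data module generates pose tracks, event logs, startle sessions and ABR
    recordings with known ground truth so every pipeline stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
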