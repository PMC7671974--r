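Package: surgkin
Title: Motion Analysis of Robot-Assisted Surgery Kinematics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reads JIGSAWS-style tool-tip kinematic recordings from
    teleoperated surgical robots (76 whitespace-separated values per 30 Hz
    frame, 19 channels for each of four manipulators), computes the three
    classical motion-analysis skill metrics -- task time, Cartesian path
    length and number of movements (local peaks of the Gaussian-smoothed
    displacement signal) -- and relates them to global rating scale (GRS)
    scores and self-declared skill levels via Mann-Whitney U comparisons and
    Pearson/Spearman correlations. Includes a minimum-jerk synthetic trial
    and cohort generator with known ground truth so the entire pipeline is
    testable without access to the dataset, plus a command-line interface
    and a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
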