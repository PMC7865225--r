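Package: cbelief
Title: Complex Evidence Theory: Complex Mass Functions, Fusion, and
    Betting-Commitment Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for complex evidence theory, the extension of
    Dempster-Shafer belief functions to complex-valued mass functions
    (complex basic belief assignments, CBBAs). Provides validated frames of
    discernment and CBBA containers, the complex Dempster rule of
    combination with its conflict coefficient, the complex pignistic
    transformation and betting commitments over all subsets, the
    betting-commitment-based distance between CBBAs (which reduces to
    Liu's difBetP on classical mass functions), and a (weighted)
    multi-attribute minimum-distance classifier for evidential pattern
    recognition, e.g. sensor-based medical diagnosis. Includes worked
    reference examples, a seeded random-CBBA generator for property
    testing, JSON/CSV readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
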