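Package: golayscan
Title: Golay-Coded Air-Coupled Ultrasonic Inspection of Wood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coded-excitation air-coupled ultrasonic through-transmission
    inspection of wooden boards. Generates Golay complementary pairs and
    baseline codes (Barker-7, uniform bursts), modulates them onto wide-pulse
    or square-wave carriers, propagates them through a synthetic
    through-transmission channel for virtual boards (interface
    reflection/transmission from acoustic impedance, frequency-dependent
    attenuation, transducer ringing, receiver band-pass filtering, additive
    noise), decodes received traces by matched filtering with complementary
    summation, and builds A-scan traces and C-scan peak-voltage images with
    knot/pit classification and overlap scoring against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    png,
    pracma,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
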