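Package: aortastiff
Title: Aortic Stiffness Indices from CMR Velocity, Area and Centerline Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes regional and local indices of aortic stiffness from
    cardiovascular magnetic resonance derived inputs. Regional aortic arch
    pulse wave velocity is obtained from the transit time between ascending
    and descending aorta velocity waveforms (least-squares matching of the
    systolic up-slope after 1 ms cubic resampling) combined with the arc
    length of an interpolating 3D Bezier centerline clipped to the
    phase-contrast slice plane. Local ascending-aorta strain, distensibility
    and Bramwell-Hill theoretical pulse wave velocity are derived from
    lumen-area curves and carotid or brachial pulse pressure, with carotid
    pressure calibrated from applanation tonometry by the mean/diastolic
    rescaling rule. A synthetic cohort generator with known ground truth and
    cohort-level regression, reproducibility and group statistics make every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
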