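Package: seedsqi
Title: Sound Seed Selection from SWIR Hyperspectral Images via the Seed
    Quality Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens conifer seeds (Cryptomeria japonica and Chamaecyparis
    obtusa) for anatomical soundness from short-wavelength-infrared (SWIR)
    hyperspectral reflectance images. Sound seeds show a lipid absorption
    dip near 1,730 nm ("m-shaped" spectra) that unsound seeds lack; the
    package quantifies the dip with a three-band angular index (SQI),
    segments seed areas by spectral similarity, maps the index pixelwise,
    and selects sound seeds by single-parameter (maxSQI) or dual-parameter
    (maxSQI plus a peak-to-base area ratio threshold) rules calibrated by
    total-error-rate minimization with cross-lot validation. Includes ENVI
    cube input/output, radiance-to-reflectance calibration against a
    reference target, and a synthetic plate generator for end-to-end
    testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
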