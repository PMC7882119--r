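Package: dualmlc
Title: Dosimetric Commissioning of a Dual-Layer MLC Ring-Gantry Linac
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dosimetric commissioning of a stacked-and-staggered
    dual-layer multileaf collimator (MLC) on a ring-gantry linear
    accelerator. Implements a parametric leaf-end model (Offset, Gain,
    Curvature, tip width, transmission, tongue-and-groove width), a fluence
    and simplified kernel dose engine for static and dynamic deliveries, a
    virtual measurement laboratory (sweeping-gap ion-chamber sessions,
    abutting-field and complementary bar-pattern scans, modulated test
    plans with chamber points and a cylindrical diode array), the
    parameter-estimation pipeline (dosimetric leaf gap, RMS sweeping-gap
    optimization, midpoint-shift regression, modulated-plan offset scan),
    and an evaluation layer with local/global gamma analysis, per-detector
    dose-error statistics and TG-119-style confidence limits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
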