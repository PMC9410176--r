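Package: repolab
Title: Ventricular Repolarization Morphology Markers from 12-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ventricular repolarization from resting 12-lead
    electrocardiograms. Reduces the eight independent surface leads to a
    three-dimensional decomposition space by singular value decomposition,
    locates QRS and T-wave landmarks on the resulting energy envelope, and
    computes the total cosine R-to-T (TCRT) and T-wave morphology dispersion
    (TMD, TMDpre, TMDpost) markers from randomly selected and averaged beats.
    Measures QT, Bazett-corrected QT, and Tpeak-Tend intervals on lead V5 by
    the tangent method. Includes a rank-3 cardiac dipole simulator with a
    programmable spatial angle between depolarization and repolarization
    loops, two-group cohort synthesis, and the nonparametric case-control
    statistics layer (Kruskal-Wallis, Fisher's exact, multivariable linear
    model) used to compare marker distributions between groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
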