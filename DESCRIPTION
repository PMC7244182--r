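Package: tricomp
Title: Configural Vector Models of Human Path Integration in the
    Triangle Completion Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative models of human homing behaviour in the triangle
    completion task, in which a walker is guided along two sides of a
    triangle and must return to the origin unguided.  Implements a
    weighted vector-addition model of the configural homing vector, an
    extension with an exponentially decaying trial-history term, and the
    classical Encoding-Error Model (law-of-cosines return path), all
    under Weber-scaled isotropic Gaussian response noise.  Provides
    per-subject maximum-likelihood fitting with multi-start bounded
    optimisation, forward simulation, AIC/BIC model comparison,
    random-effects group model selection via exceedance probabilities,
    model-recovery confusion matrices, synthetic session generators for
    two experimental designs (varied triangle shape at fixed return
    distance; fixed scalene shape at perimeters from 15 to 506 metres),
    and descriptive summaries of angular, distance and position errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
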