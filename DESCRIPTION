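Package: skullkin
Title: Multi-Loop Linkage Kinematics of Highly Kinetic Skulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and fitting three-dimensional multi-loop linkage
    models of kinetic skulls from marker-based motion data. Provides rigid-body
    alignment and trajectory smoothing, fitting of revolute, universal, spherical
    and prismatic joint models to the relative motion of articulated bone pairs,
    assembly of link/joint graphs with loop counting and Chebychev-Gruebler-Kutzbach
    mobility analysis, constrained forward kinematics of parallel mechanisms,
    sequential degree-of-freedom freezing to rank the degrees of freedom actually
    used in recorded motion, and rule-based classification of cranial
    expansion-wave motion patterns with associated prey velocity profiles. Includes
    a bilaterally symmetric catfish-like five-loop skull fixture and a seeded
    synthetic-data generator so the full pipeline can be exercised without any
    in vivo recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
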