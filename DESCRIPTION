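Package: fiberpol
Title: Polarized Fluorescence Analysis of Oriented Muscle Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of steady-state polarized
    fluorescence from probes bound to oriented actin filaments in ghost
    muscle fibers.  Implements the helix-plus-isotropic orientation model
    (cone half-angles, disordered-probe fraction, filament wobble), probe
    orientation fitting by bounded multi-start least squares, conversion of
    filament wobble to bending stiffness via the semiflexible-filament
    relation, actin-frame correction of tropomyosin emission angles, Hill
    analysis of calcium-activated ATPase assays, mutant-versus-wild-type
    delta tables with trinary significance calls, and nearest-neighbour
    classification of mutation signatures into congenital myopathy groups.
    Includes a seeded synthetic-data generator emulating fiber ensembles
    and ATPase titrations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
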