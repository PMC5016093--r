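Package: magnetolimits
Title: Order-of-Magnitude Biophysics of Magnetogenetics Proposals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the physical plausibility of proposed magnetogenetics
    and molecular-magnetoreception mechanisms by chaining order-of-magnitude
    biophysics calculations: thermal alignment of paramagnetic complexes
    (Langevin statistics), single-particle magnetizability derived from bulk
    susceptibility measurements with CGS/SI conversion, magnetostatic forces
    on ferritin (field-gradient pull, dipole-dipole attraction, anisotropy
    torque, collective membrane stress), and magnetic-nanoparticle heating
    (specific loss power scaling, steady-state nanoscale conduction,
    interfacial thermal conductance). Each computed quantity is compared with
    the relevant biophysical threshold and reported as a signed log-unit gap,
    with a reproduction table, tidy verdict tibbles, and ggplot2 methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
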