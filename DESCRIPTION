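Package: adcomplement
Title: Structural Modeling of IgM- and Complement-Mediated Adenovirus
    Neutralization and Its Inhibition by Coagulation Factor X
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained structural modeling pipeline for the adenovirus
    (HAdv-C5) capsid facet and its decoration by host immune and coagulation
    proteins. Generates synthetic bead models of the hexon trimer, penton
    base, fiber, pentameric IgM, the C1 complex, complement fragments C4b and
    C3b, and coagulation factor X; assembles an 18-trimer facet with helically
    built fibers; enumerates bent-IgM poses with template-driven C1/C4b
    placement and convertase-guided C3b propagation; models steric competition
    between factor X and IgM; and computes nonbonded interaction energies
    (electrostatic plus van der Waals) with chain, domain, and residue-pair
    decomposition, including a fixed-base steepest-descent relaxation of
    vertex models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
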