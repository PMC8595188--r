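Package: canaflow
Title: Fluid-Structure Interaction of an Osteocyte Process in a Canaliculus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interstitial fluid flow through the pericellular matrix
    of a bone canaliculus and the resulting deformation of the osteocyte
    process membrane. Flow is modeled by the Brinkman equation and solved with
    a lattice Boltzmann method; the process membrane is a Skalak hyperelastic
    membrane discretized into triangular finite elements; tethering elements
    (perlecan-like fibers) are tension-only linear springs connecting the
    membrane to the canalicular wall; fluid and structure are coupled by the
    immersed boundary method. Includes a synthetic generator for irregular
    process/canaliculus geometries, closed-form flow validation cases, and
    post-processing of membrane strain concentration near tether attachments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
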