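Package: lbbbsim
Title: Segmental Electromechanical Heart Model for Left Bundle Branch Block
    Strain Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop cardiac electromechanical simulator built from four
    coupled sub-models: a cellular-automata conduction system (26 automata with
    SDD/UDP/ARP/RRP phases and a synthesized ECG), Gaussian-driven time-varying
    elastance atria, a multi-segment representation of the left (16 AHA
    segments) and right (3 segments) ventricular walls with active/passive
    tension and hydraulic piston coupling, and a lumped-parameter systemic and
    pulmonary circulation with perfect-diode valves. Includes longitudinal
    strain analysis for left bundle branch block (septal flash, septal rebound
    stretch), deterministic one-parameter-at-a-time personalization of
    per-segment contractility and activation delay against observed wall strain
    curves, synthetic patient fixtures, and a fuzzy c-means module for late
    gadolinium enhancement scar transmurality mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    igraph,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
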