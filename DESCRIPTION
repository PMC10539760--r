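Package: ligandconf
Title: Free-Ligand Conformational Dynamics from NMR and Torsional Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing free-ligand conformational preferences
    and rotational dynamics of small molecules in solution. Simulates two-site
    chemical-exchange NMR lineshapes from slow exchange through coalescence,
    fits first-order exchange rates from selective-EXSY build-up curves and
    converts them to rotational barriers via Arrhenius and Eyring relations,
    samples torsional potentials with a replica-exchange Metropolis sampler
    (with histogram, free-energy, radial-time and ergodicity reports), clusters
    conformer ensembles to diverse representatives, fits simplex-constrained
    conformer populations against experimental shifts, couplings and
    NOE-derived distances, and parses printed proton shift lists for rotamer
    integral accounting. A synthetic-data module generates every input with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
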