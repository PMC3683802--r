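Package: capsidsim
Title: Coarse-Grained Simulation of Virus Capsid Assembly Around Nucleic Acids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained model of icosahedral virus capsid assembly
    around linear polyelectrolytes and base-paired nucleic acids. Rigid
    pentameric subunits carrying flexible, positively charged arginine-rich
    motif (ARM) tails interact with anionic cargo through screened
    Debye-Hueckel electrostatics and short-range excluded volume. The
    package provides builders for subunits, assembled dodecahedral capsids
    and virus-specific parameterizations; a generator and analyzer for
    nucleic-acid secondary structures with tunable maximum ladder distance
    (MLD) and junction statistics; the full pair/bond/angle force field
    with analytic forces; overdamped Brownian dynamics for mixed
    rigid-body plus bead systems with replica exchange and a semipermeable
    subunit mode; Monte Carlo polymer sampling; equilibrium estimators
    (Widom chain-increment chemical potentials, optimal packaged length,
    encapsidation and subunit dimerization free energies); and structural
    analyses (assembly outcome classification, bridging segments,
    radial/angular densities).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
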