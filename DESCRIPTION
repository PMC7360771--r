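Package: nxcr
Title: Machine-Learned Additive Exchange-Correlation Functionals from
    Atom-Centered Density Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing machine-learned additive
    corrections to exchange-correlation density functionals. Electron
    densities on real-space grids are projected onto orthonormal
    atom-centered radial x spherical-harmonic bases, reduced to
    rotation/reflection-invariant power-spectrum features, and mapped to
    energies by permutation-invariant per-species (Behler-Parrinello)
    neural networks. The functional derivative of the learned energy is
    assembled analytically as a linear combination of the basis functions,
    so the correction can drive self-consistent field calculations. The
    package includes delta-learning against reference energies with
    variance filtering, feature scaling and principal-component truncation,
    k-fold cross-validation, iterative freeze-and-grow training against a
    built-in three-dimensional toy self-consistent solver, a deterministic
    synthetic-data generator with a known analytic target functional,
    Gaussian cube and XYZ readers/writers, and density-moment diagnostics
    (dipole, traceless quadrupole, second radial moment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'system.R'
    'constants.R'
    'harmonics.R'
    'grid.R'
    'radial.R'
    'projector.R'
    'symmetrizer.R'
    'network.R'
    'model.R'
    'scf.R'
    'training.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'moments.R'
    'nxcr-package.R'
    'show-methods.R'
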