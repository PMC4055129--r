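Package: qsarforge
Title: Ligand-Based 2D/3D-QSAR Modelling for Folate-Pathway Inhibitor Discovery
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable quantitative structure-activity relationship (QSAR)
    toolkit for nominating small-molecule inhibitors of dihydrofolate
    reductase (DHFR) and thymidylate synthase (TS). Provides molecule input
    (SMILES/SDF) with seeded 3D embedding, Gasteiger-Marsili partial charges
    and Shrake-Rupley solvent-accessible surface areas; eleven named
    topological, charged-partial-surface-area and shadow descriptors;
    genetic function approximation (GFA) descriptor-subset selection scored
    by the Friedman lack-of-fit criterion; three 2D-QSAR regressors
    (multiple linear regression, epsilon-SVR with a Gaussian kernel, and a
    Bayesian-network category regression); CoMFA/CoMSIA-style molecular
    field generation with NIPALS partial least squares, leave-one-out q2
    and field-fraction reporting; and an ADMET-level candidate filtering
    and ranking stage. Curated activity, docking-score and ADMET tables for
    a published DHFR inhibitor series ship as plain-text fixtures, together
    with seeded synthetic-data generators for every model class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    ChemmineOB,
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
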