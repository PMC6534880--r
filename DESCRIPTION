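Package: smilesrl
Title: De Novo Molecule Generation with Recurrent SMILES Networks and
    Exploration-Regularized Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates candidate small molecules for a protein target by
    training a recurrent SMILES language model (embedding plus stacked
    gated recurrent units) and fine-tuning it with a policy-gradient
    reinforcement-learning loop whose reward is the activity probability
    of a QSAR classifier on ECFP6 fingerprints.  During reinforcement
    learning a frozen copy of the generator (the exploration network)
    stochastically overrides token selection at a configurable rate,
    which preserves the chemical diversity of the generated library.
    Includes dataset curation rules for pChEMBL activity tables, four
    QSAR algorithms (random forest, support-vector machine, naive Bayes,
    deep neural network), Tanimoto internal-diversity and substructure
    metrics, chemical-space projections, scaffold-space cluster
    comparison, and a synthetic fragment-grammar fixture generator so
    the whole pipeline is testable without external databases.
    Cheminformatics primitives (SMILES parsing, fingerprints, scaffolds)
    and the scikit-learn estimators are delegated to a bundled Python
    worker (RDKit, scikit-learn) spoken to over a local socket.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: Python (>= 3.8) with rdkit, scikit-learn, numpy,
    joblib available on the PATH as 'python'
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
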