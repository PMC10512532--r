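Package: pepstack
Title: Stacked Ensemble Prediction of Peptide Bioactivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Trains and applies stacked ensembles for binary peptide
    bioactivity classification (e.g. tyrosinase inhibitory peptides).
    Peptides are encoded with ten descriptor families: six sequence-based
    encoders (amino acid and dipeptide composition, dipeptide deviation
    from expected mean, pseudo and amphiphilic pseudo amino acid
    composition, physicochemical property means) and four keyed
    substructure fingerprints computed on peptide SMILES built from
    residue templates. A zoo of thirteen learning algorithms is
    grid-tuned by cross-validated Matthews correlation coefficient;
    out-of-fold predicted confidences of every (encoder, algorithm)
    baseline form a probabilistic feature vector which a genetic
    algorithm prunes before a partial-least-squares meta-classifier is
    fitted. Includes a synthetic peptide data generator, an evaluation
    harness (ACC, BACC, Sn, Sp, MCC, AUC) and a virtual-screening
    ranking workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    ChemmineOB,
    class,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    ranger,
    rpart,
    xgboost
Suggests:
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
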