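Package: endostrat
Title: Stratification of Multimorbid Patients into Endotypes from ICD-10 Diagnoses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify multimorbid patients into endotypes from
    lifetime ICD-10 diagnosis records. Diagnoses are mapped to the 17
    Charlson broad disease classes (Quan 2005 ICD-10 coding) and the
    Charlson Comorbidity Index; multimorbid patients (two or more classes)
    are embedded by multiple correspondence analysis of the binary disease
    indicator matrix, rotated with a fixed 2x2 matrix and partitioned into
    five clusters by x-axis cut-offs. Cluster assignments are validated
    with a CART decision tree (80/20 split, accuracy and per-cluster
    Jaccard similarity) and characterized by demographics, per-cluster
    disease prevalence, pairwise co-occurrence and exportable
    disease-disease interaction networks. A synthetic cohort generator
    emulating a five-endotype mixture makes every stage testable without
    access to restricted electronic health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
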