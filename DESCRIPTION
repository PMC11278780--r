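Package: chemotypeR
Title: Chemotype Prediction for Grass Endophytes from Alkaloid
    Biosynthesis Gene Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the alkaloid chemotype of Epichloe fungal endophyte
    strains from PCR presence/absence profiles of alkaloid-biosynthesis
    genes.  Declarative dependency models of the ergot-alkaloid (EAS),
    indole-diterpene (IDT/LTM), loline (LOL) and peramine (ppzA) pathways
    are evaluated by boolean reachability to give the set of producible
    metabolites per strain, from which mating type, peramine allele,
    cluster pattern codes, chemotype type and a livestock-safety category
    are derived.  Includes readers and writers for strain marker tables
    and field-survey count tables, infection-frequency summaries, and a
    seeded simulator of marker profiles with known ground-truth chemotypes
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
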