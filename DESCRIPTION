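Package: molekaryo
Title: Molecular Karyotyping and Parent-of-Origin Analysis of Androgenetic
    Hydatidiform Moles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for molecular karyotyping of complete hydatidiform moles
    from duo SNP-array data (mole villous tissue plus maternal blood).
    Implements STR-based conceptus classification (androgenetic monospermic
    versus dispermic versus biparental), per-chromosome copy-number calling
    from B-allele-frequency band structure and log R ratio shifts, and the
    selected-BAF procedure that restricts mole BAF to loci where the mother
    is homozygous AA and reads loss of the BAF~1 band as evidence of a
    maternal homolog. Includes a seeded simulator of parental genomes,
    meiosis with Poisson recombination, molar conceptus constitutions
    (monospermic, dispermic, triploid, aneuploid, biparental disomies) and
    rendered SNP-array and STR tables, plus cohort-level aggregation with
    Fisher's exact testing of aneuploidy and neoplasia rates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
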