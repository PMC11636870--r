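Package: revokedb
Title: Searchable Symmetric Encryption with Instant ID-Based Deletion for
    Genomic Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dynamic searchable symmetric encryption for genomic cohort
    databases with consent revocation built in. Records (SNP genotypes,
    phenotypes, gender, ethnicity) are encoded as keyword sets and stored
    on an untrusted server as an encrypted inverted index; keyword search
    uses trapdoor-permutation counter chains, and all data of one data
    owner can be physically and instantly deleted with a single
    constant-size token built from the owner's identifier. Includes a
    plaintext oracle, operation-count and transcript-shape instrumentation,
    a synthetic cohort generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: OpenSSL >= 3.0 (libcrypto)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
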