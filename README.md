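# revokedb

Dynamic searchable symmetric encryption (DSSE) for genomic cohort
databases, with consent revocation built into the cryptography: keyword
search over encrypted records on an untrusted server, and **instant,
physical, non-interactive deletion of all data belonging to one data
owner with a single constant-size token**.

## Who this is for

Data stewards (gene trustees, biobanks, medical institutions) who must
host searchable genomic data — SNP genotypes, phenotypes, demographic
attributes — on infrastructure they do not trust, while honouring
GDPR-style erasure: when a participant withdraws consent, every trace of
their records must be removed from the server *immediately*, not flagged
or deferred to a later cleanup.

## The construction in brief

Records are encoded as keyword sets (`snp:rs4988235=CT`, `pheno:...`,
`gender:...`, `eth:...`), each keyword linked to the owner's ID. The
server holds an encrypted inverted index in two maps:

* **iset**: index label ℓ → encrypted owner ID, with
  ℓ = H(g^(tag_w · (ST_c mod p))) computed in a prime-order subgroup of a
  safe-prime group (DDH-hard), where tag_w = F_p(K_T, w) is a keyword tag
  and ST_c is the keyword's *counter chain* state — advanced by the
  trustee with the secret key of an RSA trapdoor permutation
  (ST_c = π⁻¹(ST_{c−1})), walkable backwards by anyone with the public
  key.
* **fset**: owner locator F(K_S, ID) → deletion deltas
  Δ = g^(tag_w · (ST_c mod p) / e_ID), one per indexed pair, with
  e_ID = F_p(K_2, ID).

Search on w sends (tag_w, ST_c, c): the server re-derives the c labels by
walking the chain with π_PK and returns the hits; owners deleted in the
meantime are simply absent labels. Deletion of one owner sends the pair
(F(K_S, ID), e_ID) — two PRF outputs, the same size whether the owner
has 1 or 1000 keywords. Since Δ^(e_ID) = g^(tag_w · (ST_c mod p)), the
server recomputes exactly the owner's index labels and physically removes
every one of them, plus the delta list itself.

A separation of duties keeps a compromised query front-end harmless: the
*vetter* receives only the search-side keys (K_T, K_1, trapdoor public
key) and can neither insert nor forge deletion tokens.

Cryptographic kernels (BIGNUM arithmetic, safe-prime search, AES-128-CMAC
and HMAC-SHA-512 PRFs, AES-128-GCM, SHA-256) are OpenSSL `libcrypto`
behind a small Rcpp layer; the scheme logic is R.

## Worked example

```r
library(revokedb)

sys    <- trustee_setup(group = group_params("builtin-512"),
                        rsa_bits = 1024, seed = 7)
vetter <- export_vetter_keys(sys$keys, sys$state)
ctx    <- server_context(sys$keys$group, sys$keys$trapdoor)

cohort  <- generate_synthetic_cohort(n_owners = 12, n_snps = 6, seed = 1)
batch   <- lapply(cohort, encode_record)
payload <- build_add_batch(sys$keys, sys$state, batch, rng_new(2))
payload
#> add payload: 12 owner(s), 136 entries, 19368 bytes on the wire
apply_add(sys$egdb, payload)

w <- batch[[1]]$keywords[1]          # "snp:rs1001709=CC"
decrypt_results(vetter, w,
                execute_search(sys$egdb, ctx, build_search_token(vetter, w)))
#> [1] "PGP0001" "PGP0002" "PGP0005" "PGP0007" "PGP0008"

token <- build_delete_token(sys$keys, batch[[1]]$id, sys$state)
length(delete_token_wire(token))     # constant-size revocation token
#> [1] 80
apply_delete(sys$egdb, ctx, token)   # entries physically removed
#> [1] 12

decrypt_results(vetter, w,
                execute_search(sys$egdb, ctx, build_search_token(vetter, w)))
#> [1] "PGP0002" "PGP0005" "PGP0007" "PGP0008"
```

The 136 entries are the cohort's (ID, keyword) pairs; the 19368-byte
payload is exactly `Σ_owners (16 + x·(45 + 64 + 32))` at the 512-bit test
parameters (locator + per-keyword ciphertext, delta, label). After the
revocation, owner `PGP0001` is gone from every search and — as
`egdb_serialize()` confirms — from every byte of the server state, at the
cost of one 80-byte message regardless of keyword count.

A command-line driver (`inst/cli/revokedb`) exposes
`setup / add / delete / search / gen-cohort / gen-workload / replay /
stats` over serialized state; see `?run_cli`.

The methods vignette
(`vignettes/consent-revocable-search.Rmd`) documents the construction,
parameter choices, leakage shape, synthetic-data design and limitations.

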