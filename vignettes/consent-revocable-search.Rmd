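---
title: "Searchable encryption with instant ID-based deletion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchable encryption with instant ID-based deletion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revokedb)
```

## The problem

Genomic cohorts are increasingly hosted on untrusted infrastructure. Two
requirements collide there: researchers need keyword search over the
records (does any participant carry genotype `AG` at rs4988235? which
participants have phenotype X?), and participants have the right to
withdraw consent, which under GDPR-style regulation means their data must
be *erased immediately* — not flagged as deleted, not cleaned up at the
next search, but physically gone.

Dynamic searchable symmetric encryption (DSSE) solves the first
requirement: the server stores an encrypted inverted index and answers
keyword queries given a per-query token, learning neither keywords nor
record contents. Classical DSSE, however, updates per *(keyword, ID)*
pair: deleting one participant who carries `x` keywords requires `x`
deletion tokens, and many schemes only mark entries deleted. This package
implements a DSSE construction whose unit of deletion is the *data
owner*: one constant-size token physically removes every entry of one
owner, instantly and non-interactively.

## Entities and trust model

* **Trustee** (data provider): trusted; holds all keys; encrypts and
  inserts records, issues deletion tokens on consent revocation.
* **Vetter** (query front-end): trusted for search only; receives the
  search-side key subset (`kt`, `k1`, group parameters, trapdoor *public*
  key) and the shared keyword-state map. It can neither insert nor delete:
  it lacks the trapdoor secret key, the locator key `ks` and the deletion
  exponent key `k2`. This privilege separation is enforced by construction
  in `export_vetter_keys()` and by interface on the server operations,
  which accept only a `server_context()` holding public material.
* **Server**: honest-but-curious. It stores two structures: `fset`
  (owner locator → list of deletion deltas) and `iset` (index label →
  encrypted owner ID), and evaluates tokens faithfully while trying to
  learn from what it sees.

## The construction

Fix a Schnorr group: a safe prime `q = 2p + 1` and a generator `g` of the
order-`p` subgroup (quadratic residues mod `q`), in which decisional
Diffie–Hellman is assumed hard. Fix an RSA trapdoor permutation `pi` with
public key `PK` and secret key `SK`. Two PRFs drive derivation:
AES-128-CMAC (`prf_bits`, 128-bit outputs) and HMAC-SHA-512 reduced into
`[1, p-1]` (`prf_exponent`).

Per keyword `w` the trustee maintains a *counter chain*: a random anchor
`ST_0` in the RSA domain and states `ST_c = pi^{-1}(ST_{c-1})`, one
inversion per insertion of `w`. Only the trustee can extend the chain
(that needs `SK`); anyone holding `PK` can walk it back towards `ST_0`.
The shared keyword-state map **W** records the current `(ST_c, c)` per
keyword.

Inserting owner `ID` with keyword set `W_ID` emits, per pair `(ID, w)`,
with `s = ST_c mod p`, `tag_w = F_p(kt, w)` and `e_ID = F_p(k2, ID)`:

* index label `l = H(g^{tag_w * s})` — the `iset` key;
* deletion delta `Delta = g^{tag_w * s / e_ID}` — stored under the
  owner's locator `L_ID = F(ks, ID)` in `fset`;
* encrypted ID `ID' = SE.Enc(K_w, ID)` with `K_w = F(k1, w)` — the
  `iset` value (AES-128-GCM, randomized, fixed width).

**Search** on `w`: the vetter sends `(tag_w, ST_c, c)`. The server
computes `l_i = H(g^{tag_w * (ST_i mod p)})` for `i = c..1`, stepping
`ST_{i-1} = pi_{PK}(ST_i)`, and returns the `iset` hits. Labels absent
from the index are slots whose owner was deleted; the walk silently skips
them. Fresh insertions advance the chain past any state older tokens
reach, which is the mechanism behind forward privacy at the ID level.

**Deletion** of owner `ID`: the token is `(L_ID, e_ID)`, two PRF outputs,
the same bytes no matter how many keywords the owner has. The server
raises each stored `Delta` to `e_ID`: `Delta^{e_ID} = g^{tag_w * s}`,
recomputes the label, and removes the entry — the *construction
identity* that makes one token erase everything. Both `fset` and `iset`
entries are physically removed; `egdb_serialize()` after `apply_delete()`
contains no byte of the owner's locator, deltas, labels or ciphertexts.

Blinding the deltas by `1/e_ID` is what keeps the stored `fset` unlinkable
to `iset` labels until (and unless) the owner's own deletion token is
revealed; its hardness rests on DDH in the chosen group.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| group modulus `q` | 2048 bit | safe prime; deltas/labels live in its order-`p` subgroup |
| RSA modulus `N` | 2048 bit | trapdoor permutation domain (counter chains) |
| `id_width` | 16 bytes | fixed plaintext width of owner IDs before encryption |
| `lF` | 16 bytes | PRF/locator width (CMAC output) |
| `lh` | 32 bytes | index-label width (SHA-256) |
| `lD` | `ceil(|q|/8)` | serialized group-element (delta) width |
| `lE` | `id_width + 29` | ciphertext width: 12 nonce + 1 length + ID + 16 tag |

An add payload for `r` owners with `x` keywords each is exactly
`r (lF + x (lE + lD + lh))` bytes on the wire (`payload_wire()` is the
byte-accounting ground truth, and the server's storage follows the same
formula); the deletion token is `lF + ceil(|p|/8)` bytes — 80 bytes at
the 512-bit test size — constant in `x`. Analytical accountings of this
scheme class often write the deletion communication as `2 lF`; here the
second component is wider because the deletion exponent lives in `Z_p`
rather than in the PRF range. That changes nothing about the
constant-size contract, which is what the tests assert.

The test suite and the acceptance script run at *test-size* parameters —
512-bit `q`, 1024-bit RSA — chosen so a full 10-trace, 500-operation
oracle-equivalence study finishes in about a minute while exercising
arithmetic on genuinely multi-precision values. These sizes are not
secure; `group_params("builtin-2048")` plus `rsa_bits = 2048` are the
intended deployment sizes. The two builtin groups are pre-generated
public parameter sets (seeds 512001 and 2048001 of the package's own
seeded safe-prime search), in the same spirit as the standardized MODP
groups; a unit test re-verifies primality, `q = 2p + 1` and the generator
order on every run.

## Operation-count contracts

Costs are stated in primitive operations, not wall-clock time, because
only the former reproduce across hardware. Every primitive ticks a
counter (`op_counts()`), and `predict_op_counts()` gives the closed
forms: adding one owner with `x` keywords costs the client `2 + 2x` PRFs,
`2x` exponentiations, `x` hashes, `x` trapdoor inversions, `x`
encryptions; deletion costs 2 client PRFs and `x` server exponentiations
plus `x` hashes; search at counter `c` costs 1 client PRF and `c`
exponentiations, `c` hashes, `c - 1` trapdoor forward steps. The tests
assert integer equality between measured and predicted counts.

Note the search walk visits all `c` chain slots, including slots whose
owners were deleted — the per-*match* cost quoted for such schemes is a
lower bound that coincides with the walk cost only when nothing was
deleted. The instrumentation reports the walk length; the skipped-slot
behaviour is itself part of the design (deleted entries leave no trace
except an absent label).

## What the server observes

The transcript profiler (`profile_transcript()`) reduces each message to
direction, type, byte length, and — for insertions — the multiset of
per-owner entry counts. Batches are shuffled (owners, and entries within
an owner) before transmission, so two insertions with the same count
multiset but disjoint contents are byte-identically shaped; the tests
assert profile equality in that case and inequality when shapes differ.
This realizes the intended update leakage: number of owners inserted and
number of keywords per owner, nothing content-bearing. Search reveals the
repetition pattern of tokens and result counts; deletion reveals, for the
deleted owner only, the correlation between its deltas and index labels
at the moment of deletion. No formal simulator is implemented — the
package instruments observable transcript shape, not proofs.

## Synthetic cohorts

`generate_synthetic_cohort()` emulates the shape of a small genotyped
cohort: a biallelic SNP panel (per-site allele pair and minor-allele
frequency), per-owner genotypes among the three genotype states,
independent phenotype carriage at a configured prevalence (default 0.3
over a 10-label vocabulary), gender and ethnicity from small
vocabularies. Defaults give ~25 keywords per owner (20 SNPs + ~3
phenotypes + 2 categorical), and 69 owners mirrors the public
genome-project cohort size this class of scheme is typically evaluated
on. What the generator does *not* emulate: linkage disequilibrium between
sites, realistic allele-frequency spectra, phenotype–genotype
correlation, multi-allelic sites, and missingness patterns. Passing tests
therefore certify protocol correctness and leakage shape on realistically
*sized and shaped* inputs, not statistical fidelity to real genomes —
which the cryptographic layer is oblivious to anyway, since every keyword
is an opaque string by the time it reaches the index.

Keyword syntax is implementation-defined (no standard exists at this
layer): prefix-tagged canonical strings `snp:rs123=AG` (alleles sorted,
genotypes unordered), `pheno:...`, `gender:...`, `eth:...`, so categories
cannot collide.

## Numerical and degenerate-case choices

* **`ST mod p = 0`** would make a chain state index nothing
  (probability ~`1/p`). At a chain's first insertion the anchor is simply
  redrawn; deeper in a chain the trustee raises an
  `rdb_degenerate_state` error. At 512-bit `p` the event is unreachable
  in practice; the toy group (`q = 23`) exists precisely to exercise such
  paths.
* **Label collisions** in the index (probability ≤ `|iset|^2 2^{-256}`)
  are fatal by design (`rdb_collision`), not silently merged.
* **Exponent bias**: HMAC-SHA-512 reduced mod `p - 1` then shifted to
  `[1, p-1]` has bias at most `2^{-(512 - |p|)}` — negligible for `p` up
  to 256 bits and still immaterial at the test size's 511-bit `p`; a
  uniformity test on the toy group checks the mapping empirically.
* **Authentication failures** on result decryption are skipped with a
  warning rather than aborting: a single corrupt entry should not mask
  the rest of a result set.
* **Fixed widths everywhere**: IDs are length-prefixed and zero-padded to
  `id_width` before encryption; group elements and exponents serialize
  big-endian at fixed width, so message sizes depend only on counts.
* **Seeded mode** (an explicit integer seed) replaces the OS CSPRNG with
  a SHA-256 counter-mode generator for reproducible keys, cohorts and
  transcripts. It exists for testing and simulation and is documented as
  insecure.

## Open design points, resolved

* **Key-role assignment**: the four PRF keys map to locator (`ks`),
  per-keyword encryption (`k1`), keyword tag (`kt`), deletion exponent
  (`k2`) — the minimal assignment under which the vetter needs exactly
  `(kt, k1)` and the deletion token needs exactly `(ks, k2)`.
* **First-insertion convention**: `ST_0` is never an insertion state; the
  first insertion uses `ST_1 = pi^{-1}(ST_0)` at counter 1, so "counter =
  number of slots ever created" is exact and the search walk has a
  well-defined floor.
* **Who deletes**: the trustee issues deletion tokens (it alone holds
  `ks`, `k2`); the vetter remains search-only.
* **Per-pair encryption**: each `(ID, w)` slot carries its own ciphertext
  under `K_w` — necessary for per-keyword decryptability, at `x`
  encryptions per owner rather than one.
* **State synchronisation**: trustee and vetter share one keyword-state
  map in-process; in CLI mode the state file is the snapshot and
  staleness surfaces as counter mismatch, never silent wrong answers.
* **Search token content**: the token carries `tag_w` itself (not
  `g^{tag_w}`), so the server performs exactly one exponentiation per
  chain slot.

## Worked example

```{r example}
sys <- trustee_setup(group = group_params("builtin-512"), rsa_bits = 1024,
                     seed = 7)
vetter <- export_vetter_keys(sys$keys, sys$state)
ctx <- server_context(sys$keys$group, sys$keys$trapdoor)

cohort <- generate_synthetic_cohort(n_owners = 12, n_snps = 6, seed = 1)
batch <- lapply(cohort, encode_record)
payload <- build_add_batch(sys$keys, sys$state, batch, rng_new(2))
apply_add(sys$egdb, payload)

w <- batch[[1]]$keywords[1]
hits <- decrypt_results(vetter, w,
                        execute_search(sys$egdb, ctx,
                                       build_search_token(vetter, w)))
hits

token <- build_delete_token(sys$keys, batch[[1]]$id, sys$state)
length(delete_token_wire(token))   # constant, whatever the keyword count
apply_delete(sys$egdb, ctx, token) # number of entries physically removed

decrypt_results(vetter, w,
                execute_search(sys$egdb, ctx, build_search_token(vetter, w)))
```

## Limitations

* Arithmetic is not constant-time; timing side channels are out of scope,
  as are hardware key stores and malicious-server defences.
* Security argument territory (simulators, formal forward/backward
  privacy games, hardness reductions) is not implemented; only the
  mechanical properties those arguments rely on are tested (permutation
  round trips, construction identity, transcript shape).
* The group backend is the classic safe-prime subgroup; an elliptic-curve
  backend would shrink `lD` roughly tenfold at 128-bit security but is
  not provided.
* The storage backend is in-memory maps with a JSONL dump; swapping in an
  external key-value store means implementing the same four-verb
  interface, not changing the scheme.
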