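#' Prime-order group setup
#'
#' The deletion deltas and index labels live in a cyclic group of prime
#' order `p`, instantiated as the order-`p` subgroup of quadratic residues
#' of the multiplicative group modulo a safe prime `q = 2p + 1` (a Schnorr
#' group), the simplest group in which the decisional Diffie-Hellman
#' problem is believed hard. Group elements are hex-encoded integers in
#' `[1, q-1]` satisfying `e^p = 1 (mod q)`; exponents are integers in
#' `Z_p`.
#'
#' `group_setup()` searches for fresh parameters; with a seed the search is
#' deterministic. `group_params()` returns pre-generated parameter sets
#' shipped with the package (group parameters are public, so sharing them
#' across deployments is standard practice, as with the RFC 3526 MODP
#' groups): `"builtin-512"` and `"builtin-2048"` (bit length of `q`), plus
#' the tiny `"toy"` group `q = 23, p = 11, g = 2` for worked examples and
#' unit arithmetic only -- its 11 elements admit only 11 distinct index
#' labels, so it cannot back a real index.
#'
#' @param bits Bit length of the modulus `q` (>= 16; 2048 for real use).
#' @param seed Optional integer seed for a reproducible (insecure) search.
#' @param name Name of a built-in parameter set.
#' @return An object of class `rdb_group`: list with hex fields `p`
#'   (subgroup order), `q` (modulus), `g` (generator), plus `bits` and
#'   `elem_bytes`/`exp_bytes`, the fixed serialization widths of group
#'   elements and exponents.
#' @examples
#' g <- group_params("toy")
#' group_exp(g, g$g, "b")   # g^p = 1
#' @export
group_setup <- function(bits = 2048, seed = NULL) {
  stopifnot(bits >= 16)
  rng <- rng_new(seed)
  nb <- ceiling((bits - 1) / 8)
  start <- rng_bytes(rng, nb)
  # force exact bit length of p = bits - 1 so q = 2p + 1 has `bits` bits
  excess <- 8 * nb - (bits - 1)
  start[1] <- as.raw(bitwOr(bitwAnd(as.integer(start[1]),
                                    bitwShiftR(255L, excess)),
                            bitwShiftR(128L, excess)))
  p <- cx_next_safe_prime(raw_to_hex(start))
  if (cx_nbits(p) != bits - 1)
    rdb_stop("prime search left the requested bit range", "setup")
  q <- cx_add(cx_mul("2", p), "1")
  repeat {
    h <- rng_bn(rng, "2", cx_sub(q, "2"))
    g <- bn_mod_exp(h, "2", q)  # square => order p (or 1)
    if (g != "1") break
  }
  new_group(p = p, q = q, g = g, bits = bits)
}

#' @rdname group_setup
#' @export
group_params <- function(name = c("builtin-2048", "builtin-512", "toy")) {
  name <- match.arg(name)
  gp <- .builtin_groups[[name]]
  new_group(p = gp$p, q = gp$q, g = gp$g, bits = cx_nbits(gp$q))
}

new_group <- function(p, q, g, bits) {
  structure(list(p = hex_canon(p), q = hex_canon(q), g = hex_canon(g),
                 bits = as.integer(bits),
                 elem_bytes = as.integer(ceiling(bits / 8)),
                 exp_bytes = as.integer(ceiling((bits - 1) / 8))),
            class = "rdb_group")
}

#' @export
print.rdb_group <- function(x, ...) {
  cat(sprintf("Schnorr group: %d-bit safe-prime modulus, %d-byte elements\n",
              x$bits, x$elem_bytes))
  invisible(x)
}

#' Group exponentiation
#'
#' Computes `base^a mod q`. The subgroup is closed under exponentiation,
#' so the result is again a group element. Counts one `group_exp`
#' primitive operation.
#'
#' @param group An `rdb_group`.
#' @param base Group element (hex).
#' @param a Exponent (hex, reduced mod `p` by the group law).
#' @return Group element (hex).
#' @export
group_exp <- function(group, base, a) {
  op_tick("group_exp")
  bn_mod_exp(base, bn_mod(a, group$p), group$q)
}

#' Inverse of an exponent modulo the group order
#'
#' Deletion deltas are formed as `e^(1/e_ID)`, so the trustee needs
#' `a^(-1) mod p` for nonzero exponents.
#'
#' @inheritParams group_exp
#' @param a Nonzero exponent (hex).
#' @export
exponent_inverse <- function(group, a) {
  if (bn_mod(a, group$p) == "0")
    rdb_stop("exponent is 0 mod p and has no inverse", "degenerate_exponent")
  bn_mod_inv(a, group$p)
}

#' Full subgroup membership test (`e^p = 1 mod q` and `1 <= e < q`).
#' @inheritParams group_exp
#' @param e Candidate element (hex).
#' @export
is_group_element <- function(group, e) {
  bn_cmp(e, "0") > 0 && bn_cmp(e, group$q) < 0 &&
    bn_mod_exp(e, group$p, group$q) == "1"
}

#' Hash a group element to an index label
#'
#' The random-oracle hash `H` mapping group elements to the fixed-width
#' index labels of the encrypted index: SHA-256 over a domain-separation
#' tag byte followed by the element encoded big-endian at the group's
#' fixed element width, so the label depends only on the canonical
#' encoding. Counts one `hash` primitive operation.
#'
#' @inheritParams group_exp
#' @param e Group element (hex).
#' @return 32-byte label as a 64-character hex string.
#' @export
hash_to_index <- function(group, e) {
  if (bn_cmp(e, "0") <= 0 || bn_cmp(e, group$q) >= 0)
    rdb_stop("value outside the group element range", "invariant")
  op_tick("hash")
  raw_to_hex(cx_sha256(c(as.raw(1L), hex_to_raw_width(e, group$elem_bytes))))
}
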