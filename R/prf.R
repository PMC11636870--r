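#' Pseudorandom functions and symmetric encryption
#'
#' Two PRF families drive all key and tag derivation. `prf_bits` is
#' AES-128-CMAC over the length-prefixed input and returns 16 bytes: it
#' derives the server-side owner locator and the per-keyword encryption
#' key. `prf_exponent` is HMAC-SHA-512 interpreted as a big-endian integer
#' and mapped into `[1, p-1]`: it derives the keyword tag and the owner
#' deletion exponent. The 512-bit MAC width makes the `mod (p-1)` reduction
#' bias negligible for group orders up to 256 bits and small for the sizes
#' used here.
#'
#' `se_encrypt`/`se_decrypt` are randomized authenticated encryption
#' (AES-128-GCM) of fixed-width plaintexts: the owner ID is length-prefixed
#' and zero-padded to `width` bytes before encryption so every ciphertext
#' in the index has the same serialized size and result lengths leak
#' nothing beyond counts.
#'
#' @param key Raw 16-byte PRF/cipher key.
#' @param input Character scalar or raw vector.
#' @return `prf_bits`: raw 16 bytes. `prf_exponent`: hex exponent in
#'   `[1, p-1]`. `se_encrypt`: list with raw fields `nonce` (12 bytes) and
#'   `body` (`width + 17` bytes including the GCM tag). `se_decrypt`: the
#'   plaintext string, or `NULL` when authentication fails.
#' @examples
#' k <- as.raw(1:16)
#' identical(prf_bits(k, "rs123=AG"), prf_bits(k, "rs123=AG"))
#' @export
prf_bits <- function(key, input) {
  check_prf_key(key)
  op_tick("prf")
  cx_cmac_aes128(key, prf_input(input))
}

#' @rdname prf_bits
#' @param group An `rdb_group` fixing the exponent range.
#' @export
prf_exponent <- function(group, key, input) {
  check_prf_key(key)
  op_tick("prf")
  h <- cx_hmac_sha512(key, prf_input(input))
  hex_canon(cx_add(bn_mod(raw_to_hex(h), cx_sub(group$p, "1")), "1"))
}

# 4-byte big-endian length prefix removes input-extension ambiguity
prf_input <- function(input) {
  r <- if (is.raw(input)) input else utf8_raw(input)
  c(hex_to_raw_width(hex_canon(sprintf("%x", length(r))), 4), r)
}

check_prf_key <- function(key) {
  if (!is.raw(key) || length(key) != 16L)
    rdb_stop("PRF key must be a raw vector of 16 bytes", "config")
  invisible(TRUE)
}

#' @rdname prf_bits
#' @param m Plaintext string (an owner ID), at most `width` bytes.
#' @param width Fixed plaintext width in bytes.
#' @param rng Randomness source for the nonce.
#' @export
se_encrypt <- function(key, m, width = 16L, rng = NULL) {
  check_prf_key(key)
  if (is.null(rng)) rng <- rng_new()
  mr <- utf8_raw(m)
  if (length(mr) > width)
    rdb_stop(sprintf("plaintext exceeds the fixed width of %d bytes", width),
             "width")
  pt <- c(as.raw(length(mr)), mr, raw(width - length(mr)))
  nonce <- rng_bytes(rng, 12L)
  op_tick("se_encrypt")
  list(nonce = nonce, body = cx_gcm_seal(key, nonce, pt))
}

#' @rdname prf_bits
#' @param ct Ciphertext list as returned by `se_encrypt`.
#' @export
se_decrypt <- function(key, ct) {
  check_prf_key(key)
  op_tick("se_decrypt")
  pt <- cx_gcm_open(key, ct$nonce, ct$body)
  if (is.null(pt)) return(NULL)
  n <- as.integer(pt[1])
  if (n > length(pt) - 1L) return(NULL)
  rawToChar(pt[seq_len(n) + 1L])
}

# serialized ciphertext width: nonce + length byte + id width + GCM tag
se_ct_bytes <- function(id_width) 12L + 1L + as.integer(id_width) + 16L
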