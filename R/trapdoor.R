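#' RSA trapdoor permutation
#'
#' The per-keyword counter chain `ST_0 -> ST_1 -> ...` is generated by a
#' trapdoor permutation: anyone holding the public key can walk the chain
#' towards `ST_0` (`tp_forward`), but only the trustee's secret key walks
#' it away from `ST_0` (`tp_inverse`). Instantiated as textbook RSA over
#' `Z_N^*`: forward is `x^e mod N`, inverse is `x^d mod N`. The two maps
#' are mutually inverse bijections on the domain, which is the only
#' property the chain construction uses.
#'
#' @param bits RSA modulus bit length (>= 32; 2048 for real use; toy sizes
#'   are allowed for tests).
#' @param seed Optional integer seed for reproducible (insecure) key
#'   generation.
#' @param rng Optional `rdb_rng` overriding `seed`.
#' @return `tp_keygen()` returns an object of class `rdb_trapdoor` with hex
#'   fields `n`, `e` (public) and `d` (secret), and `bits`.
#' @examples
#' kp <- tp_keypair(n = "ca1", e = "11", d = "ac1")  # 3233, 17, 2753
#' tp_forward(kp, tp_inverse(kp, "2a"))              # "2a"
#' @export
tp_keygen <- function(bits = 2048, seed = NULL, rng = NULL) {
  stopifnot(bits >= 32, bits %% 2 == 0)
  if (is.null(rng)) rng <- rng_new(seed)
  half <- bits / 2
  e <- "10001"  # 65537
  gen_prime <- function() {
    nb <- ceiling(half / 8)
    repeat {
      start <- rng_bytes(rng, nb)
      excess <- 8 * nb - half
      # top two bits set so that N = p1*p2 has the full bit length
      top <- bitwOr(bitwAnd(as.integer(start[1]), bitwShiftR(255L, excess)),
                    bitwShiftR(192L, excess))
      start[1] <- as.raw(top)
      p <- cx_next_prime(raw_to_hex(start))
      if (cx_nbits(p) == half && cx_gcd(cx_sub(p, "1"), e) == "1") return(p)
    }
  }
  p1 <- gen_prime()
  repeat {
    p2 <- gen_prime()
    if (p2 != p1) break
  }
  n <- cx_mul(p1, p2)
  phi <- cx_mul(cx_sub(p1, "1"), cx_sub(p2, "1"))
  d <- bn_mod_inv(e, phi)
  tp_keypair(n = n, e = e, d = d)
}

#' @rdname tp_keygen
#' @param n,e,d RSA modulus, public exponent, private exponent (hex). `d`
#'   may be `NULL` for a public-only key.
#' @export
tp_keypair <- function(n, e, d = NULL) {
  structure(list(n = hex_canon(n), e = hex_canon(e),
                 d = if (!is.null(d)) hex_canon(d),
                 bits = cx_nbits(n)),
            class = "rdb_trapdoor")
}

#' @rdname tp_keygen
#' @param kp An `rdb_trapdoor` key (public part suffices for `tp_forward`).
#' @param x Domain element: hex integer in `[1, N-1]` coprime to `N`.
#' @export
tp_forward <- function(kp, x) {
  tp_check_domain(kp, x)
  op_tick("tp_forward")
  bn_mod_exp(x, kp$e, kp$n)
}

#' @rdname tp_keygen
#' @export
tp_inverse <- function(kp, x) {
  if (is.null(kp$d))
    rdb_stop("secret exponent absent: cannot invert the permutation",
             "missing_key")
  tp_check_domain(kp, x)
  op_tick("tp_inverse")
  bn_mod_exp(x, kp$d, kp$n)
}

tp_check_domain <- function(kp, x) {
  if (bn_cmp(x, "0") <= 0 || bn_cmp(x, kp$n) >= 0 || cx_gcd(x, kp$n) != "1")
    rdb_stop("value outside the permutation domain Z_N^*", "domain")
  invisible(TRUE)
}

#' @export
print.rdb_trapdoor <- function(x, ...) {
  cat(sprintf("RSA trapdoor permutation: %d-bit modulus (%s key)\n",
              x$bits, if (is.null(x$d)) "public" else "full"))
  invisible(x)
}
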