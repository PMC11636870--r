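#' Randomness sources
#'
#' All protocol randomness (key material, chain seeds, encryption nonces,
#' batch shuffling) flows through an `rdb_rng` object. The default source is
#' the operating system CSPRNG. A seeded source, built from a SHA-256
#' counter-mode generator, yields reproducible key material and transcripts
#' for tests and simulation studies; seeded mode is NOT suitable for
#' protecting real data and is documented as such.
#'
#' @param seed `NULL` for the OS generator, or a single integer for the
#'   deterministic test generator.
#' @return An object of class `rdb_rng`.
#' @examples
#' r <- rng_new(seed = 1)
#' identical(rng_bytes(r, 8), rng_bytes(rng_new(seed = 1), 8))
#' @export
rng_new <- function(seed = NULL) {
  e <- new.env(parent = emptyenv())
  if (is.null(seed)) {
    e$kind <- "os"
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    e$kind <- "drbg"
    e$key <- cx_sha256(c(utf8_raw("revokedb-drbg-v1:"),
                         utf8_raw(format(as.integer(seed)))))
    e$counter <- 0
    e$buf <- raw(0)
  }
  structure(e, class = "rdb_rng")
}

#' @rdname rng_new
#' @param rng An `rdb_rng` object.
#' @param n Number of bytes to draw.
#' @export
rng_bytes <- function(rng, n) {
  stopifnot(inherits(rng, "rdb_rng"), n >= 0)
  if (rng$kind == "os") return(cx_rand_bytes(as.integer(n)))
  while (length(rng$buf) < n) {
    ctr <- hex_to_raw_width(hex_canon(sprintf("%x", rng$counter)), 8)
    rng$counter <- rng$counter + 1
    rng$buf <- c(rng$buf, cx_sha256(c(rng$key, ctr)))
  }
  out <- rng$buf[seq_len(n)]
  rng$buf <- rng$buf[-seq_len(n)]
  out
}

# uniform integer in [1, n] by rejection sampling on 4-byte draws
rng_int <- function(rng, n) {
  stopifnot(n >= 1, n < 2^31)
  lim <- floor(2^32 / n) * n
  repeat {
    b <- as.integer(rng_bytes(rng, 4))
    v <- ((b[1] * 256 + b[2]) * 256 + b[3]) * 256 + b[4]
    if (v < lim) return(v %% n + 1)
  }
}

rng_shuffle <- function(rng, x) {
  n <- length(x)
  if (n <= 1L) return(x)
  for (i in n:2) {
    j <- rng_int(rng, i)
    tmp <- x[[i]]; x[[i]] <- x[[j]]; x[[j]] <- tmp
  }
  x
}

# uniform hex integer in [lo, hi] (inclusive), canonical hex bounds
rng_bn <- function(rng, lo, hi) {
  nbytes <- ceiling(cx_nbits(hi) / 8)
  repeat {
    v <- raw_to_hex(rng_bytes(rng, nbytes))
    if (bn_cmp(v, lo) >= 0 && bn_cmp(v, hi) <= 0) return(hex_canon(v))
  }
}
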