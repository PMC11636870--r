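# hex/raw plumbing and error conditions shared across modules

raw_to_hex <- function(x) {
  if (length(x) == 0L) return("")
  paste(sprintf("%02x", as.integer(x)), collapse = "")
}

hex_to_raw <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) return(raw(0))
  if (nchar(s) %% 2L == 1L) s <- paste0("0", s)
  n <- nchar(s) %/% 2L
  as.raw(strtoi(substring(s, 2L * seq_len(n) - 1L, 2L * seq_len(n)), 16L))
}

# canonical (no leading zeros, lowercase) hex of a big integer
hex_canon <- function(s) {
  s <- tolower(s)
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  if (s == "") "0" else s
}

# big-endian fixed-width byte encoding of a hex integer
hex_to_raw_width <- function(s, width) {
  r <- hex_to_raw(hex_canon(s))
  if (length(r) > width)
    rdb_stop(sprintf("integer does not fit in %d bytes", width), "width")
  c(raw(width - length(r)), r)
}

rdb_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c(paste0("rdb_", class), "rdb_error"),
                      call = call))
}

rdb_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("rdb_", class), "rdb_warning")))
}

utf8_raw <- function(s) charToRaw(enc2utf8(s))

# modular arithmetic wrappers over the OpenSSL BIGNUM kernel (hex in/out)
bn_mod_exp <- function(b, e, m) cx_mod_exp(b, e, m)
bn_mod_inv <- function(a, m) cx_mod_inv(a, m)
bn_mod     <- function(a, m) cx_mod(a, m)
bn_mod_mul <- function(a, b, m) cx_mod_mul(a, b, m)
bn_cmp     <- function(a, b) cx_cmp(a, b)
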