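# shared fixtures: tiny textbook parameters for arithmetic checks and a
# small-but-real parameter set for protocol tests

toy_group <- function() group_params("toy")

# textbook RSA: N = 3233 = 61 * 53, e = 17, d = 2753
toy_rsa <- function() tp_keypair(n = "ca1", e = "11", d = "ac1")

test_group <- function() group_params("builtin-512")

new_test_system <- function(seed = 42, rsa_bits = 512) {
  trustee_setup(group = test_group(), rsa_bits = rsa_bits, seed = seed)
}

# full protocol stack (trustee + vetter + server) in one call
new_test_stack <- function(seed = 42, rsa_bits = 512) {
  sys <- new_test_system(seed = seed, rsa_bits = rsa_bits)
  list(keys = sys$keys, state = sys$state, egdb = sys$egdb,
       vk = export_vetter_keys(sys$keys, sys$state),
       ctx = server_context(sys$keys$group, sys$keys$trapdoor))
}

# independent square-and-multiply oracle over plain doubles (moduli < 2^26)
pow_mod_oracle <- function(base, exp, mod) {
  r <- 1
  b <- base %% mod
  while (exp > 0) {
    if (exp %% 2 == 1) r <- (r * b) %% mod
    b <- (b * b) %% mod
    exp <- exp %/% 2
  }
  r
}

hex_int <- function(x) revokedb:::hex_canon(sprintf("%x", x))
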