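#' Build a search token
#'
#' The token for keyword `w` is the tag exponent `tag_w = F_p(kt, w)`
#' together with the keyword's current chain state `ST_c` and counter `c`
#' from the shared keyword-state map. A keyword that was never inserted
#' yields a token with counter 0 (the search is a defined no-op). The
#' token exposes no PRF key, and the server can walk the chain only
#' towards `ST_0`, never extend it.
#'
#' @param vk An `rdb_vetter_keys` bundle from [export_vetter_keys()].
#' @param w Keyword string.
#' @return An `rdb_search_token`: list with `tag` (hex), `st` (hex or
#'   `NULL`), `counter`.
#' @export
build_search_token <- function(vk, w) {
  tag <- prf_exponent(vk$group, vk$kt, w)
  ks <- vk$W$get(w)
  structure(list(tag = tag,
                 st = if (!is.null(ks)) ks$st,
                 counter = if (is.null(ks)) 0L else ks$counter),
            class = "rdb_search_token",
            exp_bytes = vk$group$exp_bytes,
            st_bytes = as.integer(ceiling(vk$pk$bits / 8)))
}

#' Decrypt a search result set
#'
#' Re-derives the per-keyword key `K_w = F(k1, w)` and decrypts every
#' returned ciphertext. A ciphertext failing authentication signals an
#' index collision or corruption; it is skipped with a warning rather than
#' aborting the whole result. The returned set is deduplicated (an owner
#' matches a keyword once even if duplicate slots exist).
#'
#' @inheritParams build_search_token
#' @param rset List of ciphertexts (`list(nonce, body)`) returned by
#'   [execute_search()] for the same keyword.
#' @return Sorted character vector of owner IDs.
#' @export
decrypt_results <- function(vk, w, rset) {
  key <- prf_bits(vk$k1, w)
  ids <- character(0)
  for (ct in rset) {
    id <- se_decrypt(key, ct)
    if (is.null(id)) {
      rdb_warn("result ciphertext failed authentication; skipped",
               "integrity")
      next
    }
    ids <- c(ids, id)
  }
  sort(unique(ids))
}
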