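#' Trustee setup: keys, client state, empty encrypted database
#'
#' The trustee (data provider) generates four independent PRF keys -- `ks`
#' (owner locator), `k1` (per-keyword encryption keys), `kt` (keyword tag
#' exponents), `k2` (owner deletion exponents) -- together with the
#' trapdoor-permutation key pair and the group parameters, and initializes
#' an empty keyword-state map and an empty encrypted database. The server
#' receives only the encrypted database plus public material; the vetter
#' receives the search-side subset of the keys (see
#' [export_vetter_keys()]).
#'
#' @param group An `rdb_group`, or `NULL` to generate one of `group_bits`.
#' @param group_bits,rsa_bits Parameter sizes used when generating.
#' @param id_width Fixed byte width owner IDs are padded to before
#'   encryption (bounds the printable ID length).
#' @param seed Optional integer seed for a reproducible (insecure) instance.
#' @return A list with components `keys` (class `rdb_keyset`), `state`
#'   (class `rdb_client_state`: keyword-state map plus the live-owner set)
#'   and `egdb` (an empty [egdb_new()] database).
#' @examples
#' sys <- trustee_setup(group = group_params("builtin-512"), rsa_bits = 512,
#'                      seed = 7)
#' sys$state$W$size()
#' @export
trustee_setup <- function(group = NULL, group_bits = 2048, rsa_bits = 2048,
                          id_width = 16L, seed = NULL) {
  rng <- rng_new(seed)
  if (is.null(group))
    group <- group_setup(group_bits, seed = if (!is.null(seed)) seed + 1L)
  keys <- structure(list(
    ks = rng_bytes(rng, 16L),
    k1 = rng_bytes(rng, 16L),
    kt = rng_bytes(rng, 16L),
    k2 = rng_bytes(rng, 16L),
    trapdoor = tp_keygen(rsa_bits, rng = rng),
    group = group,
    id_width = as.integer(id_width)
  ), class = "rdb_keyset")
  for (ab in list(c("ks", "k1"), c("ks", "kt"), c("ks", "k2"),
                  c("k1", "kt"), c("k1", "k2"), c("kt", "k2"))) {
    if (identical(keys[[ab[1]]], keys[[ab[2]]]))
      rdb_stop("PRF keys are not pairwise distinct", "setup")
  }
  list(keys = keys, state = client_state_new(), egdb = egdb_new())
}

#' @export
print.rdb_keyset <- function(x, ...) {
  cat(sprintf(
    "trustee key set: 4 PRF keys, %d-bit RSA trapdoor, %d-bit group\n",
    x$trapdoor$bits, x$group$bits))
  invisible(x)
}

# client state: keyword-state map W plus the set of live (undeleted) owners
client_state_new <- function() {
  W <- new.env(parent = emptyenv())
  live <- new.env(parent = emptyenv())
  st <- new.env(parent = emptyenv())
  st$W <- structure(
    list(get = function(w) get0(w, envir = W, inherits = FALSE),
         set = function(w, v) assign(w, v, envir = W),
         keys = function() ls(W, sorted = TRUE),
         size = function() length(ls(W))),
    class = "rdb_keyword_state_map")
  st$live <- live
  structure(st, class = "rdb_client_state")
}

#' @export
print.rdb_client_state <- function(x, ...) {
  cat(sprintf("client state: %d keyword chains, %d live owners\n",
              x$W$size(), length(ls(x$live))))
  invisible(x)
}

live_ids <- function(state) ls(state$live, sorted = TRUE)

#' Deterministic per-owner material
#'
#' Each owner ID maps to a server-side locator `L_ID = F(ks, ID)` (the key
#' of the delta store) and a deletion exponent `e_ID = F_p(k2, ID)`. Both
#' are deterministic, so the deletion token for an owner can be recomputed
#' at any time without per-owner client storage.
#'
#' @param keys An `rdb_keyset`.
#' @param id Owner ID string (non-empty, at most `id_width` bytes).
#' @return List with `locator` (hex, 16 bytes) and `exponent` (hex in
#'   `[1, p-1]`).
#' @export
derive_id_material <- function(keys, id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (nchar(id) == 0L) rdb_stop("owner ID must be non-empty", "validation")
  if (length(utf8_raw(id)) > keys$id_width)
    rdb_stop("owner ID exceeds the configured fixed width", "width")
  list(locator = raw_to_hex(prf_bits(keys$ks, id)),
       exponent = prf_exponent(keys$group, keys$k2, id))
}

#' Deterministic per-keyword material
#'
#' Each keyword maps to a tag exponent `tag_w = F_p(kt, w)` entering the
#' index-label exponent, and a symmetric key `K_w = F(k1, w)` encrypting
#' the owner IDs filed under that keyword.
#'
#' @inheritParams derive_id_material
#' @param w Keyword string (non-empty).
#' @return List with `tag` (hex exponent) and `key` (raw 16 bytes).
#' @export
derive_keyword_material <- function(keys, w) {
  stopifnot(is.character(w), length(w) == 1L)
  if (nchar(w) == 0L) rdb_stop("keyword must be non-empty", "validation")
  list(tag = prf_exponent(keys$group, keys$kt, w),
       key = prf_bits(keys$k1, w))
}

#' Advance a keyword's counter chain by one step
#'
#' On the first insertion for a keyword a random chain anchor `ST_0` is
#' drawn from the permutation domain and the first usable state is
#' `ST_1 = pi^{-1}(ST_0)` at counter 1; later insertions apply one more
#' inverse permutation. States whose residue mod `p` is zero cannot index
#' anything (`ST mod p` is the chain's contribution to the label
#' exponent); at the chain start the anchor is simply redrawn, while
#' deeper in a chain this raises a `rdb_degenerate_state` error -- at
#' realistic parameter sizes the event has probability about `1/p` and is
#' unreachable.
#'
#' @inheritParams derive_id_material
#' @param state A keyword state `list(st, st0, counter)` or `NULL` when the
#'   keyword has never been inserted.
#' @param rng Randomness source for the chain anchor.
#' @return The new keyword state: `st` (hex, current `ST_c`), `st0` (hex,
#'   the anchor), `counter`.
#' @export
advance_chain <- function(keys, state = NULL, rng = NULL) {
  if (is.null(rng)) rng <- rng_new()
  kp <- keys$trapdoor
  p <- keys$group$p
  if (is.null(state)) {
    repeat {
      st0 <- rng_bn(rng, "2", cx_sub(kp$n, "1"))
      if (cx_gcd(st0, kp$n) != "1") next
      st1 <- tp_inverse(kp, st0)
      if (bn_mod(st1, p) != "0")
        return(list(st = st1, st0 = st0, counter = 1L))
    }
  }
  stc <- tp_inverse(kp, state$st)
  if (bn_mod(stc, p) == "0")
    rdb_stop("chain state degenerate (ST = 0 mod p)", "degenerate_state")
  list(st = stc, st0 = state$st0, counter = state$counter + 1L)
}

#' Batch insertion of owners
#'
#' Encrypts a batch of owners for the server. For every `(ID, w)` pair the
#' keyword's chain is advanced once to `ST_c`; with `s = ST_c mod p` the
#' entry carries the index label `l = H(g^(tag_w * s))`, the deletion delta
#' `Delta = g^(tag_w * s / e_ID)` and the encrypted ID
#' `ID' = SE.Enc(K_w, ID)`. Entries are grouped under the owner's locator
#' (exactly what single-token deletion later needs) and the order of owners
#' and of each owner's entries is shuffled before transmission, so the
#' payload's observable structure is only the per-owner entry counts.
#'
#' @inheritParams derive_id_material
#' @param state The trustee's `rdb_client_state`; updated in place.
#' @param batch List of `list(id = <string>, keywords = <character>)`, e.g.
#'   from [encode_record()]. IDs must not currently be live; re-inserting a
#'   previously deleted owner is allowed and opens fresh chain slots.
#' @param rng Randomness source (chain anchors, nonces, shuffling).
#' @return An `rdb_add_payload`: list of per-owner blocks `list(locator,
#'   entries)`, each entry `list(index, delta, nonce, body)`. The attribute
#'   `"wire"` carries the exact serialized byte layout used for size
#'   accounting.
#' @export
build_add_batch <- function(keys, state, batch, rng = NULL) {
  if (is.null(rng)) rng <- rng_new()
  ids <- vapply(batch, `[[`, "", "id")
  if (anyDuplicated(ids))
    rdb_stop("duplicate owner IDs within one batch", "validation")
  present <- ids[vapply(ids, function(i)
    isTRUE(get0(i, envir = state$live, inherits = FALSE)), logical(1))]
  if (length(present) > 0L)
    rdb_stop(paste0("owner(s) already live: ",
                    paste(present, collapse = ", ")), "validation")
  g <- keys$group
  blocks <- vector("list", length(batch))
  for (bi in seq_along(batch)) {
    rec <- batch[[bi]]
    kws <- rec$keywords
    if (length(kws) == 0L)
      rdb_stop(sprintf("owner '%s' has an empty keyword set", rec$id),
               "validation")
    if (anyDuplicated(kws)) {
      rdb_warn(sprintf("duplicate keywords for owner '%s' deduplicated",
                       rec$id), "dedup")
      kws <- unique(kws)
    }
    idm <- derive_id_material(keys, rec$id)
    einv <- exponent_inverse(g, idm$exponent)
    entries <- vector("list", length(kws))
    for (ki in seq_along(kws)) {
      w <- kws[[ki]]
      km <- derive_keyword_material(keys, w)
      st <- advance_chain(keys, state$W$get(w), rng)
      state$W$set(w, st)
      s <- bn_mod(st$st, g$p)
      e <- group_exp(g, g$g, bn_mod_mul(km$tag, s, g$p))
      delta <- group_exp(g, e, einv)
      label <- hash_to_index(g, e)
      ct <- se_encrypt(km$key, rec$id, width = keys$id_width, rng = rng)
      entries[[ki]] <- list(index = label, delta = delta,
                            nonce = ct$nonce, body = ct$body)
    }
    assign(rec$id, TRUE, envir = state$live)
    blocks[[bi]] <- list(locator = idm$locator,
                         entries = rng_shuffle(rng, entries))
  }
  payload <- structure(rng_shuffle(rng, blocks), class = "rdb_add_payload")
  attr(payload, "elem_bytes") <- g$elem_bytes
  attr(payload, "id_width") <- keys$id_width
  payload
}

#' @export
print.rdb_add_payload <- function(x, ...) {
  cat(sprintf("add payload: %d owner(s), %d entries, %d bytes on the wire\n",
              length(x), sum(lengths(lapply(x, `[[`, "entries"))),
              length(payload_wire(x))))
  invisible(x)
}

#' Build a constant-size deletion token
#'
#' A consent revocation needs one message: the owner's locator and deletion
#' exponent, both deterministic PRF outputs. Its byte size is independent
#' of how many keywords the owner has, and the server needs nothing else to
#' physically remove every entry of the owner (see [apply_delete()]).
#'
#' @inheritParams derive_id_material
#' @param state Optional `rdb_client_state`; when given, the owner is
#'   marked no longer live (enabling later re-insertion).
#' @return An `rdb_delete_token`: list with `locator` and `exponent` (hex),
#'   serialized width fixed by the key parameters.
#' @export
build_delete_token <- function(keys, id, state = NULL) {
  idm <- derive_id_material(keys, id)
  if (!is.null(state) && !is.null(get0(id, envir = state$live,
                                       inherits = FALSE)))
    rm(list = id, envir = state$live)
  structure(list(locator = idm$locator, exponent = idm$exponent),
            class = "rdb_delete_token",
            exp_bytes = keys$group$exp_bytes)
}

#' Export the vetter's (search-side) keys
#'
#' The vetter builds search tokens and decrypts results; it holds the
#' keyword-tag key `kt`, the keyword-encryption key `k1`, the group
#' parameters, the trapdoor PUBLIC key and (a shared reference to) the
#' keyword-state map. It holds neither the trapdoor secret key, nor `ks`,
#' nor `k2`, so a compromised vetter can neither insert nor forge deletion
#' tokens.
#'
#' @inheritParams derive_id_material
#' @param state The trustee's `rdb_client_state`; the returned bundle
#'   shares its keyword-state map, so trustee insertions are immediately
#'   visible to the vetter.
#' @return An object of class `rdb_vetter_keys`.
#' @export
export_vetter_keys <- function(keys, state) {
  structure(list(kt = keys$kt, k1 = keys$k1, group = keys$group,
                 pk = tp_keypair(keys$trapdoor$n, keys$trapdoor$e),
                 id_width = keys$id_width, W = state$W),
            class = "rdb_vetter_keys")
}

#' @export
print.rdb_vetter_keys <- function(x, ...) {
  cat(sprintf("vetter key bundle: search-side keys, %d keyword chains\n",
              x$W$size()))
  invisible(x)
}
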