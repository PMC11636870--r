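#' Encrypted database held by the server
#'
#' The server state is two structures: `fset`, mapping each owner locator
#' to that owner's list of deletion deltas, and `iset`, the encrypted
#' inverted index mapping index labels to encrypted owner IDs. The two are
#' created and destroyed together: at all times the number of index
#' entries equals the total number of stored deltas.
#'
#' @return `egdb_new()` returns an empty database of class `rdb_egdb`.
#' @export
egdb_new <- function() {
  e <- new.env(parent = emptyenv())
  e$fset <- new.env(parent = emptyenv())
  e$iset <- new.env(parent = emptyenv())
  structure(e, class = "rdb_egdb")
}

#' @export
print.rdb_egdb <- function(x, ...) {
  s <- egdb_stats(x)
  cat(sprintf("encrypted database: %d owner locators, %d index entries\n",
              s$n_locators, s$n_index_entries))
  invisible(x)
}

#' The server's public context
#'
#' Everything the server ever computes with: group parameters and the
#' trapdoor PUBLIC key. No server operation takes secret key material --
#' the honest-but-curious server could not use it even by mistake.
#'
#' @param group An `rdb_group`.
#' @param pk Trapdoor public key (an `rdb_trapdoor`, secret part ignored).
#' @return An object of class `rdb_server_ctx`.
#' @export
server_context <- function(group, pk) {
  structure(list(group = group, pk = tp_keypair(pk$n, pk$e)),
            class = "rdb_server_ctx")
}

#' Apply a batch-insertion payload
#'
#' Files every entry: the index label into `iset`, the delta under the
#' owner's locator in `fset`. A pre-existing index label would break the
#' index's injectivity (probability at most `|iset|^2 / 2^256`) and is
#' treated as fatal.
#'
#' @param egdb An `rdb_egdb`; modified in place.
#' @param payload An `rdb_add_payload`.
#' @return The number of index entries inserted, invisibly.
#' @export
apply_add <- function(egdb, payload) {
  n <- 0L
  for (block in payload) {
    for (en in block$entries) {
      if (!is.null(get0(en$index, envir = egdb$iset, inherits = FALSE)))
        rdb_stop("index label collision in the encrypted index", "collision")
      assign(en$index, list(nonce = en$nonce, body = en$body),
             envir = egdb$iset)
      n <- n + 1L
    }
    cur <- get0(block$locator, envir = egdb$fset, inherits = FALSE)
    assign(block$locator,
           c(cur, lapply(block$entries, `[[`, "delta")),
           envir = egdb$fset)
  }
  invisible(n)
}

#' Physically delete one owner with a single token
#'
#' For every delta stored under the token's locator the server recomputes
#' the index label `H(Delta^{e_ID})` and removes that entry from the
#' index, then drops the locator's delta list. Removal is immediate and
#' physical -- no tombstones, no deferral to a later search -- which is
#' what consent revocation requires. A token for an unknown locator
#' removes nothing; a recomputed label missing from the index means the
#' construction identity was violated and raises an integrity error.
#'
#' @inheritParams apply_add
#' @param ctx The server's `rdb_server_ctx`.
#' @param token An `rdb_delete_token`.
#' @return Number of index entries removed.
#' @export
apply_delete <- function(egdb, ctx, token) {
  deltas <- get0(token$locator, envir = egdb$fset, inherits = FALSE)
  if (is.null(deltas)) return(0L)
  labels <- character(length(deltas))
  for (i in seq_along(deltas)) {
    e <- group_exp(ctx$group, deltas[[i]], token$exponent)
    labels[i] <- hash_to_index(ctx$group, e)
    if (is.null(get0(labels[i], envir = egdb$iset, inherits = FALSE)))
      rdb_stop("recomputed index label absent: delta/index invariant broken",
               "integrity")
  }
  rm(list = labels, envir = egdb$iset)
  rm(list = token$locator, envir = egdb$fset)
  length(labels)
}

#' Evaluate a search token
#'
#' Starting from the token's chain state `ST_c`, the server computes the
#' index label `H(g^(tag_w * (ST_i mod p)))` for `i = c, ..., 1`, stepping
#' with the public permutation (`c - 1` forward evaluations). Labels
#' present in the index contribute their encrypted ID to the result set;
#' absent labels are slots whose owner was deleted and are silently
#' skipped -- deletion leaves no other trace in the walk.
#'
#' @inheritParams apply_delete
#' @param token An `rdb_search_token`.
#' @return List of ciphertexts (`list(nonce, body)`), at most `counter`.
#' @export
execute_search <- function(egdb, ctx, token) {
  if (token$counter == 0L) return(list())
  g <- ctx$group
  st <- token$st
  rset <- list()
  for (i in seq(token$counter, 1L)) {
    s <- bn_mod(st, g$p)
    if (s != "0") {
      e <- group_exp(g, g$g, bn_mod_mul(token$tag, s, g$p))
      hit <- get0(hash_to_index(g, e), envir = egdb$iset, inherits = FALSE)
      if (!is.null(hit)) rset[[length(rset) + 1L]] <- hit
    }
    if (i > 1L) st <- tp_forward(ctx$pk, st)
  }
  rset
}

#' Size and count report for the encrypted database
#'
#' Pure summary of the server state: entry counts and the serialized byte
#' sizes of each structure, itemized by the width symbols of the storage
#' accounting (locator width, delta width, label width, ciphertext width).
#'
#' @inheritParams apply_add
#' @param elem_bytes Group-element width in bytes (delta width); inferred
#'   from stored deltas when omitted.
#' @param id_width Fixed ID plaintext width (ciphertext width follows).
#' @return List of counts and byte totals.
#' @export
egdb_stats <- function(egdb, elem_bytes = NULL, id_width = 16L) {
  locs <- ls(egdb$fset)
  n_deltas <- 0L
  for (l in locs)
    n_deltas <- n_deltas + length(get(l, envir = egdb$fset))
  n_iset <- length(ls(egdb$iset))
  if (is.null(elem_bytes)) {
    elem_bytes <- if (length(locs) > 0L)
      length(hex_to_raw(get(locs[1], envir = egdb$fset)[[1]])) else 0L
  }
  lF <- 16L; lh <- 32L; lE <- se_ct_bytes(id_width)
  list(n_locators = length(locs),
       n_deltas = n_deltas,
       n_index_entries = n_iset,
       fset_bytes = length(locs) * lF + n_deltas * elem_bytes,
       iset_bytes = n_iset * (lh + lE),
       total_bytes = length(locs) * lF + n_deltas * elem_bytes +
         n_iset * (lh + lE))
}
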