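# Wire encodings and at-rest serialization.
#
# Every message crossing the client -> server boundary has a canonical
# binary layout (fixed-width big-endian fields); JSON-lines files are the
# at-rest transport with hex-encoded fields. Size accounting is always done
# on the binary layout, never on JSON overhead.

#' Canonical byte layout of client-to-server messages
#'
#' `payload_wire()` serializes a batch-insertion payload: per owner the
#' 16-byte locator followed by, per entry, the 32-byte index label, the
#' fixed-width delta, the 12-byte nonce and the fixed-width encrypted ID.
#' A batch of `r` owners with `x` keywords each is therefore exactly
#' `r * (lF + x * (lh + lD + lE))` bytes, the scheme's communication
#' accounting. `delete_token_wire()` (locator plus fixed-width exponent)
#' and `search_token_wire()` (tag, chain state, 4-byte counter) are
#' constant-size.
#'
#' @param payload,token Message objects from [build_add_batch()],
#'   [build_delete_token()], [build_search_token()].
#' @return A raw vector.
#' @export
payload_wire <- function(payload) {
  eb <- attr(payload, "elem_bytes")
  out <- lapply(payload, function(block) {
    c(hex_to_raw(block$locator),
      unlist(lapply(block$entries, function(en) {
        c(hex_to_raw(en$index), hex_to_raw_width(en$delta, eb),
          en$nonce, en$body)
      })))
  })
  unlist(out)
}

#' @rdname payload_wire
#' @export
delete_token_wire <- function(token) {
  c(hex_to_raw(token$locator),
    hex_to_raw_width(token$exponent, attr(token, "exp_bytes")))
}

#' @rdname payload_wire
#' @export
search_token_wire <- function(token) {
  c(hex_to_raw_width(token$tag, attr(token, "exp_bytes")),
    if (!is.null(token$st))
      hex_to_raw_width(token$st, attr(token, "st_bytes"))
    else raw(attr(token, "st_bytes")),
    hex_to_raw_width(hex_canon(sprintf("%x", token$counter)), 4))
}

#' Write / read key files
#'
#' Key files are JSON. The trustee file holds all key material (PRF keys,
#' full trapdoor key pair, group parameters); the vetter file holds only
#' the search-side subset (`kt`, `k1`, group, trapdoor public key) -- the
#' RSA private exponent and the keys `ks`, `k2` never appear in it.
#'
#' @param keys An `rdb_keyset` (trustee role) or `rdb_vetter_keys`.
#' @param path File path.
#' @export
keys_write <- function(keys, path) {
  if (inherits(keys, "rdb_keyset")) {
    obj <- list(role = "trustee",
                group = keys$group[c("p", "q", "g", "bits")],
                rsa = keys$trapdoor[c("n", "e", "d")],
                prf_keys = list(ks = raw_to_hex(keys$ks),
                                k1 = raw_to_hex(keys$k1),
                                kt = raw_to_hex(keys$kt),
                                k2 = raw_to_hex(keys$k2)),
                id_width = keys$id_width)
  } else if (inherits(keys, "rdb_vetter_keys")) {
    obj <- list(role = "vetter",
                group = keys$group[c("p", "q", "g", "bits")],
                rsa = keys$pk[c("n", "e")],
                prf_keys = list(k1 = raw_to_hex(keys$k1),
                                kt = raw_to_hex(keys$kt)),
                id_width = keys$id_width)
  } else rdb_stop("unknown key object", "validation")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname keys_write
#' @param state For the vetter role, the client state whose keyword-state
#'   map the bundle should reference.
#' @export
keys_read <- function(path, state = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  grp <- new_group(obj$group$p, obj$group$q, obj$group$g, obj$group$bits)
  if (identical(obj$role, "trustee")) {
    structure(list(ks = hex_to_raw(obj$prf_keys$ks),
                   k1 = hex_to_raw(obj$prf_keys$k1),
                   kt = hex_to_raw(obj$prf_keys$kt),
                   k2 = hex_to_raw(obj$prf_keys$k2),
                   trapdoor = tp_keypair(obj$rsa$n, obj$rsa$e, obj$rsa$d),
                   group = grp, id_width = as.integer(obj$id_width)),
              class = "rdb_keyset")
  } else {
    if (is.null(state)) state <- client_state_new()
    structure(list(kt = hex_to_raw(obj$prf_keys$kt),
                   k1 = hex_to_raw(obj$prf_keys$k1),
                   group = grp,
                   pk = tp_keypair(obj$rsa$n, obj$rsa$e),
                   id_width = as.integer(obj$id_width), W = state$W),
              class = "rdb_vetter_keys")
  }
}

#' Persist the client state (keyword-state map and live-owner set)
#'
#' @param state An `rdb_client_state`.
#' @param path File path (JSON).
#' @export
state_write <- function(state, path) {
  kws <- state$W$keys()
  obj <- list(keywords = lapply(stats::setNames(kws, kws), function(w) {
    s <- state$W$get(w)
    list(st = s$st, st0 = s$st0, counter = s$counter)
  }), live = live_ids(state))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname state_write
#' @export
state_read <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  state <- client_state_new()
  for (w in names(obj$keywords)) {
    s <- obj$keywords[[w]]
    state$W$set(w, list(st = s$st, st0 = s$st0,
                        counter = as.integer(s$counter)))
  }
  for (id in obj$live) assign(id, TRUE, envir = state$live)
  state
}

#' Dump / load / serialize the encrypted database
#'
#' The database is stored as two JSON-lines files: `fset.jsonl` with one
#' `{"locator": .., "deltas": [..]}` object per owner, and `iset.jsonl`
#' with one `{"index": .., "nonce": .., "body": ..}` object per index
#' entry, all fields hex. `egdb_serialize()` returns the same text as one
#' string, which is what the physical-deletion byte-scan inspects.
#'
#' @param egdb An `rdb_egdb`.
#' @param dir Directory for the two files (created if needed).
#' @export
egdb_write <- function(egdb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- egdb_serialize_parts(egdb)
  writeLines(txt$fset, file.path(dir, "fset.jsonl"))
  writeLines(txt$iset, file.path(dir, "iset.jsonl"))
  invisible(dir)
}

#' @rdname egdb_write
#' @export
egdb_read <- function(dir) {
  egdb <- egdb_new()
  for (ln in readLines(file.path(dir, "fset.jsonl"))) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    assign(o$locator, lapply(o$deltas, as.character), envir = egdb$fset)
  }
  for (ln in readLines(file.path(dir, "iset.jsonl"))) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    assign(o$index, list(nonce = hex_to_raw(o$nonce),
                         body = hex_to_raw(o$body)), envir = egdb$iset)
  }
  egdb
}

#' @rdname egdb_write
#' @export
egdb_serialize <- function(egdb) {
  txt <- egdb_serialize_parts(egdb)
  paste(c(txt$fset, txt$iset), collapse = "\n")
}

egdb_serialize_parts <- function(egdb) {
  fl <- vapply(ls(egdb$fset, sorted = TRUE), function(l) {
    as.character(jsonlite::toJSON(
      list(locator = l, deltas = get(l, envir = egdb$fset)),
      auto_unbox = TRUE))
  }, "")
  il <- vapply(ls(egdb$iset, sorted = TRUE), function(ix) {
    en <- get(ix, envir = egdb$iset)
    as.character(jsonlite::toJSON(
      list(index = ix, nonce = raw_to_hex(en$nonce),
           body = raw_to_hex(en$body)), auto_unbox = TRUE))
  }, "")
  list(fset = unname(fl), iset = unname(il))
}
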