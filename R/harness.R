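#' Plaintext inverted-index oracle
#'
#' Brute-force ground truth: a mutable inverted index mapping each keyword
#' to the set of currently live owner IDs, mirroring every add/delete
#' applied to the encrypted system. Correctness of the whole scheme means
#' that decrypting any search result equals `oracle_search` at the same
#' point of the operation sequence.
#'
#' @return `plaintext_index()` returns an empty oracle of class
#'   `rdb_oracle`.
#' @export
plaintext_index <- function() {
  e <- new.env(parent = emptyenv())
  e$kw <- new.env(parent = emptyenv())   # keyword -> character vector of IDs
  e$ids <- new.env(parent = emptyenv())  # id -> its keywords
  structure(e, class = "rdb_oracle")
}

#' @rdname plaintext_index
#' @param index An `rdb_oracle`.
#' @param op One workload operation: `list(op = "add", batch = ...)` or
#'   `list(op = "del", id = ...)` (searches do not change the index).
#' @export
oracle_apply <- function(index, op) {
  if (op$op == "add") {
    for (rec in op$batch) {
      assign(rec$id, unique(rec$keywords), envir = index$ids)
      for (w in unique(rec$keywords)) {
        cur <- get0(w, envir = index$kw, inherits = FALSE)
        assign(w, c(cur, rec$id), envir = index$kw)
      }
    }
  } else if (op$op == "del") {
    kws <- get0(op$id, envir = index$ids, inherits = FALSE)
    for (w in kws) {
      cur <- get(w, envir = index$kw)
      assign(w, setdiff(cur, op$id), envir = index$kw)
    }
    if (!is.null(kws)) rm(list = op$id, envir = index$ids)
  }
  invisible(index)
}

#' @rdname plaintext_index
#' @param w Keyword to look up.
#' @return `oracle_search()` returns the sorted IDs currently holding `w`.
#' @export
oracle_search <- function(index, w) {
  sort(get0(w, envir = index$kw, inherits = FALSE, ifnotfound = character(0)))
}

#' Transcript-shape profile of a message log
#'
#' Reduces each client-to-server message to what the honest-but-curious
#' server observes structurally: direction, message type, byte length on
#' the wire and -- for batch insertions -- the multiset of per-owner entry
#' counts. Two add batches with the same per-owner keyword-count multiset
#' produce identical profiles regardless of which owners or keywords they
#' contain; that is exactly the intended update leakage (number of owners
#' and number of keywords per owner, nothing else). Profiles are computed
#' from serialized messages only, never from secret state.
#'
#' @param log List of messages: each `list(type = "add"|"delete"|"search",
#'   msg = <payload or token>)`.
#' @return List of per-message profiles `list(direction, type, bytes,
#'   shape)`; comparable with [identical()].
#' @export
profile_transcript <- function(log) {
  lapply(log, function(entry) {
    msg <- entry$msg
    if (entry$type == "add") {
      counts <- sort(vapply(msg, function(b) length(b$entries), 0L))
      list(direction = "client->server", type = "add",
           bytes = length(payload_wire(msg)),
           shape = list(n_ids = length(msg), per_id_entries = counts))
    } else if (entry$type == "delete") {
      list(direction = "client->server", type = "delete",
           bytes = length(delete_token_wire(msg)), shape = NULL)
    } else {
      list(direction = "client->server", type = "search",
           bytes = length(search_token_wire(msg)), shape = NULL)
    }
  })
}

#' Generate a random add/delete/search workload
#'
#' Builds a reproducible operation trace over a cohort: the cohort is
#' split into `n_add_batches` insertion batches; deletions target owners
#' that are live at that point of the trace; searches draw keywords from
#' the cohort vocabulary. The trace always starts with an insertion and
#' never schedules an infeasible deletion.
#'
#' @param cohort List of `genomic_record`s.
#' @param n_add_batches,n_deletes,n_searches Operation mix counts.
#' @param seed Integer seed.
#' @return An `rdb_workload`: list of operations (`op` = `add`/`del`/
#'   `search` with `batch`/`id`/`keyword`).
#' @export
generate_workload <- function(cohort, n_add_batches, n_deletes, n_searches,
                              seed) {
  stopifnot(n_add_batches >= 1, n_deletes >= 0, n_searches >= 0)
  if (n_deletes > length(cohort))
    rdb_stop("more deletions than owners in the cohort", "validation")
  rng <- rng_new(seed)
  enc <- lapply(cohort, encode_record)
  enc <- rng_shuffle(rng, enc)
  vocab <- cohort_vocabulary(cohort)
  # split owners into batches (each non-empty)
  n <- length(enc)
  if (n_add_batches > n)
    rdb_stop("more add batches than owners", "validation")
  cuts <- sort(rng_shuffle(rng, seq_len(n - 1L))[seq_len(n_add_batches - 1L)])
  bounds <- c(0L, cuts, n)
  batches <- lapply(seq_len(n_add_batches), function(i)
    enc[(bounds[i] + 1L):bounds[i + 1L]])
  # interleave: first op is an add; deletes only when enough owners are live
  ops <- list()
  pending <- c(rep("add", n_add_batches - 1L), rep("del", n_deletes),
               rep("search", n_searches))
  pending <- rng_shuffle(rng, pending)
  live <- character(0)
  deleted <- character(0)
  next_batch <- 1L
  take_batch <- function() {
    if (next_batch > n_add_batches) return(NULL)
    b <- batches[[next_batch]]
    next_batch <<- next_batch + 1L
    live <<- c(live, vapply(b, `[[`, "", "id"))
    list(op = "add", batch = b)
  }
  ops[[1L]] <- take_batch()
  for (kind in pending) {
    op <- if (kind == "add") {
      # may be NULL when a deferred deletion already pulled this batch in
      take_batch()
    } else if (kind == "del") {
      if (length(live) == 0L) {
        # no live owner at this point: pull the next batch forward
        nb <- take_batch()
        if (!is.null(nb)) ops[[length(ops) + 1L]] <- nb
        if (length(live) == 0L)
          rdb_stop("infeasible mix: deletion scheduled with no live owner",
                   "validation")
      }
      id <- live[rng_int(rng, length(live))]
      live <- setdiff(live, id)
      deleted <- c(deleted, id)
      list(op = "del", id = id)
    } else {
      list(op = "search", keyword = vocab[rng_int(rng, length(vocab))])
    }
    if (!is.null(op)) ops[[length(ops) + 1L]] <- op
  }
  structure(ops, class = "rdb_workload", seed = seed)
}

#' @export
print.rdb_workload <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "op")
  cat(sprintf("workload: %d ops (%d add batches, %d deletes, %d searches)\n",
              length(x), sum(kinds == "add"), sum(kinds == "del"),
              sum(kinds == "search")))
  invisible(x)
}

#' Write / read a workload trace as JSON lines
#'
#' One operation per line: `{"op":"add","batch":[{"id":..,"keywords":[..]}]}`,
#' `{"op":"del","id":..}` or `{"op":"search","keyword":..}`.
#'
#' @param workload An `rdb_workload`.
#' @param path File path.
#' @export
workload_write <- function(workload, path) {
  lines <- vapply(workload, function(op)
    as.character(jsonlite::toJSON(op, auto_unbox = TRUE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname workload_write
#' @export
workload_read <- function(path) {
  ops <- lapply(readLines(path), function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (o$op == "add")
      o$batch <- lapply(o$batch, function(b)
        list(id = b$id, keywords = vapply(b$keywords, as.character, "")))
    o
  })
  structure(ops, class = "rdb_workload")
}

#' Replay a workload against the encrypted system with oracle verification
#'
#' Runs the full protocol over a trace: the trustee encrypts insertions
#' and deletion tokens, the server applies them, the vetter issues search
#' tokens and decrypts results. After EVERY search the decrypted result is
#' compared with the plaintext oracle, and after every deletion each of
#' the deleted owner's keywords is searched to certify the owner is
#' already gone -- deletion is instant, not deferred. Primitive-operation
#' counts and message sizes are accumulated along the way.
#'
#' @param workload An `rdb_workload` (or plain list of operations).
#' @param group,rsa_bits,seed System parameters passed to
#'   [trustee_setup()].
#' @param verify_deletes Re-search every deleted owner's keywords right
#'   after the deletion (quadratic in trace size; on by default).
#' @return Report list: `oracle_match`, `mismatches`, `n_searches_checked`,
#'   `removed_total`, `op_counts`, `message_bytes`, `egdb` and the final
#'   system objects.
#' @export
replay_workload <- function(workload, group = NULL, rsa_bits = 2048,
                            seed = NULL, verify_deletes = TRUE) {
  sys <- trustee_setup(group = group, rsa_bits = rsa_bits, seed = seed)
  vk <- export_vetter_keys(sys$keys, sys$state)
  ctx <- server_context(sys$keys$group, sys$keys$trapdoor)
  rng <- rng_new(if (!is.null(seed)) seed + 101L)
  oracle <- plaintext_index()
  mism <- 0L
  checked <- 0L
  removed <- 0L
  bytes <- c(add = 0, delete = 0, search = 0)
  run_search <- function(w) {
    tok <- build_search_token(vk, w)
    bytes["search"] <<- bytes["search"] + length(search_token_wire(tok))
    decrypt_results(vk, w, execute_search(sys$egdb, ctx, tok))
  }
  total <- with_op_counts(for (op in workload) {
    if (op$op == "add") {
      payload <- build_add_batch(sys$keys, sys$state, op$batch, rng)
      bytes["add"] <- bytes["add"] + length(payload_wire(payload))
      apply_add(sys$egdb, payload)
      oracle_apply(oracle, op)
    } else if (op$op == "del") {
      kws <- get0(op$id, envir = oracle$ids, inherits = FALSE)
      tok <- build_delete_token(sys$keys, op$id, sys$state)
      bytes["delete"] <- bytes["delete"] + length(delete_token_wire(tok))
      removed <- removed + apply_delete(sys$egdb, ctx, tok)
      oracle_apply(oracle, op)
      if (verify_deletes) {
        for (w in kws) {
          checked <- checked + 1L
          got <- run_search(w)
          if (op$id %in% got || !identical(got, oracle_search(oracle, w)))
            mism <- mism + 1L
        }
      }
    } else {
      checked <- checked + 1L
      got <- run_search(op$keyword)
      if (!identical(got, oracle_search(oracle, op$keyword)))
        mism <- mism + 1L
    }
  })
  list(oracle_match = mism == 0L, mismatches = mism,
       n_searches_checked = checked, removed_total = removed,
       op_counts = total$counts, message_bytes = bytes,
       egdb = sys$egdb, keys = sys$keys, state = sys$state,
       vetter = vk, ctx = ctx, oracle = oracle)
}
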