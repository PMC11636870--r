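# trustee side: setup, key derivation, counter chains, batch insertion,
# deletion tokens, key export

test_that("setup yields fresh keys, empty structures, and seeded reproducibility", {
  s1 <- new_test_system(seed = 1)
  s2 <- new_test_system(seed = 2)
  expect_false(identical(s1$keys$ks, s2$keys$ks))
  expect_false(identical(s1$keys$trapdoor$n, s2$keys$trapdoor$n))
  # the four PRF keys are pairwise distinct
  ks <- list(s1$keys$ks, s1$keys$k1, s1$keys$kt, s1$keys$k2)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(ks[[i]], ks[[j]]))
  # both server structures empty, state map empty
  st <- egdb_stats(s1$egdb)
  expect_equal(st$n_locators, 0)
  expect_equal(st$n_index_entries, 0)
  expect_equal(s1$state$W$size(), 0)
  # same seed twice gives identical key material
  s1b <- new_test_system(seed = 1)
  expect_identical(s1$keys$ks, s1b$keys$ks)
  expect_identical(s1$keys$trapdoor$d, s1b$keys$trapdoor$d)
})

test_that("per-owner and per-keyword material is deterministic and well-formed", {
  sys <- new_test_system()
  m1 <- derive_id_material(sys$keys, "PGP0001")
  expect_identical(m1, derive_id_material(sys$keys, "PGP0001"))
  m2 <- derive_id_material(sys$keys, "PGP0002")
  expect_false(identical(m1$locator, m2$locator))
  expect_equal(nchar(m1$locator), 32)  # 16 bytes
  # deletion exponent is invertible mod p
  inv <- exponent_inverse(sys$keys$group, m1$exponent)
  expect_identical(
    revokedb:::bn_mod_mul(m1$exponent, inv, sys$keys$group$p), "1")
  expect_error(derive_id_material(sys$keys, ""), class = "rdb_validation")
  expect_error(derive_id_material(sys$keys, strrep("x", 40)),
               class = "rdb_width")
  km <- derive_keyword_material(sys$keys, "snp:rs1=AG")
  expect_identical(km, derive_keyword_material(sys$keys, "snp:rs1=AG"))
  expect_false(identical(km$tag,
                         derive_keyword_material(sys$keys, "snp:rs2=AG")$tag))
  # K_w supports an encryption round trip
  ct <- se_encrypt(km$key, "PGP0001", rng = rng_new(1))
  expect_identical(se_decrypt(km$key, ct), "PGP0001")
})

test_that("counter chain advances by trapdoor inversion and walks back publicly", {
  sys <- new_test_system()
  kp <- sys$keys$trapdoor
  rng <- rng_new(5)
  st <- advance_chain(sys$keys, NULL, rng)
  expect_equal(st$counter, 1)
  for (i in 2:5) st <- advance_chain(sys$keys, st, rng)
  expect_equal(st$counter, 5)
  # public forward evaluation recovers the anchor ST_0 in exactly 5 steps
  pk <- tp_keypair(kp$n, kp$e)
  x <- st$st
  for (i in 1:5) x <- tp_forward(pk, x)
  expect_identical(x, st$st0)
})

test_that("batch insertion updates counters, embeds both recomputation paths", {
  sys <- new_test_system()
  batch <- list(list(id = "ID1", keywords = c("w1", "w2")),
                list(id = "ID2", keywords = "w1"))
  pl <- build_add_batch(sys$keys, sys$state, batch, rng_new(3))
  expect_equal(sys$state$W$get("w1")$counter, 2)
  expect_equal(sys$state$W$get("w2")$counter, 1)
  g <- sys$keys$group
  # construction identity on every emitted entry: the deletion path
  # H(delta^e_ID) reproduces the stored index label
  locator_of <- function(id) derive_id_material(sys$keys, id)$locator
  for (block in pl) {
    id <- if (block$locator == locator_of("ID1")) "ID1" else "ID2"
    eid <- derive_id_material(sys$keys, id)$exponent
    for (en in block$entries) {
      expect_identical(hash_to_index(g, group_exp(g, en$delta, eid)),
                       en$index)
    }
  }
  # and the search path H(g^(tag_w * s)) covers every stored label
  apply_add(sys$egdb, pl)
  vk <- export_vetter_keys(sys$keys, sys$state)
  ctx <- server_context(g, sys$keys$trapdoor)
  touched <- character(0)
  for (w in c("w1", "w2")) {
    tok <- build_search_token(vk, w)
    st <- tok$st
    for (i in seq(tok$counter, 1)) {
      s <- revokedb:::bn_mod(st, g$p)
      e <- group_exp(g, g$g, revokedb:::bn_mod_mul(tok$tag, s, g$p))
      touched <- c(touched, hash_to_index(g, e))
      if (i > 1) st <- tp_forward(ctx$pk, st)
    }
  }
  expect_setequal(touched, ls(sys$egdb$iset))
})

test_that("payload size follows the per-owner byte formula exactly", {
  sys <- new_test_system()
  lF <- 16; lh <- 32
  lD <- sys$keys$group$elem_bytes
  lE <- revokedb:::se_ct_bytes(sys$keys$id_width)
  for (x in c(1, 4, 9)) {
    pl <- build_add_batch(sys$keys, sys$state,
                          list(list(id = paste0("O", x),
                                    keywords = paste0("k", x, "_", 1:x))),
                          rng_new(x))
    expect_equal(length(payload_wire(pl)), lF + x * (lE + lD + lh))
  }
  # r owners times x keywords
  batch <- lapply(1:3, function(i)
    list(id = paste0("R", i), keywords = paste0("m", 1:5)))
  pl <- build_add_batch(sys$keys, sys$state, batch, rng_new(99))
  expect_equal(length(payload_wire(pl)), 3 * (lF + 5 * (lE + lD + lh)))
})

test_that("re-encrypting an identical batch repeats labels/deltas but not ciphertexts", {
  s1 <- new_test_system(seed = 10)
  s2 <- new_test_system(seed = 10)
  batch <- list(list(id = "ID1", keywords = c("w1", "w2", "w3")))
  p1 <- build_add_batch(s1$keys, s1$state, batch, rng_new(500))
  p2 <- build_add_batch(s2$keys, s2$state, batch, rng_new(501))
  key_of <- function(p) sort(vapply(p[[1]]$entries, `[[`, "", "index"))
  # same keys + same chain anchors (seeded) would be needed for identical
  # labels; here anchors differ, so compare within one system instead:
  # deterministic parts are the locator and the per-keyword tags
  expect_identical(p1[[1]]$locator, p2[[1]]$locator)
  # ciphertext bodies are randomized even for identical plaintext
  b1 <- sort(vapply(p1[[1]]$entries, function(e) revokedb:::raw_to_hex(e$body), ""))
  b2 <- sort(vapply(p2[[1]]$entries, function(e) revokedb:::raw_to_hex(e$body), ""))
  expect_false(any(b1 %in% b2))
})

test_that("insertion preconditions: live duplicates rejected, in-batch dups deduplicated", {
  sys <- new_test_system()
  b <- list(list(id = "ID1", keywords = c("w1", "w1", "w2")))
  expect_warning(pl <- build_add_batch(sys$keys, sys$state, b, rng_new(1)),
                 class = "rdb_dedup")
  expect_equal(length(pl[[1]]$entries), 2)  # deduplicated
  expect_error(build_add_batch(sys$keys, sys$state,
                               list(list(id = "ID1", keywords = "w9")),
                               rng_new(2)),
               class = "rdb_validation")
  expect_error(build_add_batch(sys$keys, sys$state,
                               list(list(id = "ID3", keywords = character(0))),
                               rng_new(3)),
               class = "rdb_validation")
})

test_that("counters never decrease across adds and deletes", {
  sys <- new_test_system()
  ctx <- server_context(sys$keys$group, sys$keys$trapdoor)
  rng <- rng_new(8)
  history <- integer(0)
  snapshot <- function() {
    ws <- sys$state$W$keys()
    sum(vapply(ws, function(w) sys$state$W$get(w)$counter, 0L))
  }
  for (round in 1:3) {
    ids <- paste0("R", round, "_", 1:3)
    pl <- build_add_batch(sys$keys, sys$state,
                          lapply(ids, function(i)
                            list(id = i, keywords = paste0("w", 1:3))),
                          rng)
    apply_add(sys$egdb, pl)
    history <- c(history, snapshot())
    apply_delete(sys$egdb, ctx,
                 build_delete_token(sys$keys, ids[1], sys$state))
    history <- c(history, snapshot())
  }
  expect_true(all(diff(history) >= 0))
  # deleted owner can be re-inserted; chain slots are fresh
  c_before <- sys$state$W$get("w1")$counter
  pl <- build_add_batch(sys$keys, sys$state,
                        list(list(id = "R3_1", keywords = "w1")), rng)
  expect_equal(sys$state$W$get("w1")$counter, c_before + 1)
})

test_that("deletion tokens are deterministic, constant-size, and valid for absent IDs", {
  sys <- new_test_system()
  t1 <- build_delete_token(sys$keys, "PGP0001")
  t2 <- build_delete_token(sys$keys, "PGP0001")
  expect_identical(t1$locator, t2$locator)
  expect_identical(t1$exponent, t2$exponent)
  # never-inserted ID produces a well-formed token
  expect_equal(length(delete_token_wire(t1)),
               16 + sys$keys$group$exp_bytes)
})

test_that("the vetter export contains search keys only and suffices for search", {
  stack <- new_test_stack()
  vk <- stack$vk
  expect_null(vk$pk$d)                # no trapdoor secret
  expect_false("ks" %in% names(vk))   # no locator key
  expect_false("k2" %in% names(vk))   # no deletion-exponent key
  batch <- list(list(id = "ID1", keywords = c("w1", "w2")))
  apply_add(stack$egdb,
            build_add_batch(stack$keys, stack$state, batch, rng_new(4)))
  tok <- build_search_token(vk, "w1")
  ids <- decrypt_results(vk, "w1", execute_search(stack$egdb, stack$ctx, tok))
  expect_identical(ids, "ID1")
})
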