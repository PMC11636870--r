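# harness: plaintext oracle, workload generation and replay, operation
# counting, transcript profiling, serialization of keys/state, CLI

test_that("the plaintext oracle implements inverted-index semantics", {
  idx <- plaintext_index()
  oracle_apply(idx, list(op = "add", batch = list(
    list(id = "A", keywords = c("w1", "w2")),
    list(id = "B", keywords = "w1"))))
  expect_identical(oracle_search(idx, "w1"), c("A", "B"))
  oracle_apply(idx, list(op = "del", id = "A"))
  expect_identical(oracle_search(idx, "w1"), "B")
  expect_identical(oracle_search(idx, "w2"), character(0))
  expect_identical(oracle_search(idx, "never"), character(0))
})

test_that("workloads are reproducible, feasible, and respect the mix", {
  cohort <- generate_synthetic_cohort(n_owners = 20, n_snps = 5, seed = 1)
  w1 <- generate_workload(cohort, 4, 6, 30, seed = 9)
  w2 <- generate_workload(cohort, 4, 6, 30, seed = 9)
  expect_identical(unclass(w1), unclass(w2))
  kinds <- vapply(w1, `[[`, "", "op")
  expect_equal(sum(kinds == "add"), 4)
  expect_equal(sum(kinds == "del"), 6)
  expect_equal(sum(kinds == "search"), 30)
  expect_equal(kinds[1], "add")
  # deletes always target a currently-live owner
  live <- character(0)
  for (op in w1) {
    if (op$op == "add") live <- c(live, vapply(op$batch, `[[`, "", "id"))
    if (op$op == "del") {
      expect_true(op$id %in% live)
      live <- setdiff(live, op$id)
    }
  }
  # zero-delete mix has no del records
  w0 <- generate_workload(cohort, 2, 0, 10, seed = 1)
  expect_false("del" %in% vapply(w0, `[[`, "", "op"))
  expect_error(generate_workload(cohort, 2, 21, 5, seed = 1),
               class = "rdb_validation")
  # JSONL round trip
  path <- withr::local_tempfile(fileext = ".jsonl")
  workload_write(w1, path)
  expect_identical(unclass(workload_read(path)),
                   `attributes<-`(unclass(w1), NULL))
})

test_that("replayed traces match the oracle at every checkpoint", {
  cohort <- generate_synthetic_cohort(n_owners = 15, n_snps = 5, seed = 21)
  for (seed in 1:3) {
    wl <- generate_workload(cohort, 3, 5, 40, seed = seed)
    rep <- replay_workload(wl, group = test_group(), rsa_bits = 512,
                           seed = seed)
    expect_true(rep$oracle_match)
    expect_equal(rep$mismatches, 0)
    expect_gte(rep$n_searches_checked, 40)
  }
})

test_that("measured operation counts equal the closed-form predictions", {
  for (x in c(1, 5, 50)) {
    stack <- new_test_stack(seed = x)
    b <- list(list(id = "X", keywords = paste0("w", 1:x)))
    add <- with_op_counts(build_add_batch(stack$keys, stack$state, b,
                                          rng_new(1)))
    expect_identical(add$counts, predict_op_counts("add", x = x)$client)
    apply_add(stack$egdb, add$value)
    del_c <- with_op_counts(build_delete_token(stack$keys, "X", stack$state))
    del_s <- with_op_counts(apply_delete(stack$egdb, stack$ctx, del_c$value))
    expect_identical(del_c$counts, predict_op_counts("delete", x = x)$client)
    expect_identical(del_s$counts, predict_op_counts("delete", x = x)$server)
  }
  # search at counter c: c exponentiations, c hashes, c - 1 trapdoor steps
  for (cc in c(1, 5, 50)) {
    stack <- new_test_stack(seed = 100 + cc)
    b <- lapply(seq_len(cc), function(i)
      list(id = paste0("I", i), keywords = "w"))
    apply_add(stack$egdb,
              build_add_batch(stack$keys, stack$state, b, rng_new(2)))
    tok_m <- with_op_counts(build_search_token(stack$vk, "w"))
    srch <- with_op_counts(execute_search(stack$egdb, stack$ctx, tok_m$value))
    pred <- predict_op_counts("search", c = cc)
    expect_identical(tok_m$counts, pred$client)
    expect_identical(srch$counts, pred$server)
    expect_equal(length(srch$value), cc)
  }
})

test_that("transcript profiles expose shape only", {
  stack <- new_test_stack(seed = 1)
  mk_batch <- function(ids, counts, prefix)
    mapply(function(i, x) list(id = i, keywords = paste0(prefix, i, "_", 1:x)),
           ids, counts, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  p1 <- build_add_batch(stack$keys, stack$state,
                        mk_batch(c("A", "B"), c(3, 2), "u"), rng_new(1))
  p2 <- build_add_batch(stack$keys, stack$state,
                        mk_batch(c("C", "D"), c(2, 3), "v"), rng_new(2))
  p3 <- build_add_batch(stack$keys, stack$state,
                        mk_batch(c("E", "F"), c(4, 2), "t"), rng_new(3))
  prof <- profile_transcript(list(list(type = "add", msg = p1),
                                  list(type = "add", msg = p2),
                                  list(type = "add", msg = p3)))
  # same per-owner count multiset, disjoint content: identical profiles
  expect_identical(prof[[1]], prof[[2]])
  # different shape: different profile
  expect_false(identical(prof[[1]], prof[[3]]))
  # no plaintext keyword or ID reaches the profile
  expect_false(any(grepl("A|B|u", deparse(prof[[1]]))))
  # delete tokens for any two owners have identical byte length
  t1 <- build_delete_token(stack$keys, "A")
  t2 <- build_delete_token(stack$keys, "veryverylongid")
  prof_t <- profile_transcript(list(list(type = "delete", msg = t1),
                                    list(type = "delete", msg = t2)))
  expect_identical(prof_t[[1]], prof_t[[2]])
})

test_that("key files and client state round-trip, vetter file holds no secrets", {
  sys <- new_test_system(seed = 31)
  batch <- list(list(id = "ID1", keywords = c("w1", "w2")))
  apply_add(sys$egdb, build_add_batch(sys$keys, sys$state, batch, rng_new(1)))
  dir <- withr::local_tempdir()
  tf <- file.path(dir, "trustee.json"); vf <- file.path(dir, "vetter.json")
  sf <- file.path(dir, "state.json")
  keys_write(sys$keys, tf)
  keys_write(export_vetter_keys(sys$keys, sys$state), vf)
  state_write(sys$state, sf)
  # vetter file: no RSA private exponent, no ks/k2 keys
  vtxt <- paste(readLines(vf), collapse = "")
  expect_false(grepl(sys$keys$trapdoor$d, vtxt, fixed = TRUE))
  expect_false(grepl(revokedb:::raw_to_hex(sys$keys$ks), vtxt, fixed = TRUE))
  expect_false(grepl(revokedb:::raw_to_hex(sys$keys$k2), vtxt, fixed = TRUE))
  # reloaded trustee keys derive identical material
  k2 <- keys_read(tf)
  expect_identical(derive_id_material(k2, "ID1"),
                   derive_id_material(sys$keys, "ID1"))
  # reloaded state carries counters and live set
  st2 <- state_read(sf)
  expect_equal(st2$W$get("w1")$counter, 1)
  expect_identical(revokedb:::live_ids(st2), "ID1")
  # reloaded vetter bundle + state searches correctly
  vk2 <- keys_read(vf, state = st2)
  ctx <- server_context(k2$group, k2$trapdoor)
  ids <- decrypt_results(vk2, "w1",
                         execute_search(sys$egdb, ctx,
                                        build_search_token(vk2, "w1")))
  expect_identical(ids, "ID1")
})

test_that("the CLI drives a full lifecycle through serialized state", {
  dir <- withr::local_tempdir()
  state <- file.path(dir, "state")
  cohort_tsv <- file.path(dir, "cohort.tsv")
  wl_file <- file.path(dir, "wl.jsonl")
  run <- function(...) run_cli(c(...))
  expect_equal(suppressMessages(run("gen-cohort", "--out", cohort_tsv,
                                    "--n-owners", "6", "--n-snps", "4",
                                    "--seed", "5")), 0)
  expect_equal(suppressMessages(
    run("setup", "--state", state, "--group-bits", "512",
        "--rsa-bits", "512", "--seed", "11")), 0)
  expect_true(all(file.exists(file.path(state,
    c("trustee.keys.json", "vetter.keys.json", "state.json")))))
  expect_equal(suppressMessages(run("add", "--state", state,
                                    "--cohort", cohort_tsv)), 0)
  # search for a keyword present in the cohort
  cohort <- read_cohort(cohort_tsv)
  w <- encode_record(cohort[[1]])$keywords[1]
  out <- capture.output(status <- suppressMessages(
    run("search", "--state", state, "--keyword", w)))
  expect_equal(status, 0)
  expect_true(cohort[[1]]$owner_id %in% out)
  # delete that owner; search again is empty of it, exit still 0
  expect_equal(suppressMessages(run("delete", "--state", state,
                                    "--id", cohort[[1]]$owner_id)), 0)
  out2 <- capture.output(status2 <- suppressMessages(
    run("search", "--state", state, "--keyword", w)))
  expect_equal(status2, 0)
  expect_false(cohort[[1]]$owner_id %in% out2)
  # search on an unseen keyword: empty result, exit 0
  out3 <- capture.output(status3 <- suppressMessages(
    run("search", "--state", state, "--keyword", "snp:rs0=AA")))
  expect_equal(status3, 0)
  expect_equal(length(out3), 0)
  # stats emits JSON
  outs <- capture.output(suppressMessages(run("stats", "--state", state)))
  expect_true(jsonlite::validate(paste(outs, collapse = "")))
  # replay with oracle verification reports PASS (exit 0)
  expect_equal(suppressMessages(run("gen-workload", "--cohort", cohort_tsv,
                                    "--out", wl_file, "--add-batches", "2",
                                    "--deletes", "2", "--searches", "10",
                                    "--seed", "3")), 0)
  outr <- capture.output(statusr <- suppressMessages(
    run("replay", "--workload", wl_file, "--group-bits", "512",
        "--rsa-bits", "512", "--seed", "4")))
  expect_equal(statusr, 0)
  rep <- jsonlite::fromJSON(paste(outr, collapse = ""))
  expect_true(rep$oracle_match)
  # missing state errors with nonzero status
  expect_equal(suppressMessages(run("search", "--state",
                                    file.path(dir, "nope"),
                                    "--keyword", "w")), 1)
})
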