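test_that("fragment pool conserves fragments and aggregates duplicates", {
  one <- mt("CC(=O)Nc1ccc(O)cc1")
  pool1 <- build_fragment_pool(one)
  k <- nrow(brics_fragment(one$smiles)$fragments)
  expect_lte(nrow(pool1$entries), k)
  expect_equal(sum(pool1$entries$frequency), k)
  # duplicate molecules double frequencies, entry count unchanged
  pool2 <- build_fragment_pool(rbind(one, transform(one, id = "copy")))
  expect_equal(nrow(pool2$entries), nrow(pool1$entries))
  expect_equal(sum(pool2$entries$frequency), 2 * k)
  # dummy count equals label count for every entry
  expect_equal(pool1$entries$n_attach,
               lengths(strsplit(pool1$entries$labels, "+", fixed = TRUE)))
  expect_error(build_fragment_pool(mt(character(0))),
               class = "molforge_validation_error")
})

test_that("fragment pool round-trips through CSV", {
  pool <- build_fragment_pool(corpus_30()[1:10, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_fragment_pool(pool, path)
  back <- read_fragment_pool(path)
  expect_identical(back$entries$smiles, pool$entries$smiles)
  expect_identical(back$entries$labels, pool$entries$labels)
  expect_equal(back$entries$frequency, pool$entries$frequency)
})

test_that("BRICS analogues are single edits, deduplicated, never the seed", {
  corpus <- corpus_30()
  pool <- build_fragment_pool(corpus)
  seed <- corpus[1, ]
  ana <- enumerate_brics_analogues(seed, pool, allow_delete = TRUE)
  expect_gt(nrow(ana), 0)
  expect_false(seed$smiles %in% ana$smiles)
  expect_false(any(duplicated(ana$smiles)))
  expect_true(all(ana$method == "brics"))
  expect_true(all(ana$seed_id == seed$id))
  seed_frags <- frag_multiset(seed$smiles)
  repl <- ana[grepl("^replace", ana$change_note), ]
  for (i in seq_len(min(nrow(repl), 15))) {
    d <- multiset_symdiff(seed_frags, frag_multiset(repl$smiles[i]))
    expect_lte(d, 2)  # one replacement changes at most two multiset entries
    expect_gte(d, 1)
  }
  # deletion also rewrites the capped neighbour fragment: at most three
  # entries may change, and never more
  dels <- ana[grepl("^delete", ana$change_note), ]
  for (i in seq_len(nrow(dels))) {
    d <- multiset_symdiff(seed_frags, frag_multiset(dels$smiles[i]))
    expect_lte(d, 3)
    expect_gte(d, 1)
  }
})

test_that("random mode subsamples reproducibly; caps bound the output", {
  corpus <- corpus_30()
  pool <- build_fragment_pool(corpus)
  seed <- corpus[2, ]
  full <- enumerate_brics_analogues(seed, pool)
  r1 <- enumerate_brics_analogues(seed, pool, mode = "random", n = 3,
                                  seed = 7)
  r2 <- enumerate_brics_analogues(seed, pool, mode = "random", n = 3,
                                  seed = 7)
  expect_identical(r1$smiles, r2$smiles)
  expect_lte(nrow(r1), 3)
  expect_true(all(r1$smiles %in% full$smiles))
  capped <- enumerate_brics_analogues(seed, pool, max_per_position = 1)
  expect_lte(nrow(capped), nrow(full))
})

test_that("ring relaxation legalises phenyl -> cyclohexyl replacement", {
  pool <- build_fragment_pool(mt(c("CC(=O)Nc1ccccc1", "CC(=O)NC1CCCCC1")))
  seed <- mt("CC(=O)Nc1ccccc1")
  strict <- enumerate_brics_analogues(seed, pool)
  relaxed <- enumerate_brics_analogues(seed, pool, relax_ring_labels = TRUE)
  expect_false(can("CC(=O)NC1CCCCC1") %in% strict$smiles)
  expect_true(can("CC(=O)NC1CCCCC1") %in% relaxed$smiles)
})

test_that("insertion grows and deletion shrinks by whole fragments", {
  pool <- build_fragment_pool(
    mt(c("c1ccc(-c2ccccc2)cc1", "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1")))
  seed <- mt("c1ccc(-c2ccccc2)cc1")
  grown <- enumerate_brics_analogues(seed, pool, allow_insert = TRUE)
  expect_true(can("c1ccc(-c2ccc(-c3ccccc3)cc2)cc1") %in% grown$smiles)
  shrunk <- enumerate_brics_analogues(mt("CC(=O)Nc1ccc(O)cc1"),
                                      build_fragment_pool(corpus_30()),
                                      allow_delete = TRUE)
  dels <- shrunk[grepl("^delete", shrunk$change_note), ]
  expect_gt(nrow(dels), 0)
  seed_heavy <- compute_properties(mt("CC(=O)Nc1ccc(O)cc1"))$heavy_atoms
  del_heavy <- compute_properties(dels)$heavy_atoms
  expect_true(all(del_heavy < seed_heavy))
})

test_that("MMP transforms substitute exact fragments at single cuts", {
  tol <- mt("Cc1ccccc1", id = "tol")
  out <- apply_mmp_transforms(
    tol, data.frame(lhs_smiles = "[*]C", rhs_smiles = "[*]CC"))
  expect_true(can("CCc1ccccc1") %in% out$smiles)
  expect_true(all(out$method == "mmp"))
  # a rule matching nothing contributes nothing
  none <- apply_mmp_transforms(
    tol, data.frame(lhs_smiles = "[*]Br", rhs_smiles = "[*]Cl"))
  expect_equal(nrow(none), 0)
})

test_that("ten single-site rules yield exactly the ten enumerated products", {
  seed <- mt("Cc1ccccc1", id = "tol")
  rhs <- c("[*]CC", "[*]CCC", "[*]C(C)C", "[*]CCCC", "[*]C(C)(C)C",
           "[*]CCO", "[*]CC#N", "[*]CCF", "[*]CC=C", "[*]CCCl")
  rules <- data.frame(lhs_smiles = "[*]C", rhs_smiles = rhs)
  out <- apply_mmp_transforms(seed, rules)
  # hand-enumerated: each rhs R attached to benzene
  expected <- can(c("CCc1ccccc1", "CCCc1ccccc1", "CC(C)c1ccccc1",
                    "CCCCc1ccccc1", "CC(C)(C)c1ccccc1", "OCCc1ccccc1",
                    "N#CCc1ccccc1", "FCCc1ccccc1", "C=CCc1ccccc1",
                    "ClCCc1ccccc1"))
  expect_setequal(out$smiles, expected)
  expect_equal(nrow(out), 10)
})

test_that("transform tables are validated", {
  expect_error(validate_transforms(
    data.frame(lhs_smiles = "CC", rhs_smiles = "[*]C")),
    class = "molforge_validation_error")
  expect_error(validate_transforms(
    data.frame(lhs_smiles = "[*]C", rhs_smiles = "[*]C")),
    class = "molforge_validation_error")
})

test_that("similarity search ranks self-hits first and respects cutoffs", {
  pool <- corpus_30()[1:10, ]
  hits <- similarity_search(pool[3, ], pool, "circular2", cutoff = 0.2)
  expect_identical(hits$hit_id[1], pool$id[3])
  expect_equal(hits$similarity[1], 1)
  expect_true(all(diff(hits$similarity) <= 0))
  all_hits <- similarity_search(pool[1, ], pool, "path7", cutoff = 0)
  expect_equal(nrow(all_hits), 10)
  exact <- similarity_search(pool[1, ], pool, "path7", cutoff = 1)
  expect_true(all(exact$similarity == 1))
  expect_error(similarity_search(pool[1, ], pool[integer(0), ], "path7"),
               class = "molforge_validation_error")
})

test_that("similarity filter include/exclude boundary behaviour", {
  cands <- corpus_30()[1:8, ]
  refs <- cands[1, ]
  inc <- similarity_filter(cands, refs, "include")
  expect_true(refs$id %in% inc$id)  # identical candidate kept
  exc <- similarity_filter(cands, refs, "exclude")
  expect_false(refs$id %in% exc$id)  # identical candidate removed
  all_kept <- similarity_filter(cands, refs, "include",
                                thresholds = c(path7 = 0, circular2 = 0))
  expect_equal(nrow(all_kept), nrow(cands))
  only_exact <- similarity_filter(cands, refs, "exclude",
                                  exclude_threshold = 1)
  expect_equal(nrow(only_exact), nrow(cands) - 1)
})
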