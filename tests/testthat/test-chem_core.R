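test_that("canonicalisation is idempotent and representation-invariant", {
  rec <- parse_and_canonicalise("c1ccccc1")
  expect_identical(parse_and_canonicalise(rec$smiles)$smiles, rec$smiles)
  expect_identical(can("OCC"), can("CCO"))
  for (s in corpus_30()$smiles) {
    expect_identical(can(s), s)  # stored structures are already canonical
  }
  expect_error(parse_and_canonicalise("C1CC"), class = "molforge_parse_error")
  expect_error(parse_and_canonicalise(""), class = "molforge_parse_error")
})

test_that("property vector matches hand-computed reference values", {
  p <- compute_properties(mt(c("c1ccccc1", "CCO")))
  benzene <- p[1, ]
  expect_equal(benzene$aromatic_rings, 1L)
  expect_equal(benzene$HBD, 0)
  expect_equal(benzene$RotB, 0L)
  expect_equal(benzene$heavy_atoms, 6L)
  # hand sum of standard atomic masses: 6 C + 6 H
  expect_equal(benzene$MW, 6 * 12.011 + 6 * 1.008, tolerance = 0.01)
  ethanol <- p[2, ]
  expect_equal(ethanol$HBD, 1)
  expect_equal(ethanol$HBA, 1)
  expect_equal(p$PFI_proxy, p$clogP + p$aromatic_rings)
  # determinism
  p2 <- compute_properties(mt(c("c1ccccc1", "CCO")))
  expect_identical(p, p2)
})

test_that("counts are non-negative and MW positive across the corpus", {
  p <- compute_properties(corpus_30())
  for (col in c("heavy_atoms", "HBD", "HBA", "RotB", "aromatic_rings")) {
    expect_true(all(p[[col]] >= 0), info = col)
  }
  expect_true(all(p$MW > 0))
})

test_that("tanimoto agrees with a set-arithmetic oracle on random bit sets", {
  set.seed(42)
  mkfp <- function(bits) {
    structure(list(kind = "path7", nbits = 1024, bits = bits),
              class = "molforge_fp")
  }
  for (i in 1:50) {
    a <- sort(sample(1024, sample(0:60, 1)))
    b <- sort(sample(1024, sample(0:60, 1)))
    oracle <- {
      inter <- sum(a %in% b)
      uni <- length(a) + length(b) - inter
      if (uni == 0) 1 else inter / uni
    }
    got <- tanimoto(mkfp(a), mkfp(b))
    expect_equal(got, oracle)
    expect_equal(got, tanimoto(mkfp(b), mkfp(a)))  # symmetry
    expect_gte(got, 0)
    expect_lte(got, 1)
    expect_identical(got == 1, setequal(a, b) && length(a) == length(b))
  }
  expect_equal(tanimoto(mkfp(1:3), mkfp(2:4)), 0.5)
  expect_equal(tanimoto(mkfp(integer(0)), mkfp(integer(0))), 1)
  expect_error(tanimoto(mkfp(1),
                        structure(list(kind = "circular2", nbits = 4096,
                                       bits = 1L), class = "molforge_fp")),
               class = "molforge_validation_error")
})

test_that("fingerprints are deterministic and self-similarity is exact", {
  m <- mt(c("c1ccccc1", "c1ccccc1", "C", "CC(=O)Nc1ccc(O)cc1"))
  for (kind in c("path7", "circular2")) {
    fps <- fingerprint(m, kind)
    expect_identical(fps[[1]]$bits, fps[[2]]$bits)
    expect_equal(tanimoto(fps[[1]], fps[[2]]), 1)
  }
  circ <- fingerprint(m, "circular2")
  # frozen regression: methane vs a druglike molecule is far below 0.2
  expect_lt(tanimoto(circ[[3]], circ[[4]]), 0.2)
})

test_that("SMARTS matching handles hits, misses and bad patterns", {
  m <- mt(c("c1ccccc1", "CCO"))
  expect_identical(match_smarts(m, "c1ccccc1"), c(TRUE, FALSE))
  expect_identical(match_smarts(m, "[CX3](=O)"), c(FALSE, FALSE))
  expect_error(match_smarts(m, "(["), class = "molforge_smarts_error")
})

test_that("Murcko frameworks strip substituents and genericise", {
  expect_identical(murcko_framework(mt("Cc1ccccc1")), can("c1ccccc1"))
  expect_identical(murcko_framework(mt("c1ccncc1"), "generic"),
                   can("C1CCCCC1"))
  expect_identical(murcko_framework(mt("CCCCCC")), "")
  # carbonyl attached to the retained core stays at scaffold level
  expect_identical(murcko_framework(mt("O=C(C)N1CCCCC1")),
                   can("O=CN1CCCCC1"))
})

test_that("table round-trips preserve id, structure and numeric properties", {
  tab <- compute_properties(corpus_30()[1:10, ])
  for (fmt in c("csv_with_smiles", "smi", "sdf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_molecules(tab, path, fmt)
    back <- read_molecules(path, fmt)
    expect_identical(back$records$id, tab$id, info = fmt)
    expect_identical(back$records$smiles, tab$smiles, info = fmt)
    if (fmt != "smi") {
      expect_equal(back$records$MW, tab$MW, tolerance = 1e-9, info = fmt)
    }
  }
})

test_that("malformed rows are rejected, not fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "a,CCO", "b,C1CC", "c,c1ccccc1"), path)
  res <- read_molecules(path, "csv_with_smiles")
  expect_equal(nrow(res$records), 2)
  expect_equal(nrow(res$rejects), 1)
  expect_match(res$rejects$reason, "parse")
  # smi with missing ids auto-assigns
  p2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "c1ccccc1 benz"), p2)
  r2 <- read_molecules(p2, "smi")
  expect_identical(r2$records$id, c("mol_0001", "benz"))
})

test_that("SMARTS liability lists parse with comments and validate", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# alerts", "[N+](=O)[O-] nitro", "", "[SX2H] thiol"), path)
  alerts <- read_smarts_list(path)
  expect_identical(alerts$id, c("nitro", "thiol"))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("([", bad)
  expect_error(read_smarts_list(bad), class = "molforge_smarts_error")
})
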