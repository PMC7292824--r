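make_profile_files <- function(dir) {
  xml <- file.path(dir, "p.xml")
  json <- file.path(dir, "p.json")
  writeLines(paste0(
    '<profile mode="sum" top_n="5">',
    '<criterion property="MW" min="0" max="500" gradient="0.01" hard="false"/>',
    '<criterion property="clogP" max="5" gradient="0.1" hard="false"/>',
    '</profile>'), xml)
  writeLines(paste0(
    '{"mode":"sum","top_n":5,"criteria":[',
    '{"property":"MW","min":0,"max":500,"gradient":0.01,"hard":false},',
    '{"property":"clogP","max":5,"gradient":0.1,"hard":false}]}'), json)
  list(xml = xml, json = json)
}

test_that("XML and JSON profile dialects load to the same profile", {
  dir <- withr::local_tempdir()
  files <- make_profile_files(dir)
  px <- load_profile(files$xml)
  pj <- load_profile(files$json)
  expect_equal(px$criteria, pj$criteria)
  expect_identical(px$mode, pj$mode)
  expect_identical(px$top_n, pj$top_n)
  expect_equal(nrow(px$criteria), 2)
})

test_that("invalid profiles are rejected with informative errors", {
  expect_error(score_profile("MW", min = 10, max = 5),
               class = "molforge_validation_error")
  expect_error(score_profile("MW", gradient = -1),
               class = "molforge_validation_error")
  err <- tryCatch(
    score_profile("not_a_property", known_properties = c("MW", "clogP")),
    error = function(e) conditionMessage(e))
  expect_match(err, "not_a_property")
  expect_match(err, "MW")  # names the known properties
})

test_that("profile filter partitions input with per-criterion reasons", {
  mols <- mt(c("CCO", "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"))
  res <- profile_filter(mols, "oral")
  expect_equal(nrow(res$pass) + nrow(res$fail), nrow(mols))
  expect_equal(length(intersect(res$pass$id, res$fail$id)), 0)
  expect_true(mols$id[1] %in% res$pass$id)
  expect_true(mols$id[2] %in% res$fail$id)
  expect_match(res$fail$reason, "MW|clogP")
  expect_warning(profile_filter(mt(character(0)), "oral"), "empty")
})

test_that("inhaled preset tightens clogP and PFI windows", {
  oral <- default_profile("oral")
  inhaled <- default_profile("inhaled")
  gmax <- function(p, prop) p$criteria$max[p$criteria$property == prop]
  expect_equal(gmax(inhaled, "clogP"), 3)
  expect_equal(gmax(inhaled, "PFI_proxy"), 5)
  expect_equal(gmax(inhaled, "MW"), gmax(oral, "MW"))
})

test_that("liability filter annotates all matching patterns", {
  alerts <- data.frame(id = c("aromatic_nitro", "thiol"),
                       pattern = c("c[N+](=O)[O-]", "[SX2H]"))
  mols <- mt(c("O=[N+]([O-])c1ccccc1", "CCO", "SCc1ccc(cc1)[N+](=O)[O-]"))
  res <- liability_filter(mols, alerts)
  expect_equal(nrow(res$pass) + nrow(res$fail), 3)
  expect_true(mols$id[2] %in% res$pass$id)
  expect_match(res$fail$reason[res$fail$id == mols$id[3]], "aromatic_nitro")
  expect_match(res$fail$reason[res$fail$id == mols$id[3]], "thiol")
  # empty alert list: everything passes
  none <- liability_filter(mols, alerts[integer(0), ])
  expect_equal(nrow(none$pass), 3)
})

test_that("smarts task include/exclude partition the input", {
  mols <- corpus_30()
  pat <- "C(=O)N"
  inc <- smarts_task(mols, pat, "include")
  exc <- smarts_task(mols, pat, "exclude")
  expect_equal(nrow(inc) + nrow(exc), nrow(mols))
  expect_length(intersect(inc$id, exc$id), 0)
  expect_warning(smarts_task(mols, "[Po]", "include"), "no molecules")
})

test_that("desirability obeys the piecewise-linear formula with clamping", {
  prof <- score_profile("MW", min = 100, max = 200, gradient = 0.05)
  fake <- data.frame(id = letters[1:6], smiles = "C",
                     MW = c(150, 100, 200, 210, 220, 1000))
  sc <- desirability(fake, prof)
  # hand-computed grid: inside -> 1; max+10 at g=0.05 -> 0.5; far -> clamp 0
  expect_equal(sc$score_MW, c(1, 1, 1, 0.5, 0, 0))
  expect_equal(sc$score_total, sc$score_MW)
  # below-window side
  prof2 <- score_profile("MW", min = 100, max = 200, gradient = 0.01)
  sc2 <- desirability(data.frame(id = "x", smiles = "C", MW = 40), prof2)
  expect_equal(sc2$score_MW, 1 - 0.01 * 60)
  # missing value scores zero and is flagged
  sc3 <- desirability(data.frame(id = "x", smiles = "C", MW = NA_real_),
                      prof)
  expect_equal(sc3$score_MW, 0)
  expect_true(sc3$score_flagged)
})

test_that("desirability totals are bounded and monotone in distance", {
  prof <- score_profile(c("MW", "clogP"), min = c(0, -1), max = c(400, 3),
                        gradient = c(0.01, 0.2))
  mws <- seq(400, 800, by = 50)
  sc <- desirability(data.frame(id = as.character(mws), smiles = "C",
                                MW = mws, clogP = 1), prof)
  expect_true(all(sc$score_total >= 0 & sc$score_total <= 2))
  expect_true(all(diff(sc$score_total) <= 0))
})

test_that("pareto ranks match the brute-force dominance oracle", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(2:60, 1)
    m <- sample(2:5, 1)
    s <- matrix(round(stats::runif(n * m), sample(1:3, 1)), n, m)
    expect_identical(pareto_rank(s), pareto_oracle(s),
                     info = paste("rep", rep))
  }
  # hand cases
  expect_identical(pareto_rank(rbind(c(2, 2), c(1, 1))), c(1L, 2L))
  expect_identical(pareto_rank(rbind(c(1, 1), c(1, 1))), c(1L, 1L))
})

test_that("the first Pareto front is invariant to monotone transforms", {
  set.seed(7)
  s <- matrix(stats::runif(150), 50, 3)
  r1 <- pareto_rank(s)
  s2 <- s
  s2[, 2] <- exp(3 * s2[, 2])  # strictly monotone on one criterion
  r2 <- pareto_rank(s2)
  expect_identical(which(r1 == 1L), which(r2 == 1L))
})

test_that("top-N respects whole Pareto fronts and breaks sum ties by id", {
  # construct fronts of sizes 4 and 9: rank-1 points mutually incomparable
  f1 <- cbind(1:4, 5:2 + 10)            # front of 4
  f2 <- cbind(1:9 - 10, 9:1 - 10)       # dominated front of 9
  tab <- data.frame(id = sprintf("c%02d", 1:13), smiles = "C",
                    score_a = c(f1[, 1], f2[, 1]),
                    score_b = c(f1[, 2], f2[, 2]),
                    score_total = 0)
  got <- top_n_compounds(tab, 10, "pareto",
                         score_cols = c("score_a", "score_b"))
  expect_equal(nrow(got), 13)  # 4 + 9, front never split
  got4 <- top_n_compounds(tab, 3, "pareto",
                          score_cols = c("score_a", "score_b"))
  expect_equal(nrow(got4), 4)
  # sum mode determinism under ties
  tied <- data.frame(id = c("b", "a", "c"), smiles = "C",
                     score_total = c(1, 1, 0))
  expect_identical(top_n_compounds(tied, 2, "sum")$id, c("a", "b"))
  expect_identical(top_n_compounds(tied, 10, "sum")$id, c("a", "b", "c"))
})

test_that("sphere-exclusion clustering is deterministic and groups duplicates", {
  mols <- rbind(corpus_30()[1:6, ],
                transform(corpus_30()[1, ], id = "dup1"))
  cl1 <- sphere_exclusion_cluster(mols, 0.65)
  cl2 <- sphere_exclusion_cluster(mols, 0.65)
  expect_identical(cl1, cl2)
  expect_equal(length(cl1$cluster), nrow(mols))
  # a duplicate joins its original's cluster
  expect_equal(cl1$cluster[7], cl1$cluster[1])
  # near-1 threshold: every distinct structure founds its own cluster
  hi <- sphere_exclusion_cluster(corpus_30()[1:6, ], 0.999)
  expect_equal(length(unique(hi$cluster)), 6)
})

test_that("annotation adds review columns without dropping molecules", {
  ann <- annotate_results(corpus_30()[1:8, ])
  expect_equal(nrow(ann), 8)
  expect_true(all(c("cluster", "framework", "PFI_proxy", "change_note")
                  %in% names(ann)))
})
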