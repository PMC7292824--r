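# fixtures: a seeded corpus, pool file, seed file and scoring profile
wf_fixtures <- function(dir) {
  corp <- corpus_30()
  pool_file <- file.path(dir, "pool.csv")
  write_fragment_pool(build_fragment_pool(corp), pool_file)
  seeds_file <- file.path(dir, "seeds.csv")
  write_molecules(corp[1:3, ], seeds_file, "csv_with_smiles")
  prof_file <- file.path(dir, "prof.json")
  writeLines(paste0(
    '{"mode":"sum","criteria":[',
    '{"property":"MW","min":0,"max":400,"gradient":0.01},',
    '{"property":"clogP","min":-2,"max":3,"gradient":0.1}]}'), prof_file)
  list(pool = pool_file, seeds = seeds_file, profile = prof_file,
       corp = corp)
}

three_step_spec <- function(fx, workdir) {
  list(input = fx$seeds, workdir = workdir, steps = list(
    list(task = "generate_brics", params = list(pool_file = fx$pool)),
    list(task = "profile_filter", params = list(preset = "oral")),
    list(task = "rank", params = list(profile_file = fx$profile,
                                      top_n = 10))))
}

test_that("the registry lists all built-in tasks and rejects duplicates", {
  tasks <- list_tasks()
  expect_true(all(c("generate_brics", "generate_mmp", "profile_filter",
                    "liability_filter", "smarts_filter", "rank", "merge",
                    "sparse_design", "fit_predict", "active_learn",
                    "annotate") %in% tasks$name))
  expect_error(register_task("profile_filter", identity),
               class = "molforge_validation_error")
  expect_error(describe_task("no_such_task"),
               class = "molforge_validation_error")
})

test_that("validation enforces the generator-then-filter rule", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  good <- three_step_spec(fx, file.path(dir, "wd"))
  expect_length(validate_workflow(good), 0)
  bad <- good
  bad$steps <- bad$steps[c(1, 3)]  # generate -> rank
  errs <- validate_workflow(bad)
  expect_length(errs, 1)
  expect_match(errs, "generator")
  ending <- good
  ending$steps <- ending$steps[1]
  expect_match(validate_workflow(ending), "generator")
})

test_that("validation reports unknown tasks, bad params and broken contracts", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  spec <- list(input = fx$seeds, workdir = file.path(dir, "wd"),
               steps = list(
                 list(task = "no_such_task", params = list()),
                 list(task = "rank", params = list(bogus = 1))))
  errs <- validate_workflow(spec)
  expect_true(any(grepl("unknown task: no_such_task", errs)))
  expect_true(any(grepl("missing required parameter profile_file", errs)))
  expect_true(any(grepl("unknown parameter", errs)))
  # contract: a design table does not feed a molecule task
  spec2 <- list(input = fx$seeds, workdir = file.path(dir, "wd2"),
                steps = list(
                  list(task = "sparse_design",
                       params = list(levels = c(4, 4), M = 8)),
                  list(task = "rank",
                       params = list(profile_file = fx$profile))))
  errs2 <- validate_workflow(spec2)
  expect_true(any(grepl("lacks required column", errs2)))
  expect_true(any(grepl("smiles", errs2)))
})

test_that("a three-step chain runs, logs and keeps conservation counts", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  spec <- three_step_spec(fx, file.path(dir, "wd"))
  res <- suppressWarnings(run_workflow(spec))
  expect_true(all(file.exists(res$artifacts)))
  log <- lapply(readLines(res$log), jsonlite::fromJSON)
  expect_equal(length(log), 3)
  expect_true(all(vapply(log, `[[`, character(1), "status") == "ok"))
  # auditability: counts per step recoverable from the log alone
  gen_out <- log[[1]]$n_out
  filt <- log[[2]]
  expect_equal(filt$n_in, gen_out)
  expect_equal(filt$n_in, filt$n_out + filt$n_reject)
  ranked <- utils::read.csv(res$artifacts[3])
  expect_lte(nrow(ranked), 10)
  expect_equal(nrow(ranked), log[[3]]$n_out)
})

test_that("seeded workflows are byte-identical across runs", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  r1 <- suppressWarnings(run_workflow(three_step_spec(fx,
                                                      file.path(dir, "a"))))
  r2 <- suppressWarnings(run_workflow(three_step_spec(fx,
                                                      file.path(dir, "b"))))
  for (i in 1:3) {
    expect_identical(readLines(r1$artifacts[i]), readLines(r2$artifacts[i]))
  }
})

test_that("a failing step stops the chain; resume restarts mid-way", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  wd <- file.path(dir, "wd")
  spec <- three_step_spec(fx, wd)
  spec$steps[[3]]$params$profile_file <- file.path(dir, "missing.json")
  expect_error(suppressWarnings(run_workflow(spec)), "step 3")
  # steps 1-2 artifacts exist, step 3 has no output
  expect_true(file.exists(file.path(wd, "step_01_generate_brics",
                                    "output.csv")))
  expect_false(file.exists(file.path(wd, "step_03_rank", "output.csv")))
  log <- lapply(readLines(file.path(wd, "run_log.jsonl")), jsonlite::fromJSON)
  expect_identical(log[[length(log)]]$status, "failed")
  # fix the parameter and resume from step 3 without re-running step 1
  stamp <- file.mtime(file.path(wd, "step_01_generate_brics", "output.csv"))
  spec$steps[[3]]$params$profile_file <- fx$profile
  res <- suppressWarnings(run_workflow(spec, resume = 3))
  expect_true(file.exists(res$artifacts[3]))
  expect_identical(file.mtime(file.path(wd, "step_01_generate_brics",
                                        "output.csv")), stamp)
})

test_that("workdir collisions require force", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  spec <- three_step_spec(fx, file.path(dir, "wd"))
  suppressWarnings(run_workflow(spec))
  expect_error(run_workflow(spec), "force")
  expect_silent(suppressWarnings(run_workflow(spec, force = TRUE)))
})

test_that("merge unions tables, first provenance wins, self-merge is identity", {
  corp <- corpus_30()
  machine <- corp[1:20, ]
  human <- corp[16:25, ]            # 5 structural duplicates of machine set
  human$id <- paste0("h_", human$id)
  res <- merge_tables(list(machine, human), c("machine", "human"))
  expect_equal(nrow(res$output), 25)
  expect_equal(nrow(res$rejects), 5)
  dup_rows <- res$output[res$output$smiles %in% corp$smiles[16:20], ]
  expect_true(all(dup_rows$source_label == "machine"))  # first seen wins
  expect_true(all(nzchar(res$output$source_label)))
  self <- merge_tables(list(machine, machine))
  expect_equal(nrow(self$output), nrow(machine))
})

test_that("branching reuses artifacts and rejects missing ones", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  res <- suppressWarnings(run_workflow(three_step_spec(fx,
                                                       file.path(dir, "wd"))))
  inp <- branch_input(res$artifacts[2])
  spec2 <- list(input = as.character(inp), workdir = file.path(dir, "wd2"),
                steps = list(list(task = "annotate", params = list())))
  res2 <- run_workflow(spec2)
  expect_true(file.exists(res2$artifacts[1]))
  expect_error(branch_input(file.path(dir, "nope.csv")),
               class = "molforge_validation_error")
})

test_that("workflow JSON round-trips through the reader", {
  dir <- withr::local_tempdir()
  fx <- wf_fixtures(dir)
  path <- file.path(dir, "wf.json")
  writeLines(jsonlite::toJSON(list(
    input = fx$seeds, workdir = file.path(dir, "wd"),
    steps = list(list(task = "generate_brics",
                      params = list(pool_file = fx$pool)),
                 list(task = "profile_filter",
                      params = list(preset = "oral")))),
    auto_unbox = TRUE), path)
  spec <- read_workflow(path)
  expect_length(validate_workflow(spec), 0)
  expect_identical(spec$steps[[1]]$task, "generate_brics")
})
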