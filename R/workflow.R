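# Workflow engine: a registry of Tasks with parameter schemas and column
# contracts, validation of linear Task chains (including the best-practice
# rule that a molecule generator must be followed immediately by a profile
# filter), execution over file-based artifacts with structured logging,
# merge, and branching by artifact reuse.

.molforge_registry <- new.env(parent = emptyenv())

#' Register a workflow task
#'
#' @param name unique task name.
#' @param fun callable `function(input, params, ctx)` returning
#'   `list(output = data.frame, rejects = data.frame or NULL)`.
#' @param description one-line description.
#' @param schema named list of parameter specs: each
#'   `list(type, default, required)`.
#' @param input_cols columns the task requires on its input table.
#' @param output_cols columns the task guarantees on its output; `"*"`
#'   means the input columns pass through (plus any named additions).
#' @param role `"generator"`, `"filter"` or `"other"` — drives the
#'   best-practice connectivity rules.
#' @return the registry entry, invisibly.
#' @export
register_task <- function(name, fun, description = "", schema = list(),
                          input_cols = c("id", "smiles"),
                          output_cols = "*", role = "other") {
  if (!is.null(.molforge_registry[[name]])) {
    validation_error(paste0("task already registered: ", name))
  }
  entry <- list(name = name, fun = fun, description = description,
                schema = schema, input_cols = input_cols,
                output_cols = output_cols, role = role)
  assign(name, entry, envir = .molforge_registry)
  invisible(entry)
}

#' List registered tasks
#' @return data.frame(name, role, description).
#' @export
list_tasks <- function() {
  ensure_builtin_tasks()
  nm <- sort(ls(.molforge_registry))
  data.frame(
    name = nm,
    role = vapply(nm, function(n) .molforge_registry[[n]]$role, character(1)),
    description = vapply(nm, function(n) .molforge_registry[[n]]$description,
                         character(1)),
    row.names = NULL)
}

#' Describe one task's parameters and contracts
#' @param name task name.
#' @return the registry entry.
#' @export
describe_task <- function(name) {
  ensure_builtin_tasks()
  entry <- .molforge_registry[[name]]
  if (is.null(entry)) validation_error(paste0("unknown task: ", name))
  entry
}

# best-practice connectivity rules, data-driven so new rules need no code
# change: a step whose role matches `after_role` must be immediately
# followed by a step whose role matches `next_role`.
.best_practice_rules <- data.frame(
  after_role = "generator",
  next_role = "filter",
  message = "a molecule generator must be immediately followed by a profile/liability filter"
)

.validate_params <- function(entry, params) {
  errs <- character(0)
  params <- params %||% list()
  unknown <- setdiff(names(params), names(entry$schema))
  if (length(unknown)) {
    errs <- c(errs, sprintf("task %s: unknown parameter(s) %s", entry$name,
                            paste(unknown, collapse = ", ")))
  }
  for (p in names(entry$schema)) {
    sc <- entry$schema[[p]]
    if (isTRUE(sc$required) && is.null(params[[p]])) {
      errs <- c(errs, sprintf("task %s: missing required parameter %s",
                              entry$name, p))
    }
    if (!is.null(params[[p]]) && !is.null(sc$type)) {
      ok <- switch(sc$type,
                   numeric = is.numeric(params[[p]]),
                   character = is.character(params[[p]]),
                   logical = is.logical(params[[p]]),
                   TRUE)
      if (!ok) {
        errs <- c(errs, sprintf("task %s: parameter %s must be %s",
                                entry$name, p, sc$type))
      }
    }
  }
  errs
}

# resolve a parameter with schema default
.param <- function(entry, params, name) {
  params[[name]] %||% entry$schema[[name]]$default
}

#' Validate a workflow specification
#'
#' Checks that every task is registered, parameters satisfy their schemas,
#' column contracts are compatible step to step, and the best-practice
#' connectivity rules hold (the shipped rule: generators must be followed
#' immediately by a filter step — merging or ranking unfiltered generator
#' output is rejected). All violations are reported together.
#'
#' @param spec workflow spec: `list(input=, workdir=, steps=list(
#'   list(task=, params=), ...))`, e.g. from [read_workflow()].
#' @param input_cols columns of the initial input (read from the input file
#'   when it exists).
#' @return character vector of violations; empty when the workflow is valid.
#' @export
validate_workflow <- function(spec, input_cols = NULL) {
  ensure_builtin_tasks()
  errs <- character(0)
  steps <- spec$steps
  if (!length(steps)) return("workflow has no steps")
  if (is.null(input_cols) && !is.null(spec$input) &&
      file.exists(spec$input)) {
    input_cols <- names(utils::read.csv(spec$input, nrows = 1,
                                        check.names = FALSE))
  }
  avail <- input_cols
  entries <- list()
  for (i in seq_along(steps)) {
    nm <- steps[[i]]$task
    entry <- .molforge_registry[[nm %||% "<missing>"]]
    if (is.null(entry)) {
      errs <- c(errs, sprintf("step %d: unknown task: %s", i, nm))
      entries[[i]] <- NULL
      avail <- NULL
      next
    }
    entries[[i]] <- entry
    errs <- c(errs, .validate_params(entry, steps[[i]]$params))
    if (!is.null(avail)) {
      missing <- setdiff(entry$input_cols, avail)
      if (length(missing)) {
        errs <- c(errs, sprintf(
          "step %d (%s): input lacks required column(s): %s", i, nm,
          paste(missing, collapse = ", ")))
      }
    }
    avail <- if (identical(entry$output_cols, "*")) {
      avail
    } else if ("*" %in% entry$output_cols) {
      union(avail, setdiff(entry$output_cols, "*"))
    } else {
      entry$output_cols
    }
  }
  for (i in seq_len(length(steps) - 1L)) {
    e1 <- entries[[i]]
    e2 <- entries[[i + 1L]]
    if (is.null(e1) || is.null(e2)) next
    hit <- .best_practice_rules$after_role == e1$role
    if (any(hit) && !.best_practice_rules$next_role[hit][1] == e2$role) {
      errs <- c(errs, sprintf("step %d -> %d: %s", i, i + 1L,
                              .best_practice_rules$message[hit][1]))
    }
  }
  last <- entries[[length(steps)]]
  if (!is.null(last)) {
    hit <- .best_practice_rules$after_role == last$role
    if (any(hit)) {
      errs <- c(errs, sprintf("step %d: %s (workflow ends on a generator)",
                              length(steps),
                              .best_practice_rules$message[hit][1]))
    }
  }
  errs
}

#' Read / write a workflow JSON file
#'
#' Schema: `{"input": path, "workdir": path, "steps": [{"task": name,
#' "params": {...}}, ...]}` — one single JSON object of parameters per task.
#'
#' @param path JSON file.
#' @return workflow spec list.
#' @export
read_workflow <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$steps)) validation_error("workflow JSON needs 'steps'")
  spec$steps <- lapply(spec$steps, function(s) {
    list(task = s$task, params = lapply(s$params %||% list(), function(p) {
      if (is.list(p)) unlist(p) else p
    }))
  })
  spec
}

#' Run a validated workflow
#'
#' Each step reads its predecessor's artifact, writes
#' `workdir/step_NN_<task>/output.csv` (plus `rejects.csv` when the task
#' rejects rows) and appends a structured JSON log line (task, input/output/
#' reject counts, parameters, status) to `workdir/run_log.jsonl`. A step
#' failure stops the chain with the failing step identified. `resume`
#' restarts from a given step index, reusing stored artifacts of earlier
#' steps.
#'
#' @param spec workflow spec (validated first; errors abort).
#' @param resume step index to restart from.
#' @param force overwrite an existing workdir.
#' @return list(artifacts = per-step output paths, log = log file path).
#' @export
run_workflow <- function(spec, resume = NULL, force = FALSE) {
  ensure_builtin_tasks()
  errs <- validate_workflow(spec)
  if (length(errs)) {
    validation_error(paste0("invalid workflow:\n  ",
                            paste(errs, collapse = "\n  ")))
  }
  workdir <- spec$workdir %||% validation_error("workflow needs a workdir")
  if (is.null(resume)) {
    if (dir.exists(workdir) && length(list.files(workdir)) && !force) {
      validation_error(paste0("workdir exists (use force = TRUE): ", workdir))
    }
    dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  }
  logfile <- file.path(workdir, "run_log.jsonl")
  step_dir <- function(i) {
    file.path(workdir, sprintf("step_%02d_%s", i, spec$steps[[i]]$task))
  }
  artifacts <- vapply(seq_along(spec$steps),
                      function(i) file.path(step_dir(i), "output.csv"),
                      character(1))
  start <- resume %||% 1L
  if (start > 1L && !file.exists(artifacts[start - 1L])) {
    validation_error(sprintf("cannot resume at step %d: missing artifact %s",
                             start, artifacts[start - 1L]))
  }
  for (i in seq(start, length(spec$steps))) {
    st <- spec$steps[[i]]
    entry <- .molforge_registry[[st$task]]
    in_path <- if (i == 1L) spec$input else artifacts[i - 1L]
    input <- utils::read.csv(in_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    dir.create(step_dir(i), recursive = TRUE, showWarnings = FALSE)
    ctx <- list(step_dir = step_dir(i), workdir = workdir, step = i)
    res <- tryCatch(entry$fun(input, st$params %||% list(), ctx),
                    error = function(e) e)
    if (inherits(res, "error")) {
      .log_step(logfile, i, st, nrow(input), NA_integer_, NA_integer_,
                "failed", conditionMessage(res))
      validation_error(sprintf("step %d (%s) failed: %s", i, st$task,
                               conditionMessage(res)))
    }
    utils::write.csv(res$output, artifacts[i], row.names = FALSE)
    n_rej <- 0L
    if (!is.null(res$rejects) && nrow(res$rejects)) {
      utils::write.csv(res$rejects, file.path(step_dir(i), "rejects.csv"),
                       row.names = FALSE)
      n_rej <- nrow(res$rejects)
    }
    .log_step(logfile, i, st, nrow(input), nrow(res$output), n_rej, "ok")
  }
  list(artifacts = artifacts, log = logfile)
}

.log_step <- function(logfile, i, st, n_in, n_out, n_rej, status,
                      message = NULL) {
  line <- jsonlite::toJSON(list(
    step = i, task = st$task, params = st$params %||% list(),
    n_in = n_in, n_out = n_out, n_reject = n_rej, status = status,
    message = message, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    auto_unbox = TRUE, null = "null")
  cat(line, "\n", file = logfile, append = TRUE, sep = "")
}

#' Merge molecule tables from several sources
#'
#' Union of the inputs deduplicated by canonical structure; the first-seen
#' row wins and duplicates are logged in the reject table. A `source_label`
#' column records provenance, so machine- and human-generated ideas flow
#' through the same downstream tasks.
#'
#' @param tables list of molecule tables.
#' @param labels provenance label per table.
#' @return list(output, rejects).
#' @export
merge_tables <- function(tables, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("source_%d", seq_along(tables))
  stopifnot(length(labels) == length(tables))
  for (t in tables) {
    if (!all(c("id", "smiles") %in% names(t))) {
      validation_error("every merged table needs id and smiles columns")
    }
  }
  all_cols <- unique(unlist(lapply(tables, names)))
  tabs <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    for (cc in setdiff(all_cols, names(t))) t[[cc]] <- NA
    t$source_label <- labels[i]
    t[c(all_cols, "source_label")]
  })
  big <- do.call(rbind, tabs)
  dup <- duplicated(big$smiles)
  rejects <- big[dup, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- "duplicate structure"
  out <- big[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(output = out, rejects = rejects)
}

#' Use a previous run's artifact as the input of a new workflow
#'
#' Branching by output reuse: any intermediate artifact can seed multiple
#' new designs.
#'
#' @param artifact_path path to a step's `output.csv`.
#' @return the path, validated, with the source recorded as an attribute.
#' @export
branch_input <- function(artifact_path) {
  if (!file.exists(artifact_path)) {
    validation_error(paste0("missing artifact: ", artifact_path))
  }
  structure(artifact_path, source_run = dirname(artifact_path))
}
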