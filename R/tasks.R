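# Built-in workflow tasks. Each is a thin adapter from the file/table
# interface of the engine onto the package's functions.

ensure_builtin_tasks <- function() {
  if (!is.null(.molforge_registry[["profile_filter"]])) return(invisible())

  register_task(
    "generate_brics",
    function(input, params, ctx) {
      entry <- .molforge_registry[["generate_brics"]]
      pool <- read_fragment_pool(params$pool_file)
      outs <- lapply(seq_len(nrow(input)), function(i) {
        enumerate_brics_analogues(
          input[i, , drop = FALSE], pool,
          mode = .param(entry, params, "mode"),
          n = params$n, seed = params$seed,
          relax_ring_labels = isTRUE(params$relax_ring_labels),
          allow_insert = isTRUE(params$allow_insert),
          allow_delete = isTRUE(params$allow_delete),
          max_per_position = .param(entry, params, "max_per_position"))
      })
      out <- do.call(rbind, outs)
      out <- out[!duplicated(out$smiles), , drop = FALSE]
      if (!nrow(out)) warning("generate_brics: no analogues produced")
      list(output = out)
    },
    description = "BRICS fragment-replacement analogues from a fragment pool",
    schema = list(
      pool_file = list(type = "character", required = TRUE),
      mode = list(type = "character", default = "exhaustive"),
      n = list(type = "numeric"), seed = list(type = "numeric"),
      relax_ring_labels = list(type = "logical", default = FALSE),
      allow_insert = list(type = "logical", default = FALSE),
      allow_delete = list(type = "logical", default = FALSE),
      max_per_position = list(type = "numeric", default = Inf)),
    input_cols = c("id", "smiles"),
    output_cols = c("id", "smiles", "method", "seed_id", "change_note"),
    role = "generator")

  register_task(
    "generate_mmp",
    function(input, params, ctx) {
      rules <- read_transforms(params$transforms_file)
      outs <- lapply(seq_len(nrow(input)), function(i) {
        apply_mmp_transforms(input[i, , drop = FALSE], rules)
      })
      out <- do.call(rbind, outs)
      out <- out[!duplicated(out$smiles), , drop = FALSE]
      if (!nrow(out)) warning("generate_mmp: no analogues produced")
      list(output = out)
    },
    description = "Matched-molecular-pair transform analogues",
    schema = list(transforms_file = list(type = "character",
                                         required = TRUE)),
    input_cols = c("id", "smiles"),
    output_cols = c("id", "smiles", "method", "seed_id", "change_note"),
    role = "generator")

  register_task(
    "profile_filter",
    function(input, params, ctx) {
      entry <- .molforge_registry[["profile_filter"]]
      profile <- if (!is.null(params$profile_file)) {
        load_profile(params$profile_file)
      } else {
        default_profile(.param(entry, params, "preset"))
      }
      res <- profile_filter(input, profile)
      list(output = res$pass, rejects = res$fail)
    },
    description = "Hard target-compound-profile property filter",
    schema = list(preset = list(type = "character", default = "oral"),
                  profile_file = list(type = "character")),
    input_cols = c("id", "smiles"),
    output_cols = c("*", .known_properties),
    role = "filter")

  register_task(
    "liability_filter",
    function(input, params, ctx) {
      alerts <- read_smarts_list(params$smarts_file)
      res <- liability_filter(input, alerts)
      list(output = res$pass, rejects = res$fail)
    },
    description = "SMARTS liability (undesirable chemotype) filter",
    schema = list(smarts_file = list(type = "character", required = TRUE)),
    input_cols = c("id", "smiles"),
    output_cols = "*",
    role = "filter")

  register_task(
    "smarts_filter",
    function(input, params, ctx) {
      entry <- .molforge_registry[["smarts_filter"]]
      out <- smarts_task(input, params$pattern,
                         .param(entry, params, "mode"))
      list(output = out)
    },
    description = "Keep (include) or drop (exclude) molecules matching a SMARTS",
    schema = list(pattern = list(type = "character", required = TRUE),
                  mode = list(type = "character", default = "include")),
    input_cols = c("id", "smiles"),
    output_cols = "*",
    role = "other")

  register_task(
    "rank",
    function(input, params, ctx) {
      entry <- .molforge_registry[["rank"]]
      profile <- load_profile(params$profile_file)
      scored <- desirability(input, profile)
      mode <- params$mode %||% profile$mode
      n <- params$top_n %||% profile$top_n %||% nrow(scored)
      list(output = top_n_compounds(scored, n, mode))
    },
    description = "Desirability scoring and sum/Pareto ranking",
    schema = list(profile_file = list(type = "character", required = TRUE),
                  mode = list(type = "character"),
                  top_n = list(type = "numeric")),
    input_cols = c("id", "smiles"),
    output_cols = "*",
    role = "other")

  register_task(
    "merge",
    function(input, params, ctx) {
      entry <- .molforge_registry[["merge"]]
      extra <- lapply(params$files, function(f) {
        read_molecules(f, "csv_with_smiles")$records
      })
      labels <- params$labels %||%
        c("main", sprintf("extra_%d", seq_along(extra)))
      merge_tables(c(list(input), extra), labels)
    },
    description = "Union of molecule tables, deduplicated by structure",
    schema = list(files = list(type = "character", required = TRUE),
                  labels = list(type = "character")),
    input_cols = c("id", "smiles"),
    output_cols = c("*", "source_label"),
    role = "other")

  register_task(
    "annotate",
    function(input, params, ctx) {
      entry <- .molforge_registry[["annotate"]]
      list(output = annotate_results(
        input, .param(entry, params, "cluster_threshold")))
    },
    description = "Cluster ids, Murcko frameworks and PFI for review",
    schema = list(cluster_threshold = list(type = "numeric",
                                           default = 0.65)),
    input_cols = c("id", "smiles"),
    output_cols = c("*", "cluster", "framework", "PFI_proxy"),
    role = "other")

  register_task(
    "sparse_design",
    function(input, params, ctx) {
      entry <- .molforge_registry[["sparse_design"]]
      spec <- plan_replicates(params$levels, M = params$M,
                              fraction = params$fraction)
      cells <- generate_balanced_design(
        spec, seed = .param(entry, params, "seed"))
      check_design(cells, spec)
      cells$cell_id <- sprintf("cell_%04d", seq_len(nrow(cells)))
      list(output = cells)
    },
    description = "Equally sampled sparse-array design (cells as coordinates)",
    schema = list(levels = list(type = "numeric", required = TRUE),
                  M = list(type = "numeric"),
                  fraction = list(type = "numeric"),
                  seed = list(type = "numeric", default = 1)),
    input_cols = character(0),
    output_cols = c("f1", "f2", "f3", "cell_id"),
    role = "other")

  register_task(
    "fit_predict",
    function(input, params, ctx) {
      entry <- .molforge_registry[["fit_predict"]]
      model <- fit_freewilson(input)
      write_freewilson(model, file.path(ctx$step_dir, "model.json"))
      preds <- predict_freewilson(model)
      n <- params$top_n %||% nrow(preds)
      list(output = top_predictions(
        preds, n, isTRUE(params$exclude_observed)))
    },
    description = "Free-Wilson fit and prediction of all monomer combinations",
    schema = list(top_n = list(type = "numeric"),
                  exclude_observed = list(type = "logical",
                                          default = FALSE)),
    input_cols = c("id", "m1", "m2", "response"),
    output_cols = c("m1", "m2", "m3", "pred", "se", "observed"),
    role = "other")

  register_task(
    "active_learn",
    function(input, params, ctx) {
      entry <- .molforge_registry[["active_learn"]]
      train <- utils::read.csv(params$train_file, stringsAsFactors = FALSE)
      cfg <- al_config(
        batch_size = .param(entry, params, "batch_size"),
        explore_fraction = .param(entry, params, "explore_fraction"),
        n_trees = .param(entry, params, "n_trees"),
        featurisation = .param(entry, params, "featurisation"),
        seed = .param(entry, params, "seed"))
      model <- al_build_model(train, cfg)
      preds <- al_predict(model, input)
      sel <- al_select_batch(preds, cfg)
      out <- merge(sel, input, by = "id", sort = FALSE)
      list(output = out[order(match(out$id, sel$id)), , drop = FALSE])
    },
    description = "Explore/exploit batch selection from a candidate pool",
    schema = list(train_file = list(type = "character", required = TRUE),
                  batch_size = list(type = "numeric", default = 50),
                  explore_fraction = list(type = "numeric", default = 0.2),
                  n_trees = list(type = "numeric", default = 100),
                  featurisation = list(type = "character",
                                       default = "circular2"),
                  seed = list(type = "numeric", default = 1)),
    input_cols = c("id", "smiles"),
    output_cols = c("*", "pred", "uncertainty", "category"),
    role = "other")

  invisible()
}

#' Persist / load a Free-Wilson model as JSON
#'
#' @param model a `freewilson_model`.
#' @param path JSON file.
#' @export
write_freewilson <- function(model, path) {
  jsonlite::write_json(list(
    intercept = model$intercept, intercept_se = model$intercept_se,
    effects = lapply(model$effects, as.list),
    se = lapply(model$se, as.list),
    r_squared = model$r_squared, residual_sd = model$residual_sd,
    n_train = model$n_train, ridge = model$ridge),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_freewilson
#' @export
read_freewilson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$effects <- lapply(obj$effects, unlist)
  obj$se <- lapply(obj$se, unlist)
  obj
}
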