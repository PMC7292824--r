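# Pool-based batch active learning: a seeded bagged-tree (random forest)
# regressor is built and cross-validated on the measured compounds, the
# candidate pool is predicted with per-tree dispersion as the uncertainty,
# and a batch is split between Exploit (top predicted) and Explore (top
# uncertainty among the remainder).

#' Active-learning configuration
#'
#' @param batch_size number of molecules to select per iteration.
#' @param explore_fraction fraction of the batch allocated to Explore
#'   (high-uncertainty) picks; `round(explore_fraction * batch_size)`
#'   molecules.
#' @param n_trees ensemble size.
#' @param featurisation `"circular2"` (hashed circular fingerprint, folded
#'   to `fp_bits` numeric columns) or `"rgroup"` (one-hot on `m1`/`m2`
#'   monomer id columns, matching the Free-Wilson representation of
#'   array-derived pools).
#' @param fp_bits folded fingerprint width.
#' @param cv_folds cross-validation folds for the validation report.
#' @param seed RNG seed; the whole procedure is deterministic given it.
#' @return an `al_config` list.
#' @export
al_config <- function(batch_size = 50L, explore_fraction = 0.2,
                      n_trees = 100L, featurisation = c("circular2",
                                                        "rgroup"),
                      fp_bits = 256L, cv_folds = 5L, seed = 1L) {
  featurisation <- match.arg(featurisation)
  stopifnot(batch_size >= 1, explore_fraction >= 0, explore_fraction <= 1,
            n_trees >= 1, cv_folds >= 2)
  structure(list(batch_size = as.integer(batch_size),
                 explore_fraction = explore_fraction,
                 n_trees = as.integer(n_trees),
                 featurisation = featurisation,
                 fp_bits = as.integer(fp_bits),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)), class = "al_config")
}

# featurise a molecule table into a numeric matrix
.al_features <- function(mols, config, levels = NULL) {
  if (config$featurisation == "circular2") {
    fps <- fingerprint(mols, "circular2")
    m <- matrix(0L, nrow(mols), config$fp_bits)
    for (i in seq_along(fps)) {
      cols <- unique((fps[[i]]$bits - 1L) %% config$fp_bits + 1L)
      m[i, cols] <- 1L
    }
    colnames(m) <- paste0("b", seq_len(config$fp_bits))
    list(x = m, levels = NULL)
  } else {
    pos <- intersect(c("m1", "m2", "m3"), names(mols))
    if (length(pos) < 2) validation_error("rgroup featurisation needs m1/m2")
    if (is.null(levels)) {
      levels <- lapply(pos, function(p) sort(unique(as.character(mols[[p]]))))
      names(levels) <- pos
    }
    cols <- unlist(lapply(pos, function(p) paste0(p, ":", levels[[p]])))
    m <- matrix(0L, nrow(mols), length(cols),
                dimnames = list(NULL, cols))
    for (p in pos) {
      for (l in levels[[p]]) {
        m[as.character(mols[[p]]) == l, paste0(p, ":", l)] <- 1L
      }
    }
    list(x = m, levels = levels)
  }
}

#' Build and cross-validate the surrogate model
#'
#' Fits a seeded random forest (bagged trees, `n_trees`) on the full
#' training table and reports k-fold cross-validated R^2 and RMSE. A
#' constant response is refused: uncertainty-driven selection would be
#' meaningless.
#'
#' @param train molecule table with a `response` column (plus `smiles` or
#'   monomer id columns depending on the featurisation).
#' @param config an [al_config()].
#' @return an `al_model`: the forest, featurisation context and the
#'   validation report (`cv_r2`, `cv_rmse`).
#' @export
al_build_model <- function(train, config = al_config()) {
  if (!"response" %in% names(train)) validation_error("need 'response'")
  y <- train$response
  if (nrow(train) < 2 * config$cv_folds) {
    validation_error(sprintf("need at least %d training records",
                             2 * config$cv_folds))
  }
  if (stats::sd(y) == 0) {
    validation_error("constant response: model cannot rank or explore")
  }
  feat <- .al_features(train, config)
  with_seed(config$seed, {
    folds <- sample(rep(seq_len(config$cv_folds), length.out = nrow(train)))
    preds <- numeric(nrow(train))
    for (f in seq_len(config$cv_folds)) {
      hold <- folds == f
      fit <- randomForest::randomForest(
        x = feat$x[!hold, , drop = FALSE], y = y[!hold],
        ntree = config$n_trees)
      preds[hold] <- stats::predict(fit, feat$x[hold, , drop = FALSE])
    }
    cv_rmse <- sqrt(mean((preds - y)^2))
    cv_r2 <- 1 - sum((preds - y)^2) / sum((y - mean(y))^2)
    forest <- randomForest::randomForest(x = feat$x, y = y,
                                         ntree = config$n_trees)
    structure(list(forest = forest, config = config, levels = feat$levels,
                   cv_r2 = cv_r2, cv_rmse = cv_rmse,
                   n_train = nrow(train)), class = "al_model")
  })
}

#' @export
print.al_model <- function(x, ...) {
  cat(sprintf(
    "Active-learning surrogate: %d trees on %d records | CV R^2 %.3f, RMSE %.3f\n",
    x$config$n_trees, x$n_train, x$cv_r2, x$cv_rmse))
  invisible(x)
}

#' Predict a candidate pool with per-tree uncertainty
#'
#' The prediction is the mean over the individual trees; the uncertainty is
#' the standard deviation of the per-tree predictions (the dispersion of
#' the ensemble's votes).
#'
#' @param model an `al_model`.
#' @param pool molecule table featurisable like the training set.
#' @return data.frame(id, pred, uncertainty).
#' @export
al_predict <- function(model, pool) {
  feat <- .al_features(pool, model$config, model$levels)
  all_pred <- stats::predict(model$forest, feat$x, predict.all = TRUE)
  per_tree <- all_pred$individual
  unc <- if (ncol(per_tree) == 1L) {
    rep(0, nrow(per_tree))  # a single tree casts no dissenting votes
  } else {
    apply(per_tree, 1, stats::sd)
  }
  data.frame(id = pool$id,
             pred = unname(rowMeans(per_tree)),
             uncertainty = unname(unc))
}

#' Select an explore/exploit batch
#'
#' `n_explore = round(explore_fraction * batch_size)`. Exploit picks are
#' the top `batch_size - n_explore` molecules by predicted value; Explore
#' picks are the top `n_explore` by uncertainty among the pool remaining
#' after the Exploit picks (a molecule leading both lists appears once, as
#' Exploit). Ties broken by id. If the pool is smaller than the batch the
#' whole pool is returned with a warning.
#'
#' @param pool_predictions output of [al_predict()].
#' @param config an [al_config()].
#' @return data.frame(id, pred, uncertainty, category) with category in
#'   `{"Exploit", "Explore"}`.
#' @export
al_select_batch <- function(pool_predictions, config = al_config()) {
  k <- config$batch_size
  if (nrow(pool_predictions) < k) {
    warning("pool smaller than batch: selecting the whole pool")
    k <- nrow(pool_predictions)
  }
  n_explore <- round(config$explore_fraction * k)
  n_exploit <- k - n_explore
  tab <- pool_predictions
  ord_pred <- order(-tab$pred, tab$id)
  exploit <- tab[ord_pred[seq_len(n_exploit)], , drop = FALSE]
  if (nrow(exploit)) exploit$category <- "Exploit"
  rest <- tab[!tab$id %in% exploit$id, , drop = FALSE]
  ord_unc <- order(-rest$uncertainty, rest$id)
  explore <- rest[ord_unc[seq_len(min(n_explore, nrow(rest)))], ,
                  drop = FALSE]
  if (nrow(explore)) explore$category <- "Explore"
  out <- rbind(exploit, explore)
  rownames(out) <- NULL
  out
}
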