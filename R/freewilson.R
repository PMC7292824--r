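# Classical Free-Wilson analysis: additive per-position monomer
# contributions fitted by least squares on an indicator (reference-level
# one-hot) encoding, predictions for every combination of observed
# monomers, and ranking of unsynthesised predictions.

#' Fit a Free-Wilson additive R-group model
#'
#' Fits `y = mu + sum_over_positions effect(monomer)` by least squares with
#' reference-level coding: the lexicographically first monomer id at each
#' position is pinned to effect 0, so effects read as contributions versus
#' that reference. Monomers that lost all their records (e.g. to synthesis
#' attrition) are dropped from the vocabulary with a warning. If the normal
#' equations are singular (disconnected design), a small ridge penalty
#' (1e-6 on effect terms) is applied and flagged.
#'
#' @param records data.frame with columns `id`, `m1`, `m2` (optionally
#'   `m3`) and `response` (continuous, e.g. pIC50).
#' @param vocabularies optional list of expected monomer id vectors per
#'   position; unseen members are dropped with a warning.
#' @return a `freewilson_model`: intercept, per-position effect and
#'   standard-error maps, `r_squared`, `residual_sd`, `n_train`, `ridge`
#'   flag and the training combinations.
#' @export
fit_freewilson <- function(records, vocabularies = NULL) {
  pos <- intersect(c("m1", "m2", "m3"), names(records))
  if (length(pos) < 2) validation_error("need monomer columns m1, m2[, m3]")
  if (!"response" %in% names(records)) {
    validation_error("need a 'response' column")
  }
  y <- records$response
  if (any(!is.finite(y))) validation_error("responses must be finite")
  vocab <- lapply(pos, function(p) sort(unique(as.character(records[[p]]))))
  names(vocab) <- pos
  if (!is.null(vocabularies)) {
    if (is.null(names(vocabularies))) names(vocabularies) <- pos
    for (p in pos) {
      lost <- setdiff(vocabularies[[p]], vocab[[p]])
      if (length(lost)) {
        warning(sprintf(
          "position %s: monomer(s) %s have no records and are dropped from the vocabulary",
          p, paste(lost, collapse = ", ")))
      }
      extra <- setdiff(vocab[[p]], vocabularies[[p]])
      if (length(extra)) {
        validation_error(sprintf("position %s: unseen monomer id(s): %s",
                                 p, paste(extra, collapse = ", ")))
      }
    }
  }
  # design matrix: intercept + one indicator per non-reference monomer
  terms <- list()
  for (p in pos) {
    for (m in vocab[[p]][-1]) terms[[paste0(p, ":", m)]] <- c(p, m)
  }
  X <- matrix(0, nrow(records), 1L + length(terms))
  X[, 1] <- 1
  colnames(X) <- c("(intercept)", names(terms))
  for (t in seq_along(terms)) {
    p <- terms[[t]][1]
    m <- terms[[t]][2]
    X[as.character(records[[p]]) == m, t + 1L] <- 1
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  ridge <- FALSE
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta) || qr(XtX)$rank < ncol(X)) {
    ridge <- TRUE
    pen <- diag(c(0, rep(1e-6, length(terms))))
    beta <- solve(XtX + pen, Xty)
    warning("rank-deficient design: ridge fallback (penalty 1e-6) engaged")
  }
  fitted <- as.vector(X %*% beta)
  resid <- y - fitted
  dof <- max(nrow(X) - ncol(X), 1L)
  sigma2 <- sum(resid^2) / dof
  covb <- if (!ridge) {
    sigma2 * solve(XtX)
  } else {
    pen <- diag(c(0, rep(1e-6, length(terms))))
    A <- solve(XtX + pen)
    sigma2 * A %*% XtX %*% A
  }
  se <- sqrt(pmax(diag(covb), 0))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else 1
  effects <- ses <- list()
  for (p in pos) {
    eff <- stats::setNames(numeric(length(vocab[[p]])), vocab[[p]])
    s <- stats::setNames(numeric(length(vocab[[p]])), vocab[[p]])
    for (m in vocab[[p]][-1]) {
      idx <- match(paste0(p, ":", m), colnames(X))
      eff[m] <- beta[idx]
      s[m] <- se[idx]
    }
    effects[[p]] <- eff
    ses[[p]] <- s
  }
  structure(list(
    intercept = beta[1], intercept_se = se[1],
    effects = effects, se = ses, vocab = vocab, positions = pos,
    r_squared = r2, residual_sd = sqrt(sigma2), n_train = nrow(records),
    ridge = ridge, covb = covb, colnames = colnames(X),
    observed = unique(records[pos])
  ), class = "freewilson_model")
}

#' @export
print.freewilson_model <- function(x, ...) {
  cat("Free-Wilson model:", x$n_train, "records,",
      paste(vapply(x$vocab, length, integer(1)), collapse = " x "),
      "monomers\n")
  cat(sprintf("  intercept %.3f | R^2 %.3f | residual SD %.3f%s\n",
              x$intercept, x$r_squared, x$residual_sd,
              if (x$ridge) " | ridge fallback" else ""))
  invisible(x)
}

#' Predict every combination of observed monomers
#'
#' One row per element of the vocabulary product. Predictions for observed
#' (training) combinations equal the fitted values; the standard error is
#' the prediction SE of the linear combination.
#'
#' @param model a `freewilson_model`.
#' @return data.frame: monomer id columns, `pred`, `se`, `observed`.
#' @export
predict_freewilson <- function(model) {
  grid <- expand.grid(model$vocab, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- model$positions
  n <- nrow(grid)
  X <- matrix(0, n, length(model$colnames))
  colnames(X) <- model$colnames
  X[, 1] <- 1
  pred <- rep(model$intercept, n)
  for (p in model$positions) {
    eff <- model$effects[[p]]
    pred <- pred + eff[as.character(grid[[p]])]
    for (m in names(eff)[-1]) {
      X[grid[[p]] == m, paste0(p, ":", m)] <- 1
    }
  }
  se <- sqrt(pmax(rowSums((X %*% model$covb) * X), 0))
  obs_key <- do.call(paste, c(model$observed, sep = "\r"))
  grid_key <- do.call(paste, c(grid, sep = "\r"))
  out <- grid
  out$pred <- as.vector(pred)
  out$se <- se
  out$observed <- grid_key %in% obs_key
  rownames(out) <- NULL
  out
}

#' Top-ranked predictions
#'
#' @param predictions output of [predict_freewilson()].
#' @param n number of rows wanted.
#' @param exclude_observed drop training combinations first.
#' @return the top rows by descending prediction, ties broken by monomer
#'   ids for determinism.
#' @export
top_predictions <- function(predictions, n = 10, exclude_observed = FALSE) {
  stopifnot(n >= 1)
  tab <- if (exclude_observed) {
    predictions[!predictions$observed, , drop = FALSE]
  } else {
    predictions
  }
  pos <- intersect(c("m1", "m2", "m3"), names(tab))
  ord <- do.call(order, c(list(-tab$pred), lapply(pos, function(p) tab[[p]])))
  tab[ord[seq_len(min(n, nrow(tab)))], , drop = FALSE]
}
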