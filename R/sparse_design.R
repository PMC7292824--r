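# Equally sampled incomplete balanced block ("sparse array") designs over
# 2-3 categorical factors, plus steepest-descent assignment of physical
# reagents to design levels and product realisation.

#' Plan replicate counts for a sparse array design
#'
#' Each monomer (level) of a factor is sampled the same number of times as
#' its peers at that position: the replicate count of factor i is
#' `r_i = M / N_i`, so `M` must be divisible by every level count. For the
#' worked two-factor case of 24 x 32 levels at a 1/8 sampling fraction this
#' gives M = 96, r = (4, 3).
#'
#' @param levels integer vector of 2 or 3 level counts (each >= 2).
#' @param M total number of products, or `NULL` to derive from `fraction`.
#' @param fraction sampled fraction of the full factorial (`M = fraction *
#'   prod(levels)`).
#' @return a `design_spec`: list(levels, M, replicates).
#' @export
plan_replicates <- function(levels, M = NULL, fraction = NULL) {
  levels <- as.integer(levels)
  if (length(levels) < 2 || length(levels) > 3 || any(levels < 2)) {
    validation_error("levels must be 2 or 3 counts, each >= 2")
  }
  if (is.null(M)) {
    if (is.null(fraction)) validation_error("give M or fraction")
    M <- fraction * prod(levels)
    if (abs(M - round(M)) > 1e-9) {
      validation_error(sprintf("fraction %g of %d is not a whole number",
                               fraction, prod(levels)))
    }
    M <- as.integer(round(M))
  }
  M <- as.integer(M)
  if (M > prod(levels)) {
    validation_error("M exceeds the full factorial size")
  }
  if (any(M %% levels != 0L)) {
    l <- .lcm_vec(levels)
    lo <- (M %/% l) * l
    hi <- lo + l
    feas <- unique(c(if (lo >= max(levels)) lo,
                     if (hi <= prod(levels)) hi))
    validation_error(sprintf(
      "M = %d is not divisible by every level count (%s); nearest feasible M: %s",
      M, paste(levels, collapse = ", "),
      if (length(feas)) paste(feas, collapse = ", ") else "none"))
  }
  structure(list(levels = levels, M = M, replicates = as.integer(M / levels)),
            class = "design_spec")
}

.gcd2 <- function(a, b) if (b == 0) a else .gcd2(b, a %% b)
.lcm_vec <- function(x) Reduce(function(a, b) a * b / .gcd2(a, b), x)

#' @export
print.design_spec <- function(x, ...) {
  cat("Sparse array design spec:", paste(x$levels, collapse = " x "),
      "levels, M =", x$M, "\n  replicates per level:",
      paste(x$replicates, collapse = ", "), "\n")
  invisible(x)
}

#' Generate an equally sampled sparse array design
#'
#' Selects `M` distinct cells of the virtual array such that level `i` of
#' factor `k` appears in exactly `r_k = M / N_k` cells (exact first-order
#' marginal balance). Two-factor designs are built as a random biregular
#' bipartite matching — factor-1 levels each repeated `r_1` times matched
#' against a shuffled vector of factor-2 levels each repeated `r_2` times —
#' followed by swap-repair to remove duplicate cells (a swap exchanges
#' factor-2 partners between two cells, which preserves both margins).
#' Three-factor designs shuffle each balanced column independently with the
#' same repair. Reproducible for a fixed seed.
#'
#' @param spec a `design_spec` from [plan_replicates()].
#' @param seed RNG seed.
#' @param max_repair bound on repair sweeps before giving up (duplicate
#'   collisions are rare for M well below the factorial size; failure is
#'   surfaced, never silently ignored).
#' @return data.frame of 0-based level indices (`f1`, `f2`[, `f3`]), one
#'   row per selected cell.
#' @export
generate_balanced_design <- function(spec, seed = 1L, max_repair = 10000L) {
  stopifnot(inherits(spec, "design_spec"))
  k <- length(spec$levels)
  nm <- paste0("f", seq_len(k))
  if (spec$M == prod(spec$levels)) {
    # full factorial limit: the design is the whole array
    cells <- expand.grid(lapply(spec$levels, function(n) seq_len(n) - 1L),
                         KEEP.OUT.ATTRS = FALSE)
    names(cells) <- nm
    return(cells)
  }
  with_seed(seed, {
    for (restart in seq_len(10L)) {
      cols <- lapply(seq_len(k), function(j) {
        v <- rep(seq_len(spec$levels[j]) - 1L, spec$replicates[j])
        if (j == 1L) sort(v) else sample(v)
      })
      cells <- as.data.frame(stats::setNames(cols, nm))
      cells <- .repair_duplicates(cells, sweeps = max_repair %/% 50L)
      if (!is.null(cells)) {
        rownames(cells) <- NULL
        return(cells)
      }
    }
    validation_error(
      "could not repair duplicate cells within the sweep budget")
  })
}

# Swap-repair: duplicate cells are eliminated in sweeps. Each sweep visits
# every currently duplicated cell and exchanges one non-fixed column entry
# with a random partner cell, accepting a swap only when both resulting
# cells are previously unoccupied — which strictly reduces the duplicate
# count while preserving every marginal. Cells are keyed as mixed-radix
# integers with an occupancy hash for O(1) acceptance checks. Returns NULL
# when the sweep budget is exhausted so the caller can restart from a fresh
# shuffle.
.repair_duplicates <- function(cells, sweeps = 200L, partner_tries = 30L) {
  n <- nrow(cells)
  k <- ncol(cells)
  radix <- vapply(cells, function(v) max(v) + 1, numeric(1))
  mult <- rev(cumprod(rev(c(radix[-1], 1))))
  m <- as.matrix(cells)
  keyv <- as.vector(m %*% mult)
  cnt <- new.env(parent = emptyenv(), size = 2L * n)
  kstr <- format(keyv, scientific = FALSE, trim = TRUE)
  for (s in kstr) cnt[[s]] <- (cnt[[s]] %||% 0L) + 1L
  count_of <- function(s) cnt[[s]] %||% 0L
  for (sweep in seq_len(sweeps)) {
    dup_rows <- which(duplicated(keyv))
    if (!length(dup_rows)) {
      out <- as.data.frame(m)
      names(out) <- names(cells)
      return(out)
    }
    dup_rows <- dup_rows[sample.int(length(dup_rows))]
    for (d in dup_rows) {
      sd <- kstr[d]
      if (count_of(sd) <= 1L) next  # already repaired this sweep
      for (try in seq_len(partner_tries)) {
        o <- sample.int(n, 1L)
        if (o == d) next
        col <- if (k == 2L) 2L else sample(2:k, 1L)
        delta <- (m[o, col] - m[d, col]) * mult[col]
        if (delta == 0) next
        nd <- keyv[d] + delta
        no <- keyv[o] - delta
        snd <- format(nd, scientific = FALSE, trim = TRUE)
        sno <- format(no, scientific = FALSE, trim = TRUE)
        if (nd != no && count_of(snd) == 0L && count_of(sno) == 0L) {
          so <- kstr[o]
          cnt[[sd]] <- cnt[[sd]] - 1L
          cnt[[so]] <- cnt[[so]] - 1L
          cnt[[snd]] <- 1L
          cnt[[sno]] <- 1L
          tmp <- m[d, col]
          m[d, col] <- m[o, col]
          m[o, col] <- tmp
          keyv[d] <- nd
          keyv[o] <- no
          kstr[d] <- snd
          kstr[o] <- sno
          break
        }
      }
    }
  }
  NULL
}

#' Verify the balance invariants of a design
#'
#' @param cells design cells data.frame.
#' @param spec the generating `design_spec`.
#' @return TRUE invisibly; raises an error on any violation.
#' @export
check_design <- function(cells, spec) {
  if (nrow(cells) != spec$M) validation_error("wrong cell count")
  if (anyDuplicated(do.call(paste, cells))) {
    validation_error("duplicate cells")
  }
  for (j in seq_along(spec$levels)) {
    tab <- tabulate(cells[[j]] + 1L, nbins = spec$levels[j])
    if (!all(tab == spec$replicates[j])) {
      validation_error(sprintf("factor %d is not balanced", j))
    }
  }
  invisible(TRUE)
}

# ---- reagent assignment ----

#' Assign physical reagents to design levels by steepest descent
#'
#' The design itself is agnostic to reagent identity; this step maps each
#' abstract level to a reagent so as to maximise the summed product
#' desirability over the selected cells. Starting from a seeded random
#' assignment, all within-factor reagent swaps are evaluated each
#' iteration and the best strictly improving one applied (ties broken by
#' lowest factor, then lowest swap indices) until no swap improves or
#' `max_iters` is reached.
#'
#' @param cells design cells (0-based level indices).
#' @param product_scores numeric matrix/array indexed by reagent index per
#'   factor: `product_scores[i, j(, k)]` is the desirability total of the
#'   product made from reagent `i` at position 1, `j` at position 2 (and
#'   `k` at 3). Build it with [product_score_table()] when starting from
#'   reagent structures.
#' @param seed RNG seed for the initial random assignment.
#' @param max_iters iteration cap.
#' @return a `reagent_assignment`: list(assignment = list of per-factor
#'   integer vectors mapping level index -> reagent index,
#'   objective_trace = objective after each accepted swap (non-decreasing),
#'   objective = final value).
#' @export
assign_reagents <- function(cells, product_scores, seed = 1L,
                            max_iters = 1000L) {
  dims <- dim(product_scores)
  k <- length(dims)
  if (k != ncol(cells)) {
    validation_error("product_scores dimensionality must match the design")
  }
  idx <- as.matrix(cells) + 1L
  objective <- function(assign) {
    coords <- vapply(seq_len(k), function(j) assign[[j]][idx[, j]],
                     integer(nrow(idx)))
    sum(product_scores[coords])
  }
  with_seed(seed, {
    assign <- lapply(dims, sample)
    trace <- objective(assign)
    for (it in seq_len(max_iters)) {
      best_gain <- 0
      best <- NULL
      cur <- trace[length(trace)]
      for (j in seq_len(k)) {
        for (i1 in seq_len(dims[j] - 1L)) {
          for (i2 in seq(i1 + 1L, dims[j])) {
            cand <- assign
            tmp <- cand[[j]][i1]
            cand[[j]][i1] <- cand[[j]][i2]
            cand[[j]][i2] <- tmp
            gain <- objective(cand) - cur
            if (gain > best_gain + 1e-12) {
              best_gain <- gain
              best <- cand
            }
          }
        }
      }
      if (is.null(best)) break
      assign <- best
      trace <- c(trace, cur + best_gain)
    }
    structure(list(assignment = assign, objective_trace = trace,
                   objective = trace[length(trace)]),
              class = "reagent_assignment")
  })
}

#' Desirability score table for all reagent combinations
#'
#' Enumerates the product of every reagent combination on the scaffold,
#' computes properties and scores them under the profile, returning the
#' array consumed by [assign_reagents()].
#'
#' @param scaffold SMILES with one numbered attachment point per factor
#'   (`[1*]`, `[2*]`, ...).
#' @param reagents list of reagent tables (each with `id`, `smiles`; one
#'   single-attachment `*` per reagent SMILES).
#' @param profile a `score_profile` with scored criteria.
#' @return numeric array of desirability totals, one dimension per factor.
#' @export
product_score_table <- function(scaffold, reagents, profile) {
  dims <- vapply(reagents, nrow, integer(1))
  grid <- expand.grid(lapply(dims, seq_len))
  smi <- vapply(seq_len(nrow(grid)), function(r) {
    .assemble_product(scaffold,
                      vapply(seq_along(reagents), function(j) {
                        reagents[[j]]$smiles[grid[r, j]]
                      }, character(1)))
  }, character(1))
  tab <- data.frame(id = sprintf("p%05d", seq_len(nrow(grid))), smiles = smi)
  bad <- is.na(tab$smiles)
  if (any(bad)) {
    validation_error(sprintf("product enumeration failed for cells: %s",
                             paste(which(bad), collapse = ", ")))
  }
  scored <- desirability(compute_properties(tab), profile)
  array(scored$score_total, dim = dims)
}

# Attach one single-attachment monomer per numbered scaffold attachment
# point; returns canonical SMILES or NA.
.assemble_product <- function(scaffold, monomer_smiles) {
  sg <- mg_parse(scaffold, perceive = FALSE)[[1]]
  if (is.null(sg)) return(NA_character_)
  for (j in seq_along(monomer_smiles)) {
    d <- which(sg$atoms$elem == "*" & sg$atoms$label == j)
    if (length(d) != 1L) return(NA_character_)
    mgm <- mg_parse(monomer_smiles[j], perceive = FALSE)[[1]]
    if (is.null(mgm)) return(NA_character_)
    dm <- which(mgm$atoms$elem == "*")
    if (length(dm) != 1L) return(NA_character_)
    sg <- tryCatch(mg_join(sg, d, mgm, dm), error = function(e) NULL)
    if (is.null(sg)) return(NA_character_)
  }
  if (any(sg$atoms$elem == "*")) return(NA_character_)
  mg_to_smiles(sg)
}

#' Realise the product molecules of a designed array
#'
#' @param cells design cells (0-based level indices).
#' @param assignment a `reagent_assignment` (or NULL for identity mapping).
#' @param scaffold SMILES with numbered attachment points (`[1*]`, `[2*]`,
#'   ...), one per factor.
#' @param reagents list of reagent tables (`id`, `smiles`).
#' @return molecule table with `method = "array"`; ids encode the cell
#'   coordinates, and per-position monomer id columns (`m1`, `m2`, ...)
#'   are attached.
#' @export
realize_products <- function(cells, assignment = NULL, scaffold, reagents) {
  k <- ncol(cells)
  if (is.null(assignment)) {
    assignment <- list(assignment = lapply(vapply(reagents, nrow, integer(1)),
                                           seq_len))
  }
  amap <- assignment$assignment
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    ridx <- vapply(seq_len(k), function(j) amap[[j]][cells[r, j] + 1L],
                   integer(1))
    mono <- vapply(seq_len(k), function(j) reagents[[j]]$smiles[ridx[j]],
                   character(1))
    smi <- .assemble_product(scaffold, mono)
    if (is.na(smi)) {
      validation_error(sprintf("product realisation failed at cell (%s)",
                               paste(unlist(cells[r, ]), collapse = ", ")))
    }
    out <- data.frame(
      id = paste0("cell_", paste(unlist(cells[r, ]), collapse = "_")),
      smiles = smi, method = "array", seed_id = NA_character_,
      change_note = paste0("array cell (",
                           paste(unlist(cells[r, ]), collapse = ", "), ")"))
    for (j in seq_len(k)) out[[paste0("m", j)]] <- reagents[[j]]$id[ridx[j]]
    out
  })
  do.call(rbind, rows)
}
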