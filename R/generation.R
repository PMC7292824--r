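# Candidate generation: BRICS fragment-pool analogues, matched-molecular-pair
# transforms, similarity search, and similarity-based include/exclude
# filtering. Every generator makes exactly one change per output molecule
# (single-pass edits); deeper exploration is achieved by feeding outputs back
# in as seeds.

# ---- fragment pool ----

#' Build a labelled BRICS fragment pool from a compound collection
#'
#' Fragments every molecule at its BRICS bonds and aggregates the fragments
#' by canonical structure, recording attachment labels, heavy-atom count,
#' molecular weight (attachment points weightless) and occurrence frequency.
#'
#' @param mols molecule table (at least one valid molecule).
#' @return a `fragment_pool`: data.frame with columns `smiles`, `labels`
#'   (sorted, `+`-joined BRICS codes), `n_attach`, `heavy_atoms`, `mw`,
#'   `frequency`.
#' @export
build_fragment_pool <- function(mols) {
  if (!nrow(mols)) validation_error("empty collection")
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(mols))) {
    fr <- tryCatch(brics_fragment(mols$smiles[i]), error = function(e) NULL)
    if (is.null(fr)) next
    for (f in seq_len(nrow(fr$fragments))) {
      key <- fr$fragments$smiles[f]
      if (is.na(key)) next
      if (is.null(acc[[key]])) {
        g <- fr$graphs[[f]]
        acc[[key]] <- list(labels = fr$fragments$labels[f],
                           n_attach = sum(g$atoms$elem == "*"),
                           heavy = mg_heavy_atoms(g), freq = 1L)
      } else {
        acc[[key]]$freq <- acc[[key]]$freq + 1L
      }
    }
  }
  keys <- sort(ls(acc))
  if (!length(keys)) validation_error("no fragments produced")
  entries <- data.frame(
    smiles = keys,
    labels = vapply(keys, function(k) acc[[k]]$labels, character(1)),
    n_attach = vapply(keys, function(k) acc[[k]]$n_attach, integer(1)),
    heavy_atoms = vapply(keys, function(k) acc[[k]]$heavy, integer(1)),
    frequency = vapply(keys, function(k) acc[[k]]$freq, integer(1)),
    row.names = NULL)
  entries$mw <- .fragment_mw(entries$smiles)
  structure(list(entries = entries), class = "fragment_pool")
}

#' @export
print.fragment_pool <- function(x, ...) {
  cat("BRICS fragment pool:", nrow(x$entries), "distinct fragments, total",
      sum(x$entries$frequency), "occurrences\n")
  print(utils::head(x$entries, 10))
  invisible(x)
}

#' Persist / load a fragment pool as CSV
#'
#' Columns: `fragment_smiles,labels,heavy_atoms,mw,frequency`.
#' @param pool a `fragment_pool`.
#' @param path file path.
#' @export
write_fragment_pool <- function(pool, path) {
  e <- pool$entries
  utils::write.csv(
    data.frame(fragment_smiles = e$smiles, labels = e$labels,
               heavy_atoms = e$heavy_atoms, mw = e$mw,
               frequency = e$frequency),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_pool
#' @export
read_fragment_pool <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fragment_smiles", "labels", "frequency")
  if (!all(need %in% names(tab))) {
    validation_error("fragment pool CSV needs fragment_smiles,labels,frequency")
  }
  entries <- data.frame(
    smiles = tab$fragment_smiles, labels = as.character(tab$labels),
    n_attach = lengths(strsplit(as.character(tab$labels), "+", fixed = TRUE)),
    heavy_atoms = tab$heavy_atoms %||% NA_integer_,
    frequency = as.integer(tab$frequency))
  entries$mw <- tab$mw %||% NA_real_
  structure(list(entries = entries), class = "fragment_pool")
}

# Molecular weight of fragments with attachment points capped by hydrogen
# (the conventional R-group weight; avoids dummy-element arithmetic).
.fragment_mw <- function(smiles) {
  capped <- vapply(smiles, function(s) {
    mg <- mg_parse(s, perceive = FALSE)[[1]]
    if (is.null(mg)) return(NA_character_)
    mg$atoms$elem[mg$atoms$elem == "*"] <- "H"
    mg$atoms$label <- 0L
    mg_to_smiles(mg)
  }, character(1), USE.NAMES = FALSE)
  mw <- rep(NA_real_, length(smiles))
  ok <- !is.na(capped)
  if (any(ok)) {
    refs <- suppressWarnings(ChemmineOB::forEachMol("SMILES",
      paste0(paste(capped[ok], seq_len(sum(ok)), sep = "\t"), "\n",
             collapse = ""), identity))
    if (length(refs) == sum(ok)) {
      mw[ok] <- suppressWarnings(ChemmineOB::prop_OB(refs))$MW
    }
  }
  mw
}

# Parse a pool fragment's SMILES into a graph, verifying its dummy labels
# agree with the recorded label string.
.pool_fragment_graph <- function(smiles) {
  mg <- mg_parse(smiles, perceive = FALSE)[[1]]
  if (is.null(mg)) return(NULL)
  mg
}

# label keys for pool entries under a relaxation setting
.pool_keys <- function(pool, relax) {
  vapply(strsplit(pool$entries$labels, "+", fixed = TRUE), function(l) {
    label_key(as.integer(l), relax)
  }, character(1))
}

# ---- BRICS analogue enumeration ----

#' Enumerate single-edit BRICS analogues of a lead molecule
#'
#' Each output differs from the seed by exactly one fragment replacement,
#' insertion or deletion:
#' \itemize{
#'   \item replacement: a fragment is exchanged for a pool fragment sharing
#'     the same attachment-label multiset;
#'   \item insertion (`allow_insert`): a two-attachment pool fragment whose
#'     labels equal a cut bond's label pair is spliced into that bond
#'     (compound growth);
#'   \item deletion (`allow_delete`): a terminal fragment is removed and the
#'     open valence capped with hydrogen.
#' }
#' `relax_ring_labels` merges the aromatic-ring attachment classes (14, 16)
#' with the aliphatic-ring classes (13, 15), e.g. allowing a phenyl to be
#' replaced by a cyclohexyl. Outputs are deduplicated by canonical SMILES
#' and never include the seed itself.
#'
#' @param mol one-row molecule table (the seed).
#' @param pool a `fragment_pool`.
#' @param mode `"exhaustive"` or `"random"` (uniform sample of `n` of the
#'   exhaustive set, reproducible for a fixed `seed`).
#' @param n,seed sample size and RNG seed for `mode = "random"`.
#' @param relax_ring_labels merge aromatic/aliphatic ring label classes.
#' @param allow_insert,allow_delete enable growth / shrink edits.
#' @param max_per_position cap on pool candidates tried per fragment
#'   position (pool order, deterministic).
#' @return molecule table with provenance (`method = "brics"`, `seed_id`,
#'   `change_note` naming position and fragment). May be empty.
#' @export
enumerate_brics_analogues <- function(mol, pool,
                                      mode = c("exhaustive", "random"),
                                      n = NULL, seed = NULL,
                                      relax_ring_labels = FALSE,
                                      allow_insert = FALSE,
                                      allow_delete = FALSE,
                                      max_per_position = Inf) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "fragment_pool"))
  fr <- brics_fragment(mol$smiles[1])
  keys <- .pool_keys(pool, relax_ring_labels)
  out_smiles <- character(0)
  out_note <- character(0)
  add <- function(smi, note) {
    if (!is.null(smi) && !is.na(smi) && smi != fr$seed_smiles &&
        !(smi %in% out_smiles)) {
      out_smiles <<- c(out_smiles, smi)
      out_note <<- c(out_note, note)
    }
  }
  # replacements
  if (nrow(fr$bond_map) > 0) {
    for (p in seq_len(nrow(fr$fragments))) {
      labs <- as.integer(strsplit(fr$fragments$labels[p], "+",
                                  fixed = TRUE)[[1]])
      if (!length(labs)) next
      key <- label_key(labs, relax_ring_labels)
      cand <- which(keys == key & pool$entries$smiles != fr$fragments$smiles[p])
      if (length(cand) > max_per_position) {
        cand <- cand[seq_len(max_per_position)]
      }
      for (ci in cand) {
        g <- .pool_fragment_graph(pool$entries$smiles[ci])
        if (is.null(g)) next
        smi <- swap_fragment(fr, p, g, relax = relax_ring_labels)
        add(smi, sprintf("replace pos=%d %s -> %s", p,
                         fr$fragments$smiles[p], pool$entries$smiles[ci]))
      }
    }
  }
  # insertions: splice a 2-attachment fragment into a cut bond
  if (allow_insert && nrow(fr$bond_map) > 0) {
    two <- which(pool$entries$n_attach == 2L)
    for (j in seq_len(nrow(fr$bond_map))) {
      bm <- fr$bond_map[j, ]
      if (bm$order != 1L) next
      key <- label_key(c(bm$lab1, bm$lab2), relax_ring_labels)
      cand <- two[keys[two] == key]
      if (length(cand) > max_per_position) cand <- cand[seq_len(max_per_position)]
      for (ci in cand) {
        g <- .pool_fragment_graph(pool$entries$smiles[ci])
        if (is.null(g)) next
        smi <- tryCatch(.insert_fragment(fr, j, g, relax_ring_labels),
                        error = function(e) NULL)
        add(smi, sprintf("insert %s into joint %d",
                         pool$entries$smiles[ci], j))
      }
    }
  }
  # deletions: drop a terminal fragment, cap with hydrogen
  if (allow_delete && nrow(fr$fragments) > 1) {
    for (p in which(fr$fragments$n_joints == 1L)) {
      smi <- tryCatch(.delete_fragment(fr, p), error = function(e) NULL)
      add(smi, sprintf("delete pos=%d %s", p, fr$fragments$smiles[p]))
    }
  }
  if (mode == "random" && length(out_smiles) > (n %||% Inf)) {
    pick <- with_seed(seed %||% 1L, sample.int(length(out_smiles), n))
    pick <- sort(pick)
    out_smiles <- out_smiles[pick]
    out_note <- out_note[pick]
  }
  if (!length(out_smiles)) return(.empty_records())
  data.frame(id = sprintf("%s_brics_%03d", mol$id[1],
                          seq_along(out_smiles)),
             smiles = out_smiles, method = "brics",
             seed_id = mol$id[1], change_note = out_note)
}

# Splice a two-attachment fragment graph into joint j of a fragmentation.
.insert_fragment <- function(fr, j, g, relax = FALSE) {
  bm <- fr$bond_map[fr$bond_map$joint == j, ]
  dummies <- which(g$atoms$elem == "*")
  labs <- g$atoms$label[dummies]
  if (length(dummies) != 2L) return(NULL)
  # new fragment side labelled lab2 joins the lab1 side of the old joint
  pick2 <- .match_label(labs, bm$lab2, relax)
  if (is.na(pick2)) return(NULL)
  pick1 <- .match_label(labs[-pick2], bm$lab1, relax)
  if (is.na(pick1)) return(NULL)
  d_to_frag1 <- dummies[pick2]
  d_to_frag2 <- dummies[-pick2][pick1]
  nf <- length(fr$graphs) + 1L
  graphs <- c(fr$graphs, list(g))
  jt <- fr$joint_tab
  bmap <- fr$bond_map
  njoint <- max(bmap$joint) + 1L
  # rewire joint j: frag1 side keeps its dummy, partner becomes new fragment
  jt$frag[jt$joint == j & jt$frag == bm$frag2] <- NA  # detach old partner row
  old2 <- which(is.na(jt$frag))
  jt$frag[old2] <- nf
  jt$dummy[old2] <- d_to_frag1
  jt$label[old2] <- g$atoms$label[d_to_frag1]
  # new joint: new fragment's other dummy to the old frag2 dummy
  jt <- rbind(jt,
    data.frame(joint = njoint, frag = nf, dummy = d_to_frag2,
               label = g$atoms$label[d_to_frag2]),
    data.frame(joint = njoint, frag = bm$frag2,
               dummy = fr$joint_tab$dummy[fr$joint_tab$joint == j &
                                          fr$joint_tab$frag == bm$frag2],
               label = bm$lab2))
  bmap$lab2[bmap$joint == j] <- g$atoms$label[d_to_frag1]
  bmap$frag2[bmap$joint == j] <- nf
  bmap <- rbind(bmap, data.frame(
    joint = njoint, frag1 = nf, lab1 = g$atoms$label[d_to_frag2],
    frag2 = bm$frag2, lab2 = bm$lab2, order = 1L))
  mg_to_smiles(.assemble_graphs(graphs, jt, bmap))
}

.match_label <- function(labs, want, relax) {
  hit <- which(labs == want |
                 (relax & .relax_labels(labs) == .relax_labels(want)))
  if (length(hit)) hit[1] else NA_integer_
}

# Remove terminal fragment p; the orphaned partner dummy is dropped
# (implicit hydrogen caps the valence).
.delete_fragment <- function(fr, p) {
  jt <- fr$joint_tab
  gone <- unique(jt$joint[jt$frag == p])
  keep_j <- jt[!jt$joint %in% gone & jt$frag != p, , drop = FALSE]
  bmap <- fr$bond_map[!fr$bond_map$joint %in% gone, , drop = FALSE]
  keep_frags <- setdiff(seq_along(fr$graphs), p)
  # renumber fragments
  remap <- stats::setNames(seq_along(keep_frags), keep_frags)
  keep_j$frag <- remap[as.character(keep_j$frag)]
  bmap$frag1 <- remap[as.character(bmap$frag1)]
  bmap$frag2 <- remap[as.character(bmap$frag2)]
  big <- .assemble_graphs(fr$graphs[keep_frags], keep_j, bmap)
  orphans <- which(big$atoms$elem == "*")
  if (length(orphans)) big <- mg_drop_atoms(big, orphans)
  if (!nrow(big$atoms)) return(NULL)
  mg_to_smiles(big)
}

# ---- matched molecular pair transforms ----

#' Read an MMP transform table
#'
#' CSV columns `lhs_smiles,rhs_smiles[,support]`; both sides must carry
#' exactly one attachment point (`*`) and differ.
#' @param path CSV file.
#' @return validated data.frame with canonicalised fragment SMILES.
#' @export
read_transforms <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lhs_smiles", "rhs_smiles") %in% names(tab))) {
    validation_error("transform CSV needs lhs_smiles,rhs_smiles")
  }
  validate_transforms(data.frame(
    lhs_smiles = tab$lhs_smiles, rhs_smiles = tab$rhs_smiles,
    support = as.integer(tab$support %||% rep(1L, nrow(tab)))))
}

#' @rdname read_transforms
#' @param rules data.frame with `lhs_smiles`, `rhs_smiles` and optional
#'   `support`.
#' @export
validate_transforms <- function(rules) {
  n_attach <- function(s) lengths(regmatches(s, gregexpr("*", s, fixed = TRUE)))
  if (any(n_attach(rules$lhs_smiles) != 1L) ||
      any(n_attach(rules$rhs_smiles) != 1L)) {
    validation_error("each transform side must have exactly one attachment *")
  }
  rules$lhs_smiles <- ob_canonical(rules$lhs_smiles)
  rules$rhs_smiles <- ob_canonical(rules$rhs_smiles)
  if (anyNA(rules$lhs_smiles) || anyNA(rules$rhs_smiles)) {
    validation_error("unparseable fragment SMILES in transform table")
  }
  if (any(rules$lhs_smiles == rules$rhs_smiles)) {
    validation_error("transform lhs must differ from rhs")
  }
  if (is.null(rules$support)) rules$support <- 1L
  rules
}

#' Apply matched-molecular-pair transforms to a molecule
#'
#' The molecule is cut at every acyclic single bond in turn (single-cut
#' fragmentation). When a detached fragment equals a rule's left-hand side
#' (canonical-SMILES comparison), the rule's right-hand side is attached to
#' the remaining core in its place. Unmatched rules contribute nothing.
#' Products are deduplicated by canonical SMILES and never include the seed.
#'
#' @param mol one-row molecule table.
#' @param rules validated transform table (see [read_transforms()]).
#' @return molecule table, provenance `method = "mmp"`, `change_note`
#'   recording the rule applied.
#' @export
apply_mmp_transforms <- function(mol, rules) {
  rules <- validate_transforms(rules)
  mg <- mg_parse(mol$smiles[1], perceive = FALSE)[[1]]
  if (is.null(mg)) parse_error(paste0("cannot parse: ", mol$smiles[1]))
  rb <- mg_ring_bonds(mg)
  rhs_graphs <- lapply(rules$rhs_smiles, .pool_fragment_graph)
  out_smiles <- character(0)
  out_note <- character(0)
  seed_can <- mg_to_smiles(mg)
  for (k in seq_len(nrow(mg$bonds))) {
    if (rb[k] || mg$bonds$order[k] != 1L) next
    if (mg$atoms$elem[mg$bonds$a1[k]] == "*" ||
        mg$atoms$elem[mg$bonds$a2[k]] == "*") next
    cutg <- mg_cut_bond(mg, k, 0L, 0L)
    comp <- mg_components(cutg)
    if (max(comp) != 2L) next
    sides <- lapply(1:2, function(cc) mg_subgraph(cutg, which(comp == cc)))
    side_smi <- vapply(sides, mg_to_smiles, character(1))
    for (r in seq_len(nrow(rules))) {
      for (s in 1:2) {
        if (identical(side_smi[s], rules$lhs_smiles[r])) {
          core <- sides[[3 - s]]
          rg <- rhs_graphs[[r]]
          if (is.null(rg)) next
          d_core <- which(core$atoms$elem == "*" &
                            seq_len(nrow(core$atoms)) %in%
                              c(core$bonds$a1, core$bonds$a2))
          d_core <- d_core[length(d_core)]  # the fresh cut dummy (appended last)
          d_rg <- which(rg$atoms$elem == "*")[1]
          smi <- tryCatch(mg_to_smiles(mg_join(core, d_core, rg, d_rg)),
                          error = function(e) NULL)
          if (!is.null(smi) && !is.na(smi) && smi != seed_can &&
              !(smi %in% out_smiles)) {
            out_smiles <- c(out_smiles, smi)
            out_note <- c(out_note, sprintf("mmp %s >> %s",
                                            rules$lhs_smiles[r],
                                            rules$rhs_smiles[r]))
          }
        }
      }
    }
  }
  if (!length(out_smiles)) return(.empty_records())
  data.frame(id = sprintf("%s_mmp_%03d", mol$id[1], seq_along(out_smiles)),
             smiles = out_smiles, method = "mmp", seed_id = mol$id[1],
             change_note = out_note)
}

# ---- similarity ----

#' Similarity search of query molecules against a pool
#'
#' @param queries,pool_table molecule tables.
#' @param kind fingerprint kind (see [fingerprint()]).
#' @param cutoff Tanimoto cutoff in `[0, 1]`.
#' @return data.frame(query_id, hit_id, similarity): all pool members with
#'   similarity >= cutoff, sorted descending per query, ties broken by pool
#'   order.
#' @export
similarity_search <- function(queries, pool_table,
                              kind = c("path7", "circular2"), cutoff = 0.7) {
  kind <- match.arg(kind)
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (!nrow(pool_table)) validation_error("empty pool")
  fq <- fingerprint(queries, kind)
  fp <- fingerprint(pool_table, kind)
  out <- lapply(seq_len(nrow(queries)), function(i) {
    sims <- vapply(fp, tanimoto, numeric(1), a = fq[[i]])
    keep <- which(sims >= cutoff)
    keep <- keep[order(-sims[keep], keep)]
    if (!length(keep)) return(NULL)
    data.frame(query_id = queries$id[i], hit_id = pool_table$id[keep],
               similarity = sims[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(query_id = character(0), hit_id = character(0),
                      similarity = numeric(0))
  }
  out
}

#' Similarity include/exclude filter
#'
#' Include mode keeps a candidate if any measure passes against any
#' reference: `path7 >= thresholds["path7"]` or
#' `circular2 >= thresholds["circular2"]`. Exclude mode removes a candidate
#' only when `path7 >= exclude_threshold` against some reference — a single
#' fingerprint at a tighter threshold, so that only close analogues are
#' excluded.
#'
#' @param candidates,references molecule tables (references non-empty).
#' @param mode `"include"` or `"exclude"`.
#' @param thresholds named numeric: include thresholds per fingerprint kind.
#' @param exclude_threshold the tighter path7 threshold for exclude mode.
#' @return the surviving subset of `candidates`.
#' @export
similarity_filter <- function(candidates, references,
                              mode = c("include", "exclude"),
                              thresholds = c(path7 = 0.7, circular2 = 0.7),
                              exclude_threshold = 0.85) {
  mode <- match.arg(mode)
  if (!nrow(references)) validation_error("references must be non-empty")
  if (!nrow(candidates)) return(candidates)
  if (mode == "include") {
    f1c <- fingerprint(candidates, "path7")
    f1r <- fingerprint(references, "path7")
    f2c <- fingerprint(candidates, "circular2")
    f2r <- fingerprint(references, "circular2")
    keep <- vapply(seq_len(nrow(candidates)), function(i) {
      any(vapply(f1r, tanimoto, numeric(1), a = f1c[[i]]) >=
            thresholds[["path7"]]) ||
        any(vapply(f2r, tanimoto, numeric(1), a = f2c[[i]]) >=
              thresholds[["circular2"]])
    }, logical(1))
  } else {
    f1c <- fingerprint(candidates, "path7")
    f1r <- fingerprint(references, "path7")
    keep <- !vapply(seq_len(nrow(candidates)), function(i) {
      any(vapply(f1r, tanimoto, numeric(1), a = f1c[[i]]) >=
            exclude_threshold)
    }, logical(1))
  }
  candidates[keep, , drop = FALSE]
}
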