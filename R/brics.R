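# BRICS fragmentation and recombination.
#
# Bonds are located with the published BRICS chemical-environment rules
# (Degen et al., ChemMedChem 2008): sixteen atom environments L1-L16 and a
# compatibility table of cleavable bonds between them. The environments are
# implemented as predicates over the package's molecular graph. Every
# matching acyclic bond is cut exactly once and replaced by a pair of
# numbered attachment dummies carrying the environment labels, so that an
# unmodified fragmentation always reassembles to the input molecule.

# Compatibility table in canonical scan order; all cuts are single bonds
# except the 7-7 (vinyl/alkene) cut, which is a double bond.
.brics_pairs <- local({
  p <- rbind(
    c(1, 3), c(1, 5), c(1, 10),
    c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
    c(4, 5), c(4, 11),
    c(5, 12), c(5, 14), c(5, 16), c(5, 13), c(5, 15),
    c(6, 13), c(6, 14), c(6, 15), c(6, 16),
    c(7, 7),
    c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
    c(9, 13), c(9, 14), c(9, 15), c(9, 16),
    c(10, 13), c(10, 14), c(10, 15), c(10, 16),
    c(11, 13), c(11, 14), c(11, 15), c(11, 16),
    c(13, 14), c(13, 15), c(13, 16),
    c(14, 14), c(14, 15), c(14, 16),
    c(15, 16),
    c(16, 16)
  )
  data.frame(l1 = p[, 1], l2 = p[, 2],
             order = ifelse(p[, 1] == 7 & p[, 2] == 7, 2L, 1L))
})

# Is the unordered label pair a legal BRICS junction?
brics_legal_pair <- function(l1, l2) {
  any((.brics_pairs$l1 == l1 & .brics_pairs$l2 == l2) |
      (.brics_pairs$l1 == l2 & .brics_pairs$l2 == l1))
}

# Ring-label relaxation: aromatic-ring environments (14, 16) and
# aliphatic-ring environments (13, 15) collapse to one class, so e.g. a
# phenyl attachment may be replaced by cyclohexyl.
.relax_labels <- function(labels) {
  labels[labels %in% c(13L, 14L, 15L, 16L)] <- 13L
  labels
}

label_key <- function(labels, relax = FALSE) {
  if (relax) labels <- .relax_labels(labels)
  paste(sort(as.integer(labels)), collapse = "+")
}

# ---- environment matching ----

# Context shared by the predicates: degree, adjacency, ring flags.
.brics_ctx <- function(mg) {
  rb <- mg_ring_bonds(mg)
  list(
    adj = mg_adjacency(mg),
    deg = mg_degree(mg),
    ring_bond = rb,
    ring_atom = mg_ring_atoms(mg, rb)
  )
}

# TRUE if two *distinct* neighbours can be assigned to candidate sets A and B.
.two_distinct <- function(candA, candB) {
  for (x in candA) for (y in candB) if (x != y) return(TRUE)
  FALSE
}

# Does atom `a` of `mg` match BRICS environment `env` (integer 1..16)?
.match_env <- function(mg, ctx, a, env) {
  at <- mg$atoms
  el <- at$elem[a]
  ar <- at$arom[a]
  nb <- ctx$adj[[a]]
  deg <- ctx$deg[a]
  nbr_el <- at$elem[nb$nbr]
  nbr_ar <- at$arom[nb$nbr]
  nbr_ring <- ctx$ring_atom[nb$nbr]
  bond_ring <- ctx$ring_bond[nb$bond]
  # aromatic bond approximation: ring bond between two aromatic atoms
  bond_arom <- bond_ring & ar & nbr_ar

  dbl_O <- nb$nbr[nb$order == 2L & nbr_el == "O"]
  has_dbl <- any(nb$order >= 2L)

  switch(as.character(env),
    "1" = {  # acyl carbon [C;D3]([#0,#6,#7,#8])(=O)
      el == "C" && !ar && deg == 3L && length(dbl_O) >= 1L &&
        .two_distinct(nb$nbr[nbr_el %in% c("*", "C", "N", "O")], dbl_O)
    },
    "3" = {  # ether/ester oxygen [O;D2]-;!@[#0,#6,#1]
      el == "O" && !ar && deg == 2L &&
        any(nb$order == 1L & !bond_ring & nbr_el %in% c("*", "C"))
    },
    "4" = {  # sp3-ish carbon [C;!D1;!$(C=*)]-;!@[#6]
      el == "C" && !ar && deg >= 2L && !any(nb$order == 2L) &&
        any(nb$order == 1L & !bond_ring & nbr_el == "C")
    },
    "5" = {  # amine nitrogen
      el == "N" && !ar && deg >= 2L && !any(nb$order == 2L) &&
        all(nbr_el %in% c("C", "S", "*", "H")) &&
        !(ctx$ring_atom[a] && any(bond_ring & nbr_el == "C" & nbr_ring &
            vapply(nb$nbr, function(c2) {
              cnb <- ctx$adj[[c2]]
              any(cnb$order == 2L & at$elem[cnb$nbr] == "O")
            }, logical(1))))
    },
    "6" = {  # acyclic acyl [C;D3;!R](=O)-;!@[#0,#6,#7,#8]
      el == "C" && !ar && deg == 3L && !ctx$ring_atom[a] &&
        length(dbl_O) >= 1L &&
        .two_distinct(
          nb$nbr[nb$order == 1L & !bond_ring &
                   nbr_el %in% c("*", "C", "N", "O")], dbl_O)
    },
    "7" = {  # alkene/alkyne carbon [C;D2,D3]-[#6]
      el == "C" && !ar && deg %in% c(2L, 3L) && any(nbr_el == "C")
    },
    "8" = {  # acyclic all-single carbon [C;!R;!D1;!$(C!-*)]
      el == "C" && !ar && !ctx$ring_atom[a] && deg >= 2L &&
        all(nb$order == 1L)
    },
    "9" = {  # aromatic n flanked by aromatic c/n/o/s
      el == "N" && ar && at$charge[a] == 0L &&
        sum(bond_arom & nbr_el %in% c("C", "N", "O", "S")) >= 2L
    },
    "10" = {  # lactam nitrogen
      el == "N" && !ar && ctx$ring_atom[a] && {
        carbonyl <- nb$nbr[bond_ring & nbr_el == "C" &
          vapply(nb$nbr, function(c2) {
            cnb <- ctx$adj[[c2]]
            any(cnb$order == 2L & at$elem[cnb$nbr] == "O")
          }, logical(1))]
        other <- nb$nbr[bond_ring & nbr_el %in% c("C", "N", "O", "S")]
        .two_distinct(carbonyl, other)
      }
    },
    "11" = {  # thioether sulfur [S;D2](-;!@[#0,#6])
      el == "S" && !ar && deg == 2L &&
        any(nb$order == 1L & !bond_ring & nbr_el %in% c("*", "C"))
    },
    "12" = {  # sulfonyl [S;D4]([#6,#0])(=O)(=O)
      el == "S" && deg == 4L &&
        sum(nb$order == 2L & nbr_el == "O") >= 2L &&
        any(nbr_el %in% c("C", "*"))
    },
    "13" = {  # ring carbon next to a ring heteroatom
      el == "C" && !ar && ctx$ring_atom[a] && {
        candA <- nb$nbr[bond_ring & nb$order == 1L & !nbr_ar & nbr_ring &
                          nbr_el %in% c("C", "N", "O", "S")]
        candB <- nb$nbr[bond_ring & nb$order == 1L & !nbr_ar & nbr_ring &
                          nbr_el %in% c("N", "O", "S")]
        .two_distinct(candA, candB)
      }
    },
    "14" = {  # aromatic c adjacent to an aromatic heteroatom
      el == "C" && ar &&
        .two_distinct(nb$nbr[bond_arom & nbr_el %in% c("C", "N", "O", "S")],
                      nb$nbr[bond_arom & nbr_el %in% c("N", "O", "S")])
    },
    "15" = {  # aliphatic ring carbon between two ring carbons
      el == "C" && !ar && ctx$ring_atom[a] &&
        sum(bond_ring & nb$order == 1L & !nbr_ar & nbr_el == "C" &
              nbr_ring) >= 2L
    },
    "16" = {  # aromatic c between two aromatic c
      el == "C" && ar && sum(bond_arom & nbr_el == "C") >= 2L
    },
    FALSE
  )
}

# Locate BRICS bonds: data.frame(a1, a2, lab1, lab2, order). For each
# cleavable acyclic bond the first matching environment pair (table order)
# assigns the labels.
find_brics_bonds <- function(mg) {
  ctx <- .brics_ctx(mg)
  out <- data.frame(a1 = integer(0), a2 = integer(0),
                    lab1 = integer(0), lab2 = integer(0), order = integer(0))
  if (!nrow(mg$bonds)) return(out)
  env_cache <- new.env(parent = emptyenv())
  menv <- function(a, env) {
    key <- paste0(a, ".", env)
    if (is.null(env_cache[[key]])) {
      env_cache[[key]] <- .match_env(mg, ctx, a, env)
    }
    env_cache[[key]]
  }
  for (k in seq_len(nrow(mg$bonds))) {
    if (ctx$ring_bond[k]) next
    a <- mg$bonds$a1[k]
    b <- mg$bonds$a2[k]
    if (mg$atoms$elem[a] == "*" || mg$atoms$elem[b] == "*") next
    ord <- mg$bonds$order[k]
    for (r in seq_len(nrow(.brics_pairs))) {
      if (.brics_pairs$order[r] != ord) next
      l1 <- .brics_pairs$l1[r]
      l2 <- .brics_pairs$l2[r]
      if (menv(a, l1) && menv(b, l2)) {
        out <- rbind(out, data.frame(a1 = a, a2 = b, lab1 = l1, lab2 = l2,
                                     order = ord))
        break
      }
      if (l1 != l2 && menv(b, l1) && menv(a, l2)) {
        out <- rbind(out, data.frame(a1 = b, a2 = a, lab1 = l1, lab2 = l2,
                                     order = ord))
        break
      }
    }
  }
  out
}

# ---- fragmentation ----

#' Fragment a molecule at its BRICS bonds
#'
#' Cuts every BRICS-cleavable bond exactly once, yielding labelled fragments
#' plus the bond map needed to reassemble the parent. A molecule with no
#' BRICS bonds yields a single fragment and an empty bond map.
#'
#' @param smiles a single SMILES string (or a `MoleculeRecord` row; the
#'   `smiles` element is used).
#' @return an object of class `brics_fragmentation`: a list with
#'   `fragments` (data.frame: `fragment`, `smiles`, `labels`, `n_joints`),
#'   `bond_map` (data.frame: `joint`, `frag1`, `lab1`, `frag2`, `lab2`,
#'   `order`), the per-fragment graphs, and the seed's canonical SMILES.
#' @export
brics_fragment <- function(smiles) {
  if (is.list(smiles) || is.data.frame(smiles)) smiles <- smiles$smiles[1]
  mg <- mg_parse(smiles)[[1]]
  if (is.null(mg)) parse_error(paste0("cannot parse SMILES: ", smiles), smiles)
  seed_can <- mg_to_smiles(mg)
  bb <- find_brics_bonds(mg)
  # cut all bonds; atom ids are stable under mg_cut_bond so locate each bond
  # by its atom pair at cut time
  cut <- mg
  joints <- data.frame(joint = integer(0), d1 = integer(0), d2 = integer(0),
                       lab1 = integer(0), lab2 = integer(0), order = integer(0))
  if (nrow(bb)) {
    for (j in seq_len(nrow(bb))) {
      k <- which((cut$bonds$a1 == bb$a1[j] & cut$bonds$a2 == bb$a2[j]) |
                 (cut$bonds$a1 == bb$a2[j] & cut$bonds$a2 == bb$a1[j]))[1]
      flip <- cut$bonds$a1[k] != bb$a1[j]
      l1 <- if (flip) bb$lab2[j] else bb$lab1[j]
      l2 <- if (flip) bb$lab1[j] else bb$lab2[j]
      cut <- mg_cut_bond(cut, k, l1, l2)
      d <- attr(cut, "dummies")
      joints <- rbind(joints, data.frame(
        joint = j, d1 = d[1], d2 = d[2], lab1 = l1, lab2 = l2,
        order = bb$order[j]))
      if (flip) {  # keep (lab1, d1) on the bb$a1 side ordering irrelevant;
        joints$lab1[nrow(joints)] <- l1
        joints$lab2[nrow(joints)] <- l2
      }
    }
  }
  comp <- mg_components(cut)
  nfrag <- max(comp)
  graphs <- vector("list", nfrag)
  frag_smiles <- character(nfrag)
  labels <- vector("list", nfrag)
  joint_tab <- data.frame(joint = integer(0), frag = integer(0),
                          dummy = integer(0), label = integer(0))
  for (f in seq_len(nfrag)) {
    sub <- mg_subgraph(cut, which(comp == f))
    map <- attr(sub, "map")
    graphs[[f]] <- sub
    frag_smiles[f] <- mg_to_smiles(sub)
    labels[[f]] <- sort(sub$atoms$label[sub$atoms$elem == "*"])
    if (nrow(joints)) {
      for (j in seq_len(nrow(joints))) {
        for (side in 1:2) {
          dg <- joints[[c("d1", "d2")[side]]][j]
          lab <- joints[[c("lab1", "lab2")[side]]][j]
          loc <- match(dg, map)
          if (!is.na(loc)) {
            joint_tab <- rbind(joint_tab, data.frame(
              joint = joints$joint[j], frag = f, dummy = loc, label = lab))
          }
        }
      }
    }
  }
  bond_map <- if (nrow(joints)) {
    do.call(rbind, lapply(seq_len(nrow(joints)), function(j) {
      rows <- joint_tab[joint_tab$joint == j, ]
      data.frame(joint = j,
                 frag1 = rows$frag[1], lab1 = rows$label[1],
                 frag2 = rows$frag[2], lab2 = rows$label[2],
                 order = joints$order[j])
    }))
  } else {
    data.frame(joint = integer(0), frag1 = integer(0), lab1 = integer(0),
               frag2 = integer(0), lab2 = integer(0), order = integer(0))
  }
  structure(list(
    fragments = data.frame(
      fragment = seq_len(nfrag),
      smiles = frag_smiles,
      labels = vapply(labels, paste, character(1), collapse = "+"),
      n_joints = vapply(seq_len(nfrag),
                        function(f) sum(joint_tab$frag == f), integer(1))),
    bond_map = bond_map,
    graphs = graphs,
    joint_tab = joint_tab,
    seed_smiles = seed_can
  ), class = "brics_fragmentation")
}

#' @export
print.brics_fragmentation <- function(x, ...) {
  cat("BRICS fragmentation of", x$seed_smiles, "\n")
  cat(nrow(x$fragments), "fragment(s),", nrow(x$bond_map), "cut bond(s)\n")
  print(x$fragments)
  invisible(x)
}

# Reassemble from per-fragment graphs and a joint assignment.
# graphs: list of molgraph; joint_tab: data.frame(joint, frag, dummy, label);
# bond_map used for label/order verification.
.assemble_graphs <- function(graphs, joint_tab, bond_map) {
  offsets <- cumsum(c(0L, vapply(graphs, function(g) nrow(g$atoms),
                                 integer(1))))
  atoms <- do.call(rbind, lapply(graphs, `[[`, "atoms"))
  rownames(atoms) <- NULL
  bonds <- do.call(rbind, lapply(seq_along(graphs), function(f) {
    b <- graphs[[f]]$bonds
    b$a1 <- b$a1 + offsets[f]
    b$a2 <- b$a2 + offsets[f]
    b
  }))
  rownames(bonds) <- NULL
  big <- new_molgraph(atoms, bonds)
  adj_dummies <- integer(0)
  for (j in unique(joint_tab$joint)) {
    rows <- joint_tab[joint_tab$joint == j, ]
    if (nrow(rows) != 2L) validation_error("joint must connect two fragments")
    bm <- bond_map[bond_map$joint == j, ]
    labs <- sort(c(rows$label[1], rows$label[2]))
    want <- sort(c(bm$lab1, bm$lab2))
    if (!identical(labs, want)) {
      validation_error(sprintf(
        "label mismatch at joint %d: have {%s}, expected {%s}", j,
        paste(labs, collapse = ","), paste(want, collapse = ",")))
    }
    g1 <- rows$frag[1]; g2 <- rows$frag[2]
    d1 <- rows$dummy[1] + offsets[g1]
    d2 <- rows$dummy[2] + offsets[g2]
    b1 <- which(big$bonds$a1 == d1 | big$bonds$a2 == d1)
    b2 <- which(big$bonds$a1 == d2 | big$bonds$a2 == d2)
    if (length(b1) != 1L || length(b2) != 1L ||
        big$bonds$order[b1] != big$bonds$order[b2]) {
      validation_error(sprintf("bond-order mismatch at joint %d", j))
    }
    anchor1 <- setdiff(unlist(big$bonds[b1, c("a1", "a2")]), d1)
    anchor2 <- setdiff(unlist(big$bonds[b2, c("a1", "a2")]), d2)
    big$bonds <- rbind(big$bonds, data.frame(a1 = anchor1, a2 = anchor2,
                                             order = big$bonds$order[b1]))
    adj_dummies <- c(adj_dummies, d1, d2)
  }
  if (length(adj_dummies)) big <- mg_drop_atoms(big, adj_dummies)
  big
}

#' Reassemble a BRICS fragmentation
#'
#' Joins fragments back along the recorded bond map. Called on an unmodified
#' fragmentation this regenerates the input molecule exactly; fragments may
#' first be swapped with [swap_fragment()] provided attachment labels match.
#'
#' @param fragmentation a `brics_fragmentation` object.
#' @return canonical SMILES of the reassembled molecule.
#' @export
brics_reassemble <- function(fragmentation) {
  stopifnot(inherits(fragmentation, "brics_fragmentation"))
  big <- .assemble_graphs(fragmentation$graphs, fragmentation$joint_tab,
                          fragmentation$bond_map)
  mg_to_smiles(big)
}

# Replace fragment `pos` of a fragmentation with a labelled fragment graph.
# The replacement's dummies are assigned to the old fragment's joints by
# label (deterministic first-fit); NULL if labels cannot be matched.
swap_fragment <- function(fragmentation, pos, newgraph, relax = FALSE) {
  jt <- fragmentation$joint_tab
  mine <- jt[jt$frag == pos, , drop = FALSE]
  dummies <- which(newgraph$atoms$elem == "*")
  labs <- newgraph$atoms$label[dummies]
  key_need <- label_key(mine$label, relax)
  if (label_key(labs, relax) != key_need) return(NULL)
  # assign replacement dummies to joints by label, first-fit
  used <- logical(length(dummies))
  assigned <- integer(nrow(mine))
  for (i in seq_len(nrow(mine))) {
    want <- mine$label[i]
    cand <- which(!used & (labs == want |
      (relax & .relax_labels(labs) == .relax_labels(want))))
    if (!length(cand)) return(NULL)
    used[cand[1]] <- TRUE
    assigned[i] <- dummies[cand[1]]
  }
  graphs <- fragmentation$graphs
  graphs[[pos]] <- newgraph
  jt$dummy[jt$frag == pos] <- assigned
  jt$label[jt$frag == pos] <- newgraph$atoms$label[assigned]
  # the stored bond-map labels may no longer equal the replacement's labels
  # under relaxation; rewrite them so assembly label checks stay exact
  bm <- fragmentation$bond_map
  for (i in seq_len(nrow(mine))) {
    j <- mine$joint[i]
    newlab <- newgraph$atoms$label[assigned[i]]
    if (bm$frag1[bm$joint == j] == pos) bm$lab1[bm$joint == j] <- newlab
    if (bm$frag2[bm$joint == j] == pos) bm$lab2[bm$joint == j] <- newlab
  }
  tryCatch(mg_to_smiles(.assemble_graphs(graphs, jt, bm)),
           error = function(e) NULL)
}
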