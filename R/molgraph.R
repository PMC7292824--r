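# Internal molecular graph representation.
#
# A `molgraph` is a light connection-table view of one molecule:
#   atoms: data.frame(elem, label, charge, arom)
#     - elem    element symbol, "*" for an attachment-point dummy
#     - label   integer attachment label (BRICS bond-type code), 0 = unlabelled
#     - charge  formal charge
#     - arom    TRUE if the atom sits in an aromatic ring (perceived at parse)
#   bonds: data.frame(a1, a2, order)  (kekulized orders from OpenBabel)
# Hydrogens are implicit throughout. Structure parsing, canonical SMILES and
# aromaticity perception are delegated to OpenBabel/ChemmineR; the graph
# exists so that fragmentation and recombination can edit bonds directly.

new_molgraph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

# Parse "M  ISO"/"M  CHG" property lines from a molblock.
.parse_m_pairs <- function(lines, tag) {
  out <- integer(0)
  for (ln in grep(paste0("^M  ", tag), lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub(paste0("^M  ", tag), "", ln)),
                                "\\s+")[[1]])
    n <- toks[1]
    for (k in seq_len(n)) out[toks[2 * k]] <- toks[2 * k + 1]
  }
  out
}

# One molblock's text -> molgraph (atoms/bonds + ISO/CHG), or NULL on failure.
.molblock_to_graph <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  cl <- grep("V2000", lines)[1]
  if (is.na(cl)) return(NULL)
  natoms <- as.integer(substr(lines[cl], 1, 3))
  nbonds <- as.integer(substr(lines[cl], 4, 6))
  if (is.na(natoms) || natoms < 1) return(NULL)
  at <- lines[cl + seq_len(natoms)]
  elem <- trimws(substr(at, 32, 34))
  if (nbonds > 0) {
    bl <- lines[cl + natoms + seq_len(nbonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  label <- charge <- integer(natoms)
  iso <- .parse_m_pairs(lines, "ISO")
  chg <- .parse_m_pairs(lines, "CHG")
  if (length(iso)) label[seq_along(iso)] <- ifelse(is.na(iso), 0L, iso)
  if (length(chg)) charge[seq_along(chg)] <- ifelse(is.na(chg), 0L, chg)
  atoms <- data.frame(elem = elem, label = label, charge = charge,
                      arom = FALSE)
  new_molgraph(atoms, bonds)
}

# Aromatic perception via ChemmineR ring enumeration on the OB-generated SDF,
# tightened with a Hueckel sanity check: a ring is only accepted as aromatic
# if every ring carbon carries a double bond (in the kekulized connection
# table). ChemmineR alone flags saturated five-membered heterocycles such as
# pyrrolidine or tetrahydrofuran as aromatic. Returns
# list(arom_atoms = integer ids, n_arom_rings = count of aromatic rings of
# size <= 7).
.perceive_aromatic <- function(sdf, mg) {
  res <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 7, type = "all",
                                      arom = TRUE, inner = FALSE)),
    error = function(e) NULL
  )
  if (is.null(res) || !length(res$RINGS)) {
    return(list(arom_atoms = integer(0), n_arom_rings = 0L))
  }
  arom <- unlist(res$AROMATIC)
  ring_atoms <- lapply(res$RINGS, function(r) {
    as.integer(sub("^.*_", "", r))
  })
  has_dbl <- logical(nrow(mg$atoms))
  dbl <- mg$bonds$order >= 2L
  has_dbl[unique(c(mg$bonds$a1[dbl], mg$bonds$a2[dbl]))] <- TRUE
  sane <- vapply(ring_atoms, function(ids) {
    cs <- ids[mg$atoms$elem[ids] == "C"]
    all(has_dbl[cs])
  }, logical(1))
  arom <- arom & sane
  arom_atoms <- unique(unlist(ring_atoms[arom]))
  list(arom_atoms = as.integer(arom_atoms %||% integer(0)),
       n_arom_rings = sum(arom))
}

# Parse a vector of SMILES into molgraphs. Returns a list the same length as
# the input; failed parses are NULL. Each element also carries the SDF object
# (attribute "sdf") for descriptor/fingerprint reuse.
mg_parse <- function(smiles, perceive = TRUE) {
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) next
    txt <- tryCatch(ob_convert("SMI", "SDF", paste0(s, "\n")),
                    error = function(e) "")
    if (!grepl("V2000", txt, fixed = TRUE)) next
    mg <- .molblock_to_graph(txt)
    if (is.null(mg)) next
    if (perceive) {
      sdf <- .sdf_from_text(txt)
      if (!is.null(sdf)) {
        ar <- .perceive_aromatic(sdf, mg)
        mg$atoms$arom[ar$arom_atoms] <- TRUE
        attr(mg, "n_arom_rings") <- ar$n_arom_rings
        attr(mg, "sdf") <- sdf
      }
    }
    out[[i]] <- mg
  }
  out
}

# SDF text (one molecule) -> ChemmineR SDF object.
.sdf_from_text <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sdfstr <- methods::new(methods::getClassDef("SDFstr",
                                              package = "ChemmineR"),
                         a = list(lines))
  set <- tryCatch(
    suppressMessages(suppressWarnings(methods::as(sdfstr, "SDFset"))),
    error = function(e) NULL)
  if (is.null(set) || length(set) < 1) return(NULL)
  set[[1]]
}

# molgraph -> V2000 molblock text (with M ISO for attachment labels and
# M CHG for formal charges).
mg_to_molblock <- function(mg, title = "mol") {
  n <- nrow(mg$atoms)
  b <- nrow(mg$bonds)
  hdr <- c(title, " molforge", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, mg$atoms$elem)
  bl <- if (b > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", mg$bonds$a1, mg$bonds$a2, mg$bonds$order)
  } else character(0)
  mlines <- character(0)
  lab <- which(mg$atoms$label != 0L)
  if (length(lab)) {
    mlines <- c(mlines, sprintf("M  ISO%3d%s", length(lab),
      paste0(sprintf("%4d%4d", lab, mg$atoms$label[lab]), collapse = "")))
  }
  chg <- which(mg$atoms$charge != 0L)
  if (length(chg)) {
    mlines <- c(mlines, sprintf("M  CHG%3d%s", length(chg),
      paste0(sprintf("%4d%4d", chg, mg$atoms$charge[chg]), collapse = "")))
  }
  paste(c(hdr, at, bl, mlines, "M  END", "$$$$", ""), collapse = "\n")
}

# molgraph -> canonical SMILES (attachment labels preserved as isotopes).
mg_to_smiles <- function(mg) {
  out <- tryCatch(ob_convert("MOL", "CAN", mg_to_molblock(mg)),
                  error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

# ---- graph helpers ----

mg_degree <- function(mg) {
  tabulate(c(mg$bonds$a1, mg$bonds$a2), nbins = nrow(mg$atoms))
}

# adjacency: list of data.frame(nbr, order, bond) per atom
mg_adjacency <- function(mg) {
  n <- nrow(mg$atoms)
  adj <- rep(list(data.frame(nbr = integer(0), order = integer(0),
                             bond = integer(0))), n)
  if (!nrow(mg$bonds)) return(adj)
  long <- rbind(
    data.frame(a = mg$bonds$a1, nbr = mg$bonds$a2, order = mg$bonds$order,
               bond = seq_len(nrow(mg$bonds))),
    data.frame(a = mg$bonds$a2, nbr = mg$bonds$a1, order = mg$bonds$order,
               bond = seq_len(nrow(mg$bonds)))
  )
  sp <- split(long[c("nbr", "order", "bond")], long$a)
  adj[as.integer(names(sp))] <- sp
  adj
}

# Ring-bond flags via bridge detection (a bond is in a ring iff not a bridge).
mg_ring_bonds <- function(mg) {
  nb <- nrow(mg$bonds)
  if (!nb) return(logical(0))
  n <- nrow(mg$atoms)
  adj <- mg_adjacency(mg)
  disc <- low <- integer(n)
  visited <- logical(n)
  is_bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(n)) {
    if (visited[root]) next
    # iterative DFS with parent-edge tracking
    stack <- list(list(v = root, pe = 0L, i = 1L))
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    visited[root] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top$v
      nbrs <- adj[[v]]
      if (top$i <= nrow(nbrs)) {
        stack[[length(stack)]]$i <- top$i + 1L
        w <- nbrs$nbr[top$i]
        be <- nbrs$bond[top$i]
        if (be == top$pe) next
        if (visited[w]) {
          low[v] <- min(low[v], disc[w])
        } else {
          timer <- timer + 1L
          disc[w] <- low[w] <- timer
          visited[w] <- TRUE
          stack[[length(stack) + 1L]] <- list(v = w, pe = be, i = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[top$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

mg_ring_atoms <- function(mg, ring_bonds = mg_ring_bonds(mg)) {
  out <- logical(nrow(mg$atoms))
  if (any(ring_bonds)) {
    out[unique(c(mg$bonds$a1[ring_bonds], mg$bonds$a2[ring_bonds]))] <- TRUE
  }
  out
}

# Connected components; returns integer component id per atom.
mg_components <- function(mg) {
  n <- nrow(mg$atoms)
  comp <- integer(n)
  adj <- mg_adjacency(mg)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      ws <- adj[[v]]$nbr
      new <- ws[comp[ws] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

# Extract the subgraph on a set of atom ids (renumbered); attribute "map"
# gives old id for each new id.
mg_subgraph <- function(mg, atom_ids) {
  atom_ids <- sort(atom_ids)
  newid <- integer(nrow(mg$atoms))
  newid[atom_ids] <- seq_along(atom_ids)
  keep <- mg$bonds$a1 %in% atom_ids & mg$bonds$a2 %in% atom_ids
  bonds <- mg$bonds[keep, , drop = FALSE]
  bonds$a1 <- newid[bonds$a1]
  bonds$a2 <- newid[bonds$a2]
  rownames(bonds) <- NULL
  out <- new_molgraph(mg$atoms[atom_ids, , drop = FALSE], bonds)
  rownames(out$atoms) <- NULL
  attr(out, "map") <- atom_ids
  out
}

# Cut a bond: replace bond k by two labelled dummy atoms, one on each side.
# Returns the graph plus attr "dummies" = c(dummy attached to a1 side,
# dummy attached to a2 side).
mg_cut_bond <- function(mg, k, lab1 = 0L, lab2 = 0L) {
  stopifnot(k >= 1, k <= nrow(mg$bonds))
  a1 <- mg$bonds$a1[k]
  a2 <- mg$bonds$a2[k]
  ord <- mg$bonds$order[k]
  mg$bonds <- mg$bonds[-k, , drop = FALSE]
  rownames(mg$bonds) <- NULL
  n <- nrow(mg$atoms)
  d1 <- n + 1L
  d2 <- n + 2L
  mg$atoms <- rbind(mg$atoms,
    data.frame(elem = "*", label = as.integer(lab1), charge = 0L, arom = FALSE),
    data.frame(elem = "*", label = as.integer(lab2), charge = 0L, arom = FALSE))
  rownames(mg$atoms) <- NULL
  mg$bonds <- rbind(mg$bonds,
    data.frame(a1 = a1, a2 = d1, order = ord),
    data.frame(a1 = a2, a2 = d2, order = ord))
  rownames(mg$bonds) <- NULL
  attr(mg, "dummies") <- c(d1, d2)
  mg
}

# Join two graphs at one dummy atom each: the dummies are removed and their
# anchor atoms bonded with the order of the dummy bonds (must agree).
mg_join <- function(mg1, dummy1, mg2, dummy2) {
  b1 <- which(mg1$bonds$a1 == dummy1 | mg1$bonds$a2 == dummy1)
  b2 <- which(mg2$bonds$a1 == dummy2 | mg2$bonds$a2 == dummy2)
  if (length(b1) != 1L || length(b2) != 1L) {
    validation_error("attachment dummy must have exactly one bond")
  }
  ord1 <- mg1$bonds$order[b1]
  ord2 <- mg2$bonds$order[b2]
  if (ord1 != ord2) {
    validation_error("bond-order mismatch at attachment point")
  }
  anchor1 <- setdiff(c(mg1$bonds$a1[b1], mg1$bonds$a2[b1]), dummy1)
  anchor2 <- setdiff(c(mg2$bonds$a1[b2], mg2$bonds$a2[b2]), dummy2)
  n1 <- nrow(mg1$atoms)
  atoms <- rbind(mg1$atoms, mg2$atoms)
  rownames(atoms) <- NULL
  b2all <- mg2$bonds
  b2all$a1 <- b2all$a1 + n1
  b2all$a2 <- b2all$a2 + n1
  bonds <- rbind(mg1$bonds, b2all,
                 data.frame(a1 = anchor1, a2 = anchor2 + n1, order = ord1))
  out <- new_molgraph(atoms, bonds)
  # drop the two dummies, renumbering
  drop <- c(dummy1, dummy2 + n1)
  keepb <- !(bonds$a1 %in% drop | bonds$a2 %in% drop)
  keep_atoms <- setdiff(seq_len(nrow(atoms)), drop)
  out$bonds <- bonds[keepb, , drop = FALSE]
  sub <- mg_subgraph(new_molgraph(atoms, out$bonds), keep_atoms)
  attr(sub, "map") <- NULL
  sub
}

# Remove one atom (plus incident bonds), renumbering.
mg_drop_atoms <- function(mg, atom_ids) {
  keep <- setdiff(seq_len(nrow(mg$atoms)), atom_ids)
  keepb <- !(mg$bonds$a1 %in% atom_ids | mg$bonds$a2 %in% atom_ids)
  sub <- mg_subgraph(new_molgraph(mg$atoms, mg$bonds[keepb, , drop = FALSE]),
                     keep)
  attr(sub, "map") <- NULL
  sub
}

mg_heavy_atoms <- function(mg) {
  sum(!mg$atoms$elem %in% c("H", "*"))
}
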