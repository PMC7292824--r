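# Core molecular structure handling: canonicalisation, descriptors,
# fingerprints, substructure matching, frameworks and table I/O.
#
# Molecule tables are plain data.frames with the mandatory columns
# `id` and `smiles` (canonical), the provenance columns `method`, `seed_id`,
# `change_note`, and any number of additional numeric property columns.

.prov_cols <- c("method", "seed_id", "change_note")

.empty_records <- function() {
  data.frame(id = character(0), smiles = character(0),
             method = character(0), seed_id = character(0),
             change_note = character(0))
}

.empty_rejects <- function() {
  data.frame(row = integer(0), input = character(0), reason = character(0))
}

#' Build a molecule table from SMILES, collecting rejects
#'
#' Parses and canonicalises each structure. Invalid SMILES are not fatal:
#' they are collected into a reject table so that workflow tasks can count
#' and report them.
#'
#' @param smiles character vector of SMILES.
#' @param id compound identifiers; auto-assigned `mol_0001`... when `NULL`.
#' @param method provenance tag (`mmp`, `brics`, `similarity`, `human`,
#'   `array`).
#' @param seed_id,change_note optional provenance detail, recycled.
#' @return list with `records` (valid rows, canonical SMILES) and `rejects`
#'   (row number, offending input, reason).
#' @export
molecule_table <- function(smiles, id = NULL, method = "human",
                           seed_id = NA_character_,
                           change_note = NA_character_) {
  n <- length(smiles)
  if (is.null(id)) id <- sprintf("mol_%04d", seq_len(n))
  if (anyDuplicated(id)) validation_error("molecule ids must be unique")
  can <- ob_canonical(smiles)
  ok <- !is.na(can)
  records <- data.frame(id = as.character(id)[ok], smiles = can[ok],
                        method = rep_len(method, n)[ok],
                        seed_id = as.character(rep_len(seed_id, n))[ok],
                        change_note = as.character(rep_len(change_note, n))[ok])
  rejects <- data.frame(row = which(!ok), input = smiles[!ok],
                        reason = rep("SMILES parse failure", sum(!ok)))
  list(records = records, rejects = rejects)
}

#' Parse and canonicalise a single SMILES
#'
#' @param smiles a non-empty SMILES string.
#' @param id compound id (defaults to `"mol_0001"`).
#' @return a one-row molecule table (see [molecule_table()]).
#'   Idempotent: feeding the canonical form back returns the same structure.
#' @export
parse_and_canonicalise <- function(smiles, id = "mol_0001") {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) parse_error("empty SMILES", smiles)
  can <- ob_canonical(smiles)
  if (is.na(can)) parse_error(paste0("cannot parse SMILES: ", smiles), smiles)
  data.frame(id = id, smiles = can, method = "human",
             seed_id = NA_character_, change_note = NA_character_)
}

# ---- descriptors ----

# Rotatable bonds: acyclic single bonds between two non-terminal heavy atoms,
# neither of which is part of a triple bond.
.count_rotb <- function(mg) {
  if (!nrow(mg$bonds)) return(0L)
  rb <- mg_ring_bonds(mg)
  deg <- mg_degree(mg)
  triple <- logical(nrow(mg$atoms))
  tr <- mg$bonds$order == 3L
  triple[unique(c(mg$bonds$a1[tr], mg$bonds$a2[tr]))] <- TRUE
  ok <- mg$bonds$order == 1L & !rb &
    deg[mg$bonds$a1] > 1L & deg[mg$bonds$a2] > 1L &
    !triple[mg$bonds$a1] & !triple[mg$bonds$a2] &
    mg$atoms$elem[mg$bonds$a1] != "*" & mg$atoms$elem[mg$bonds$a2] != "*"
  sum(ok)
}

#' Compute the standard property vector for a molecule table
#'
#' Adds (or overwrites) the columns `MW` (g/mol), `heavy_atoms`, `HBD`,
#' `HBA`, `RotB`, `TPSA` (A^2), `clogP`, `aromatic_rings` and `PFI_proxy`.
#' `PFI_proxy = clogP + aromatic_rings` is a desk-computable stand-in for
#' the Property Forecast Index, whose published form uses measured
#' chromatographic logD7.4; computed clogP replaces the measurement.
#' MW, clogP, TPSA, HBD and HBA come from OpenBabel; counts are taken from
#' the package's own connection-table analysis. Deterministic: identical
#' structures always yield identical vectors.
#'
#' @param mols a molecule table (or anything with a `smiles` column).
#' @return the table with property columns appended.
#' @export
compute_properties <- function(mols) {
  if (!nrow(mols)) {
    for (p in c("MW", "heavy_atoms", "HBD", "HBA", "RotB", "TPSA", "clogP",
                "aromatic_rings", "PFI_proxy")) {
      mols[[p]] <- numeric(0)
    }
    return(mols)
  }
  props <- suppressWarnings(ChemmineOB::prop_OB(.records_to_obmols(mols)))
  mols$MW <- props$MW
  mols$HBD <- props$HBD
  mols$HBA <- props$HBA1
  mols$TPSA <- props$TPSA
  mols$clogP <- props$logP
  mgs <- mg_parse(mols$smiles)
  mols$heavy_atoms <- vapply(mgs, function(m) {
    if (is.null(m)) NA_integer_ else mg_heavy_atoms(m)
  }, integer(1))
  mols$RotB <- vapply(mgs, function(m) {
    if (is.null(m)) NA_integer_ else .count_rotb(m)
  }, integer(1))
  mols$aromatic_rings <- vapply(mgs, function(m) {
    if (is.null(m)) NA_integer_ else as.integer(attr(m, "n_arom_rings") %||% 0L)
  }, integer(1))
  mols$PFI_proxy <- mols$clogP + mols$aromatic_rings
  mols
}

# molecule table -> list of OpenBabel molecule references (structures are
# canonical and valid, so the batch conversion is safe).
.records_to_obmols <- function(mols) {
  txt <- paste0(paste(mols$smiles, mols$id, sep = "\t"), "\n", collapse = "")
  refs <- suppressWarnings(ChemmineOB::forEachMol("SMILES", txt, identity))
  if (length(refs) != nrow(mols)) {
    parse_error("internal: molecule table contains unparseable structures")
  }
  refs
}

# ---- fingerprints ----

.fp_backend <- c(path7 = "FP2", circular2 = "ECFP4")

#' Fingerprint molecules
#'
#' Two open fingerprints back the similarity machinery: `path7`, OpenBabel's
#' linear-path fingerprint (paths of length 1-7 hashed into 1024 bits), and
#' `circular2`, OpenBabel's radius-2 circular (ECFP4-class) fingerprint
#' (4096 bits). Deterministic per structure.
#'
#' @param mols molecule table.
#' @param kind `"path7"` or `"circular2"`.
#' @return list of `molforge_fp` objects (one per row): sorted on-bit
#'   positions plus the kind and width.
#' @export
fingerprint <- function(mols, kind = c("path7", "circular2")) {
  kind <- match.arg(kind)
  if (!nrow(mols)) return(list())
  m <- suppressWarnings(ChemmineOB::fingerprint_OB(
    .records_to_obmols(mols), .fp_backend[[kind]]))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(mols))
  lapply(seq_len(nrow(m)), function(i) {
    structure(list(kind = kind, nbits = ncol(m),
                   bits = which(m[i, ] != 0)),
              class = "molforge_fp")
  })
}

#' Tanimoto similarity of two fingerprints
#'
#' |a intersect b| / |a union b|; symmetric, in `[0, 1]`, equal to 1 exactly
#' on identical bit sets, and defined as 1 when both sets are empty.
#'
#' @param a,b `molforge_fp` objects of the same kind.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "molforge_fp"), inherits(b, "molforge_fp"))
  if (!identical(a$kind, b$kind)) {
    validation_error(sprintf("fingerprint kind mismatch: %s vs %s",
                             a$kind, b$kind))
  }
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(union(a$bits, b$bits))
  if (nu == 0L) return(1)
  ni / nu
}

# All-pairs Tanimoto between two fingerprint lists -> matrix.
.tanimoto_matrix <- function(fps1, fps2) {
  outer(seq_along(fps1), seq_along(fps2),
        Vectorize(function(i, j) tanimoto(fps1[[i]], fps2[[j]])))
}

# ---- substructure ----

#' SMARTS substructure match
#'
#' @param mols molecule table.
#' @param pattern a SMARTS pattern.
#' @return logical vector, `TRUE` where the pattern matches at least once.
#' @export
match_smarts <- function(mols, pattern) {
  .check_smarts(pattern)
  if (!nrow(mols)) return(logical(0))
  counts <- suppressWarnings(ChemmineOB::smartsSearch_OB(
    .records_to_obmols(mols), pattern, uniqueMatches = TRUE))
  as.vector(counts) > 0
}

# Validate a SMARTS pattern; raises molforge_smarts_error when it does not
# compile (probed against a one-atom molecule).
.check_smarts <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    smarts_error("SMARTS pattern must be a non-empty string", pattern)
  }
  probe <- suppressWarnings(ChemmineOB::forEachMol("SMILES", "C\tprobe\n",
                                                   identity))
  ok <- tryCatch({
    suppressWarnings(ChemmineOB::smartsSearch_OB(probe, pattern,
                                                 uniqueMatches = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    smarts_error(paste0("invalid SMARTS pattern: ", pattern), pattern)
  }
  invisible(TRUE)
}

# ---- frameworks ----

#' Murcko framework of each molecule
#'
#' `scaffold` keeps ring systems and their connecting linkers (atoms
#' double-bonded to the retained core, e.g. carbonyl oxygens, stay);
#' `generic` additionally erases atom types to carbon and bond orders to
#' single. Acyclic molecules map to the empty-framework sentinel `""`.
#'
#' @param mols molecule table.
#' @param level `"scaffold"` or `"generic"`.
#' @return character vector of framework canonical SMILES (`""` for acyclic
#'   molecules).
#' @export
murcko_framework <- function(mols, level = c("scaffold", "generic")) {
  level <- match.arg(level)
  vapply(mols$smiles, function(s) {
    mg <- mg_parse(s, perceive = FALSE)[[1]]
    if (is.null(mg)) return(NA_character_)
    repeat {
      deg <- mg_degree(mg)
      # prune terminal atoms attached by a single bond
      single_at <- logical(nrow(mg$atoms))
      ords <- integer(nrow(mg$atoms))
      for (k in seq_len(nrow(mg$bonds))) {
        ords[mg$bonds$a1[k]] <- max(ords[mg$bonds$a1[k]], mg$bonds$order[k])
        ords[mg$bonds$a2[k]] <- max(ords[mg$bonds$a2[k]], mg$bonds$order[k])
      }
      drop <- which(deg <= 1L & (ords <= 1L | deg == 0L))
      if (!length(drop) || length(drop) == nrow(mg$atoms)) break
      mg <- mg_drop_atoms(mg, drop)
    }
    if (!nrow(mg$bonds) || !any(mg_ring_bonds(mg))) return("")
    if (level == "generic") {
      mg$atoms$elem <- "C"
      mg$atoms$charge <- 0L
      mg$atoms$label <- 0L
      mg$bonds$order <- 1L
    }
    out <- mg_to_smiles(mg)
    if (is.na(out)) "" else out
  }, character(1), USE.NAMES = FALSE)
}

# ---- table I/O ----

#' Read a molecule table from disk
#'
#' Formats: `csv_with_smiles` (UTF-8, header, mandatory `id,smiles`
#' columns, additional numeric columns kept as properties), `smi` (one
#' SMILES per line, optional second whitespace-separated token as id) and
#' `sdf` (V2000/V3000; id from `id_tag`, auto-assigned when absent).
#' Malformed rows are collected into the reject table, never fatal; row
#' order of valid rows is preserved.
#'
#' @param path input file.
#' @param format one of `"csv_with_smiles"`, `"smi"`, `"sdf"`.
#' @param id_tag SDF data field holding the compound id.
#' @return list(records, rejects).
#' @export
read_molecules <- function(path, format = c("csv_with_smiles", "smi", "sdf"),
                           id_tag = "id") {
  format <- match.arg(format)
  if (!file.exists(path)) validation_error(paste0("no such file: ", path))
  if (format == "csv_with_smiles") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    if (!all(c("id", "smiles") %in% names(tab))) {
      validation_error("CSV must have 'id' and 'smiles' columns")
    }
    res <- molecule_table(tab$smiles, id = tab$id)
    extra <- setdiff(names(tab), c("id", "smiles"))
    for (col in extra) {
      v <- tab[[col]]
      if (col %in% .prov_cols) {
        res$records[[col]] <- as.character(v)[match(res$records$id, tab$id)]
      } else {
        res$records[[col]] <- suppressWarnings(
          as.numeric(v)[match(res$records$id, tab$id)])
      }
    }
    res
  } else if (format == "smi") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    toks <- strsplit(lines, "\\s+")
    smi <- vapply(toks, `[`, character(1), 1)
    ids <- vapply(toks, function(t) {
      if (length(t) >= 2) t[2] else NA_character_
    }, character(1))
    if (anyNA(ids)) ids[is.na(ids)] <-
        sprintf("mol_%04d", which(is.na(ids)))
    molecule_table(smi, id = ids)
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- suppressWarnings(ChemmineR::validSDF(sdfset))
    rejects <- data.frame(row = which(!valid),
                          input = rep("<sdf record>", sum(!valid)),
                          reason = rep("invalid SDF record", sum(!valid)))
    sdfset <- sdfset[valid]
    if (!length(sdfset)) return(list(records = .empty_records(),
                                     rejects = rejects))
    smi <- as.character(
      suppressWarnings(ChemmineR::sdf2smiles(sdfset)))
    blocks <- ChemmineR::datablock(sdfset)
    ids <- vapply(seq_along(blocks), function(i) {
      db <- blocks[[i]]
      if (length(db) && id_tag %in% names(db)) db[[id_tag]]
      else sprintf("mol_%04d", i)
    }, character(1))
    res <- molecule_table(smi, id = ids)
    # numeric data fields become properties
    fields <- setdiff(unique(unlist(lapply(blocks, names))), id_tag)
    for (f in fields) {
      v <- vapply(blocks, function(db) {
        if (f %in% names(db)) db[[f]] else NA_character_
      }, character(1))
      num <- suppressWarnings(as.numeric(v))
      if (any(!is.na(num))) res$records[[f]] <- num[match(res$records$id, ids)]
    }
    res$rejects <- rbind(rejects, res$rejects)
    res
  }
}

#' Write a molecule table to disk
#'
#' Inverse of [read_molecules()]: `write` then `read` round-trips ids,
#' canonical structures and numeric properties for all three formats.
#'
#' @param mols molecule table.
#' @param path output file.
#' @param format one of `"csv_with_smiles"`, `"smi"`, `"sdf"`.
#' @param id_tag SDF data field to store the id under.
#' @export
write_molecules <- function(mols, path,
                            format = c("csv_with_smiles", "smi", "sdf"),
                            id_tag = "id") {
  format <- match.arg(format)
  if (format == "csv_with_smiles") {
    utils::write.csv(mols, path, row.names = FALSE, quote = TRUE)
  } else if (format == "smi") {
    writeLines(paste(mols$smiles, mols$id), path)
  } else {
    numcols <- names(mols)[vapply(mols, is.numeric, logical(1))]
    blocks <- vapply(seq_len(nrow(mols)), function(i) {
      txt <- ob_convert("SMI", "SDF",
                        paste0(mols$smiles[i], "\t", mols$id[i], "\n"))
      fields <- c(sprintf("> <%s>\n%s\n", id_tag, mols$id[i]),
                  vapply(numcols, function(cc) {
                    sprintf("> <%s>\n%s\n", cc,
                            format(mols[[cc]][i], digits = 12))
                  }, character(1)))
      sub("\\$\\$\\$\\$\n$",
          paste0(paste(fields, collapse = "\n"), "\n$$$$\n"), txt)
    }, character(1))
    writeLines(paste(blocks, collapse = ""), sep = "", con = path)
  }
  invisible(path)
}

#' Read a SMARTS liability list
#'
#' Plain text, one pattern per line; `#` starts a comment; blank lines
#' ignored. An optional whitespace-separated second token names the pattern,
#' else patterns are named `alert_01`...
#'
#' @param path file path.
#' @return data.frame(id, pattern), every pattern validated.
#' @export
read_smarts_list <- function(path) {
  if (!file.exists(path)) validation_error(paste0("no such file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  pat <- vapply(toks, `[`, character(1), 1)
  ids <- vapply(seq_along(toks), function(i) {
    if (length(toks[[i]]) >= 2) toks[[i]][2] else sprintf("alert_%02d", i)
  }, character(1))
  for (i in seq_along(pat)) {
    tryCatch(.check_smarts(pat[i]), molforge_smarts_error = function(e) {
      smarts_error(sprintf("invalid SMARTS on line %d: %s", i, pat[i]),
                   pat[i])
    })
  }
  data.frame(id = ids, pattern = pat)
}
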