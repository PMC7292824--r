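# Synthetic combinatorial libraries with known additive ground truth, an
# assay/attrition observation model, and a deterministic druglike molecule
# corpus — so every module is testable without external data.

#' Specify a synthetic two/three-position combinatorial library
#'
#' True activities follow the additive Free-Wilson model
#' `y = mu + a_i + b_j (+ c_k)` with per-monomer effects drawn from
#' `N(0, effect_sd)`. A fraction of cells may receive an extra interaction
#' term from `N(0, interaction_sd)` (non-additivity), observations gain
#' `N(0, noise_sd)` measurement noise, and each designed compound
#' independently fails synthesis with probability `attrition_rate`. The
#' defaults mirror a published MMP-12 sparse-array campaign: a 50 x 50
#' virtual library (2500 products) in which 100 designed compounds returned
#' 64 measured records, i.e. roughly 36% attrition, with pIC50-scale
#' responses around a baseline of 5.
#'
#' @param n_levels integer vector (length 2 or 3) of monomers per position.
#' @param scaffold scaffold SMILES with one numbered attachment point per
#'   position; the default is a phenyl-sulphonamide template with two
#'   attachment points.
#' @param mu baseline response (pIC50 units).
#' @param effect_sd SD of true per-monomer contributions.
#' @param noise_sd assay noise SD.
#' @param interaction_fraction fraction of cells with an interaction term.
#' @param interaction_sd SD of interaction terms.
#' @param attrition_rate probability a designed compound returns no data.
#' @param seed RNG seed.
#' @return a `library_spec` list.
#' @export
library_spec <- function(n_levels = c(50L, 50L),
                         scaffold = "O=S(=O)(c1ccc([1*])cc1)N([2*])CC(=O)O",
                         mu = 5, effect_sd = 0.5, noise_sd = 0.2,
                         interaction_fraction = 0, interaction_sd = 0.3,
                         attrition_rate = 0.36, seed = 1L) {
  stopifnot(length(n_levels) %in% c(2L, 3L), all(n_levels >= 2),
            effect_sd >= 0, noise_sd >= 0, interaction_sd >= 0,
            interaction_fraction >= 0, interaction_fraction <= 1,
            attrition_rate >= 0, attrition_rate < 1)
  structure(list(n_levels = as.integer(n_levels), scaffold = scaffold,
                 mu = mu, effect_sd = effect_sd, noise_sd = noise_sd,
                 interaction_fraction = interaction_fraction,
                 interaction_sd = interaction_sd,
                 attrition_rate = attrition_rate, seed = as.integer(seed)),
            class = "library_spec")
}

# deterministic monomer vocabulary: simple alkyl/aryl/heteroaryl R-groups
# cycled and elaborated to the requested count
.monomer_vocabulary <- function(n, prefix) {
  base <- c("[*]C", "[*]CC", "[*]CCC", "[*]C(C)C", "[*]CCCC", "[*]C(C)(C)C",
            "[*]C1CC1", "[*]C1CCC1", "[*]C1CCCC1", "[*]C1CCCCC1",
            "[*]c1ccccc1", "[*]c1ccncc1", "[*]c1cccnc1", "[*]c1ccco1",
            "[*]c1cccs1", "[*]Cc1ccccc1", "[*]CCc1ccccc1", "[*]CO",
            "[*]CCO", "[*]CCN", "[*]CC(=O)O", "[*]CCF", "[*]CC(F)(F)F",
            "[*]COC", "[*]CCOC", "[*]CC#N", "[*]Cc1ccco1", "[*]Cc1cccs1",
            "[*]CC1CC1", "[*]Cc1ccncc1")
  out <- character(n)
  for (i in seq_len(n)) {
    k <- (i - 1L) %% length(base) + 1L
    gen <- (i - 1L) %/% length(base)
    # elaborate repeats with extra methylenes to keep structures distinct
    out[i] <- if (gen == 0) base[k] else {
      sub("[*]", paste0("[*]", strrep("C", gen)), base[k], fixed = TRUE)
    }
  }
  data.frame(id = sprintf("%s%02d", prefix, seq_len(n)), smiles = out)
}

#' Enumerate a synthetic virtual library with ground-truth activities
#'
#' @param spec a [library_spec()].
#' @param structures also enumerate product SMILES from the scaffold and
#'   monomer structures (skip for large purely numerical simulations).
#' @return list with `library` (data.frame: `m1`, `m2`[, `m3`] monomer ids,
#'   0-based `f1`, `f2`[, `f3`] level indices, `y_true`, and `smiles` when
#'   `structures = TRUE`), `monomers` (per-position reagent tables) and
#'   `params` (true `mu`, per-position effect vectors, interaction map).
#' @export
make_library <- function(spec, structures = FALSE) {
  stopifnot(inherits(spec, "library_spec"))
  k <- length(spec$n_levels)
  prefixes <- c("A", "B", "C")[seq_len(k)]
  monomers <- lapply(seq_len(k), function(j) {
    .monomer_vocabulary(spec$n_levels[j], prefixes[j])
  })
  with_seed(spec$seed, {
    effects <- lapply(seq_len(k), function(j) {
      stats::setNames(stats::rnorm(spec$n_levels[j], 0, spec$effect_sd),
                      monomers[[j]]$id)
    })
    grid <- expand.grid(lapply(spec$n_levels, function(n) seq_len(n) - 1L))
    names(grid) <- paste0("f", seq_len(k))
    y <- spec$mu
    for (j in seq_len(k)) y <- y + effects[[j]][grid[[j]] + 1L]
    inter <- numeric(nrow(grid))
    if (spec$interaction_fraction > 0) {
      pick <- which(stats::runif(nrow(grid)) < spec$interaction_fraction)
      inter[pick] <- stats::rnorm(length(pick), 0, spec$interaction_sd)
    }
    lib <- grid
    for (j in seq_len(k)) {
      lib[[paste0("m", j)]] <- monomers[[j]]$id[grid[[j]] + 1L]
    }
    lib$y_true <- as.vector(y + inter)
    if (structures) {
      lib$smiles <- vapply(seq_len(nrow(lib)), function(r) {
        .assemble_product(spec$scaffold, vapply(seq_len(k), function(j) {
          monomers[[j]]$smiles[grid[r, j] + 1L]
        }, character(1)))
      }, character(1))
      if (anyNA(lib$smiles)) {
        validation_error("chemistry enumeration failed for some cells")
      }
    }
    list(library = lib, monomers = monomers,
         params = list(mu = spec$mu, effects = effects,
                       interaction = inter))
  })
}

#' Observe designed cells through the assay/attrition model
#'
#' Each designed cell is independently lost with probability
#' `attrition_rate`; survivors are measured with additive Gaussian noise.
#'
#' @param lib output of [make_library()].
#' @param cells design cells (0-based `f1`, `f2`[, `f3`]), e.g. from
#'   [generate_balanced_design()].
#' @param spec the [library_spec()] (for noise/attrition rates).
#' @param seed observation RNG seed (defaults to `spec$seed + 1`).
#' @return data.frame of measured records: `id`, monomer ids, `response`.
#' @export
observe_library <- function(lib, cells, spec, seed = NULL) {
  k <- length(spec$n_levels)
  key <- do.call(paste, c(lib$library[paste0("f", seq_len(k))], sep = "_"))
  want <- do.call(paste, c(cells, sep = "_"))
  idx <- match(want, key)
  if (anyNA(idx)) validation_error("design cells outside the library")
  with_seed(seed %||% (spec$seed + 1L), {
    kept <- stats::runif(length(idx)) >= spec$attrition_rate
    idx <- idx[kept]
    out <- lib$library[idx, , drop = FALSE]
    out$response <- out$y_true + stats::rnorm(length(idx), 0, spec$noise_sd)
    out$y_true <- NULL
    out$id <- sprintf("obs_%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out
  })
}

#' Deterministic druglike molecule corpus
#'
#' Assembles `n` valid, unique, diverse structures from a curated scaffold
#' and substituent vocabulary (amide/ether/amine-linked aromatics and
#' aliphatics), spanning molecular weights that both pass and violate the
#' oral profile. Used as fixture material for generator and filter tests.
#'
#' @param n corpus size.
#' @param seed RNG seed; the corpus is reproducible.
#' @return molecule table.
#' @export
make_molecule_corpus <- function(n = 100L, seed = 1L) {
  stopifnot(n >= 1)
  cores <- c("O=C([1*])Nc1ccc([2*])cc1",     # anilide
             "O=C([1*])N([2*])C",            # N-methyl amide
             "[1*]c1ccc([2*])cc1",           # para-arene
             "[1*]c1cccc([2*])c1",           # meta-arene
             "[1*]c1ccc(O[2*])cc1",          # aryl ether
             "O=S(=O)([1*])N([2*])C",        # sulfonamide
             "[1*]C(=O)OC([2*])",            # ester
             "[1*]c1ncc([2*])cn1",           # pyrimidine
             "[1*]N1CCN([2*])CC1",           # piperazine
             "O=C([1*])N1CCC([2*])CC1")      # acyl piperidine
  subs <- c("[*]C", "[*]CC", "[*]CCC", "[*]C(C)C", "[*]C(C)(C)C",
            "[*]C1CCCCC1", "[*]c1ccccc1", "[*]c1ccncc1", "[*]c1ccc(F)cc1",
            "[*]c1ccc(Cl)cc1", "[*]c1ccc(OC)cc1", "[*]Cc1ccccc1",
            "[*]CCO", "[*]CCN(C)C", "[*]CC(=O)O", "[*]CC(F)(F)F",
            "[*]c1ccc(-c2ccccc2)cc1", "[*]CCCCCCCCCC",
            "[*]c1ccc(CCc2ccc(CC)cc2)cc1", "[*]CCOCC")
  with_seed(seed, {
    seen <- character(0)
    smiles <- character(0)
    guard <- 0L
    while (length(smiles) < n && guard < 50L * n) {
      guard <- guard + 1L
      core <- sample(cores, 1L)
      s1 <- sample(subs, 1L)
      s2 <- sample(subs, 1L)
      smi <- .assemble_product(core, c(s1, s2))
      if (!is.na(smi) && !smi %in% seen) {
        seen <- c(seen, smi)
        smiles <- c(smiles, smi)
      }
    }
    if (length(smiles) < n) {
      validation_error("could not assemble the requested corpus size")
    }
    molecule_table(smiles, id = sprintf("corpus_%04d", seq_len(n)))$records
  })
}
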