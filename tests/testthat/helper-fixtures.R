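# Shared fixtures, built in code and cached for the session.

# small deterministic druglike corpus (generator/filter tests)
corpus_30 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_molecule_corpus(30, seed = 11)
    val
  }
})

# molecule table from raw SMILES, ids auto-assigned
mt <- function(smiles, id = NULL) molecule_table(smiles, id = id)$records

# canonical form shorthand
can <- function(s) mt(s)$smiles

# multiset of BRICS fragment SMILES of a molecule (for single-edit checks)
frag_multiset <- function(smiles) sort(brics_fragment(smiles)$fragments$smiles)

# Independent Pareto oracle: O(n^2 m) dominance matrix, then rank(i) =
# 1 + max rank over i's dominators (longest dominance chain), computed by
# fixpoint iteration — a different route than the implementation's
# front-peeling.
pareto_oracle <- function(scores) {
  n <- nrow(scores)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(scores))) {
    ge <- ge & outer(scores[, k], scores[, k], `>=`)
    gt <- gt | outer(scores[, k], scores[, k], `>`)
  }
  dom <- ge & gt  # dom[i, j]: i dominates j
  rank <- rep(NA_integer_, n)
  while (anyNA(rank)) {
    for (i in which(is.na(rank))) {
      ds <- which(dom[, i])
      if (!length(ds)) rank[i] <- 1L
      else if (!anyNA(rank[ds])) rank[i] <- 1L + max(rank[ds])
    }
  }
  rank
}

# evaluate expr under a local seed without disturbing the global stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

# symmetric difference size of two multisets
multiset_symdiff <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  keys <- union(names(ta), names(tb))
  na0 <- function(x) ifelse(is.na(x), 0L, as.integer(x))
  sum(abs(na0(ta[keys]) - na0(tb[keys])))
}
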