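# Internal utilities: error conditions and OpenBabel wrappers.

stop_molforge <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "molforge_error")))
}

#' @noRd
parse_error <- function(msg, smiles = NULL) {
  stop_molforge(msg, "molforge_parse_error", smiles = smiles)
}

#' @noRd
smarts_error <- function(msg, pattern = NULL) {
  stop_molforge(msg, "molforge_smarts_error", pattern = pattern)
}

#' @noRd
validation_error <- function(msg) {
  stop_molforge(msg, "molforge_validation_error")
}

# OpenBabel conversion, warnings silenced (OB is chatty on stderr).
ob_convert <- function(from, to, text) {
  suppressWarnings(ChemmineOB::convertFormat(from, to, text))
}

# Canonicalise a vector of SMILES one at a time; NA for failures.
ob_canonical <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ob_convert("SMI", "CAN", paste0(s, "\n")), error = function(e) "")
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic integer RNG scope: evaluate expr under a local seed without
# touching the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
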