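# Target compound profile enforcement, desirability scoring, Pareto ranking
# and annotation of survivors.

.known_properties <- c("MW", "heavy_atoms", "HBD", "HBA", "RotB", "TPSA",
                       "clogP", "aromatic_rings", "PFI_proxy")

new_score_profile <- function(criteria, mode = "sum", top_n = NULL) {
  structure(list(criteria = criteria, mode = mode, top_n = top_n),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat("Score profile: mode =", x$mode,
      if (!is.null(x$top_n)) paste0("(top ", x$top_n, ")"), "\n")
  print(x$criteria)
  invisible(x)
}

.validate_criteria <- function(criteria, known_properties) {
  need <- c("property", "min", "max", "gradient", "hard")
  if (!all(need %in% names(criteria))) {
    validation_error(paste("criteria need columns:",
                           paste(need, collapse = ", ")))
  }
  unknown <- setdiff(criteria$property, known_properties)
  if (length(unknown)) {
    validation_error(sprintf(
      "unknown propert%s: %s; known names: %s",
      if (length(unknown) > 1) "ies" else "y",
      paste(unknown, collapse = ", "),
      paste(known_properties, collapse = ", ")))
  }
  if (any(criteria$min > criteria$max)) {
    validation_error("criterion min must be <= max")
  }
  if (any(criteria$gradient < 0)) {
    validation_error("criterion gradient must be >= 0")
  }
  criteria
}

#' Build a score profile in code
#'
#' @param property,min,max,gradient,hard vectors defining one criterion per
#'   element; `min`/`max` may be `-Inf`/`Inf`, `gradient` is the
#'   desirability slope per unit outside the window (used when
#'   `hard = FALSE`), `hard` criteria are pass/fail filters.
#' @param mode ranking mode, `"sum"` or `"pareto"`.
#' @param top_n optional output cap for [top_n_compounds()].
#' @param known_properties property names accepted in this profile; extend
#'   when scoring externally supplied columns (e.g. ADMET predictions).
#' @return a `score_profile`.
#' @export
score_profile <- function(property, min = -Inf, max = Inf, gradient = 0,
                          hard = FALSE, mode = c("sum", "pareto"),
                          top_n = NULL,
                          known_properties = .known_properties) {
  mode <- match.arg(mode)
  criteria <- data.frame(
    property = property,
    min = rep_len(min, length(property)),
    max = rep_len(max, length(property)),
    gradient = rep_len(gradient, length(property)),
    hard = rep_len(hard, length(property)))
  new_score_profile(.validate_criteria(criteria, known_properties),
                    mode, top_n)
}

#' Load a score profile from XML or JSON
#'
#' XML schema:
#' `<profile mode="sum|pareto" top_n="..."><criterion property="MW" min="0"
#' max="500" gradient="0.01" hard="false"/></profile>`; the JSON mirror uses
#' identical field names
#' (`{"mode": ..., "top_n": ..., "criteria": [{...}]}`). Both dialects
#' produce identical profiles. Unknown property names are rejected along
#' with the list of known names.
#'
#' @param path profile file.
#' @param dialect `"auto"` (by extension), `"xml"` or `"json"`.
#' @param known_properties accepted property names.
#' @return a `score_profile`.
#' @export
load_profile <- function(path, dialect = c("auto", "xml", "json"),
                         known_properties = .known_properties) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml"
               else "json"
  }
  num_or <- function(x, default) {
    if (is.null(x) || is.na(x) || !nzchar(x)) default else as.numeric(x)
  }
  if (dialect == "xml") {
    doc <- xml2::read_xml(path)
    mode <- xml2::xml_attr(doc, "mode")
    if (is.na(mode)) mode <- "sum"
    top_n <- xml2::xml_attr(doc, "top_n")
    top_n <- if (is.na(top_n)) NULL else as.integer(top_n)
    nodes <- xml2::xml_find_all(doc, ".//criterion")
    if (!length(nodes)) validation_error("profile has no criteria")
    criteria <- do.call(rbind, lapply(nodes, function(nd) {
      data.frame(
        property = xml2::xml_attr(nd, "property"),
        min = num_or(xml2::xml_attr(nd, "min"), -Inf),
        max = num_or(xml2::xml_attr(nd, "max"), Inf),
        gradient = num_or(xml2::xml_attr(nd, "gradient"), 0),
        hard = tolower(xml2::xml_attr(nd, "hard") %||% "false") %in%
          c("true", "1", "yes"))
    }))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    mode <- obj$mode %||% "sum"
    top_n <- if (is.null(obj$top_n)) NULL else as.integer(obj$top_n)
    cr <- obj$criteria
    if (is.null(cr) || !nrow(as.data.frame(cr))) {
      validation_error("profile has no criteria")
    }
    cr <- as.data.frame(cr)
    criteria <- data.frame(
      property = cr$property,
      min = vapply(seq_len(nrow(cr)),
                   function(i) num_or(cr$min[i], -Inf), numeric(1)),
      max = vapply(seq_len(nrow(cr)),
                   function(i) num_or(cr$max[i], Inf), numeric(1)),
      gradient = vapply(seq_len(nrow(cr)),
                        function(i) num_or(cr$gradient[i], 0), numeric(1)),
      hard = as.logical(cr$hard %||% rep(FALSE, nrow(cr))))
  }
  if (!mode %in% c("sum", "pareto")) {
    validation_error("profile mode must be 'sum' or 'pareto'")
  }
  new_score_profile(.validate_criteria(criteria, known_properties),
                    mode, top_n)
}

#' Preconfigured target compound profiles
#'
#' Hard property windows for typical oral and inhaled programmes. The
#' shipped windows (oral: MW <= 500, clogP <= 5, HBD <= 5, HBA <= 10,
#' TPSA <= 140, RotB <= 10, PFI_proxy <= 7; inhaled: clogP <= 3,
#' PFI_proxy <= 5, others as oral) are package conventions, fully
#' overridable via a profile file.
#'
#' @param preset `"oral"` or `"inhaled"`.
#' @return a `score_profile` of hard criteria.
#' @export
default_profile <- function(preset = c("oral", "inhaled")) {
  preset <- match.arg(preset)
  p <- score_profile(
    property = c("MW", "clogP", "HBD", "HBA", "TPSA", "RotB", "PFI_proxy"),
    max = c(500, 5, 5, 10, 140, 10, 7),
    hard = TRUE)
  if (preset == "inhaled") {
    p$criteria$max[p$criteria$property == "clogP"] <- 3
    p$criteria$max[p$criteria$property == "PFI_proxy"] <- 5
  }
  p
}

# make sure required property columns exist, computing them when absent
.ensure_properties <- function(mols, props) {
  missing <- setdiff(props, names(mols))
  if (length(missing)) {
    if (all(missing %in% .known_properties)) {
      mols <- compute_properties(mols)
    }
  }
  mols
}

#' Filter molecules against a target compound profile
#'
#' A molecule fails when ANY hard criterion is violated; every failure lists
#' all violated criteria. Scored (`hard = FALSE`) criteria are ignored here.
#' `pass` and `fail` partition the input.
#'
#' @param mols molecule table.
#' @param profile a `score_profile`, or a preset name (`"oral"`,
#'   `"inhaled"`).
#' @return list(pass, fail); `fail` carries a `reason` column.
#' @export
profile_filter <- function(mols, profile = "oral") {
  if (is.character(profile)) profile <- default_profile(profile)
  stopifnot(inherits(profile, "score_profile"))
  hard <- profile$criteria[profile$criteria$hard, , drop = FALSE]
  if (!nrow(mols)) {
    warning("profile_filter: empty input")
    fail <- mols
    fail$reason <- character(0)
    return(list(pass = mols, fail = fail))
  }
  mols <- .ensure_properties(mols, hard$property)
  reasons <- rep("", nrow(mols))
  for (k in seq_len(nrow(hard))) {
    x <- mols[[hard$property[k]]]
    bad <- is.na(x) | x < hard$min[k] | x > hard$max[k]
    msg <- sprintf("%s=%s outside [%g, %g]", hard$property[k],
                   ifelse(is.na(x), "NA", format(x, digits = 4)),
                   hard$min[k], hard$max[k])
    reasons[bad] <- ifelse(nzchar(reasons[bad]),
                           paste(reasons[bad], msg[bad], sep = "; "),
                           msg[bad])
  }
  ok <- !nzchar(reasons)
  fail <- mols[!ok, , drop = FALSE]
  fail$reason <- reasons[!ok]
  list(pass = mols[ok, , drop = FALSE], fail = fail)
}

#' Filter molecules against a SMARTS liability list
#'
#' @param mols molecule table.
#' @param smarts_list data.frame(id, pattern), e.g. from
#'   [read_smarts_list()]. Empty list passes everything.
#' @return list(pass, fail); `fail` gains a `reason` column naming all
#'   matching pattern ids.
#' @export
liability_filter <- function(mols, smarts_list) {
  if (!nrow(mols) || !nrow(smarts_list)) {
    fail <- mols[integer(0), , drop = FALSE]
    fail$reason <- character(0)
    return(list(pass = mols, fail = fail))
  }
  hits <- matrix(FALSE, nrow(mols), nrow(smarts_list))
  for (k in seq_len(nrow(smarts_list))) {
    hits[, k] <- match_smarts(mols, smarts_list$pattern[k])
  }
  reason <- apply(hits, 1, function(h) {
    paste(smarts_list$id[h], collapse = "; ")
  })
  bad <- rowSums(hits) > 0
  fail <- mols[bad, , drop = FALSE]
  fail$reason <- reason[bad]
  list(pass = mols[!bad, , drop = FALSE], fail = fail)
}

#' Keep or drop molecules matching one SMARTS pattern
#'
#' `include` keeps matches, `exclude` keeps non-matches; for a fixed pattern
#' the two results partition the input.
#'
#' @param mols molecule table.
#' @param pattern SMARTS pattern.
#' @param mode `"include"` or `"exclude"`.
#' @return the surviving subset.
#' @export
smarts_task <- function(mols, pattern, mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  .check_smarts(pattern)
  if (!nrow(mols)) return(mols)
  m <- match_smarts(mols, pattern)
  keep <- if (mode == "include") m else !m
  if (!any(keep)) warning("smarts_task: no molecules survive")
  mols[keep, , drop = FALSE]
}

#' Linear desirability scores under a profile
#'
#' Each scored (`hard = FALSE`) criterion contributes 1 inside its
#' `[min, max]` window and decreases linearly at `gradient` per unit outside
#' it, clamped at 0 (an unbounded decrease would let one property veto the
#' whole sum invisibly). A missing property value scores 0 and is flagged.
#' The total is the sum over scored criteria.
#'
#' @param mols molecule table.
#' @param profile `score_profile`.
#' @return `mols` with one `score_<property>` column per scored criterion,
#'   a `score_total` column, and a logical `score_flagged` column marking
#'   rows with missing property values.
#' @export
desirability <- function(mols, profile) {
  stopifnot(inherits(profile, "score_profile"))
  soft <- profile$criteria[!profile$criteria$hard, , drop = FALSE]
  if (!nrow(soft)) validation_error("profile has no scored criteria")
  mols <- .ensure_properties(mols, soft$property)
  flagged <- rep(FALSE, nrow(mols))
  total <- rep(0, nrow(mols))
  for (k in seq_len(nrow(soft))) {
    x <- mols[[soft$property[k]]]
    if (is.null(x)) x <- rep(NA_real_, nrow(mols))
    below <- pmax(soft$min[k] - x, 0)
    above <- pmax(x - soft$max[k], 0)
    s <- pmax(1 - soft$gradient[k] * (below + above), 0)
    s[is.na(x)] <- 0
    flagged <- flagged | is.na(x)
    mols[[paste0("score_", soft$property[k])]] <- s
    total <- total + s
  }
  mols$score_total <- total
  mols$score_flagged <- flagged
  mols
}

#' Pareto rank a score matrix
#'
#' Compound A dominates B when A >= B on every criterion with strict
#' inequality on at least one. Rank 1 is the non-dominated front; fronts
#' are peeled iteratively. Compounds with equal score vectors share a rank.
#'
#' @param scores numeric matrix, n compounds x m >= 2 criteria (higher is
#'   better), all finite.
#' @return integer vector of front indices (1 = best).
#' @export
pareto_rank <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) validation_error("pareto ranking needs >= 2 criteria")
  if (any(!is.finite(scores))) validation_error("scores must be finite")
  n <- nrow(scores)
  rank <- integer(n)
  remaining <- seq_len(n)
  front <- 0L
  while (length(remaining)) {
    front <- front + 1L
    sub <- scores[remaining, , drop = FALSE]
    nondom <- vapply(seq_along(remaining), function(i) {
      ge <- sub >= matrix(sub[i, ], nrow(sub), ncol(sub), byrow = TRUE)
      gt <- sub > matrix(sub[i, ], nrow(sub), ncol(sub), byrow = TRUE)
      dominators <- rowSums(ge) == ncol(sub) & rowSums(gt) > 0
      !any(dominators)
    }, logical(1))
    rank[remaining[nondom]] <- front
    remaining <- remaining[!nondom]
  }
  rank
}

#' Select the top-N compounds from scored/ranked molecules
#'
#' Sum mode returns exactly `min(n, nrow)` rows by descending `score_total`
#' (ties broken by id for determinism). Pareto mode returns whole fronts in
#' rank order until at least `n` compounds are collected — fronts are never
#' split, so more than `n` rows may come back. Pareto output also carries
#' the within-front sum score for deterministic downstream ordering.
#'
#' @param mols molecule table with score columns (see [desirability()]).
#' @param n target count (>= 1).
#' @param mode `"sum"` or `"pareto"`.
#' @param score_cols columns to use as Pareto criteria (default: all
#'   `score_<property>` columns).
#' @return subset of `mols`, with `pareto_rank` column in Pareto mode.
#' @export
top_n_compounds <- function(mols, n, mode = c("sum", "pareto"),
                            score_cols = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (!nrow(mols)) return(mols)
  if (mode == "sum") {
    if (is.null(mols$score_total)) validation_error("missing score_total")
    ord <- order(-mols$score_total, mols$id)
    mols[ord[seq_len(min(n, nrow(mols)))], , drop = FALSE]
  } else {
    if (is.null(score_cols)) {
      score_cols <- grep("^score_", names(mols), value = TRUE)
      score_cols <- setdiff(score_cols, c("score_total", "score_flagged"))
    }
    rk <- pareto_rank(as.matrix(mols[score_cols]))
    mols$pareto_rank <- rk
    taken <- integer(0)
    for (f in sort(unique(rk))) {
      taken <- c(taken, which(rk == f))
      if (length(taken) >= n) break
    }
    sub <- mols[taken, , drop = FALSE]
    ord <- order(sub$pareto_rank,
                 -(sub$score_total %||% rep(0, nrow(sub))), sub$id)
    sub[ord, , drop = FALSE]
  }
}

#' Sphere-exclusion clustering
#'
#' Greedy single pass in input order: a molecule joins the first existing
#' cluster whose centroid is at least `threshold` similar, otherwise founds
#' a new cluster with itself as centroid. Deterministic for fixed input
#' order and threshold.
#'
#' @param mols molecule table.
#' @param threshold Tanimoto similarity threshold in (0, 1).
#' @param kind fingerprint kind.
#' @return list(cluster = integer ids per molecule, centroids = row indices
#'   of cluster centroids).
#' @export
sphere_exclusion_cluster <- function(mols, threshold = 0.65,
                                     kind = c("circular2", "path7")) {
  kind <- match.arg(kind)
  stopifnot(threshold > 0, threshold < 1)
  if (!nrow(mols)) return(list(cluster = integer(0), centroids = integer(0)))
  fps <- fingerprint(mols, kind)
  centroids <- integer(0)
  cluster <- integer(nrow(mols))
  for (i in seq_len(nrow(mols))) {
    assigned <- FALSE
    for (ci in seq_along(centroids)) {
      if (tanimoto(fps[[i]], fps[[centroids[ci]]]) >= threshold) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, i)
      cluster[i] <- length(centroids)
    }
  }
  list(cluster = cluster, centroids = centroids)
}

#' Annotate a result table for chemist review
#'
#' Surfaces provenance (`change_note`), adds sphere-exclusion cluster ids,
#' Murcko frameworks (scaffold level) and `PFI_proxy`. No molecule is
#' dropped.
#'
#' @param mols molecule table.
#' @param cluster_threshold similarity threshold for clustering.
#' @return the table with `cluster`, `framework` and `PFI_proxy` columns.
#' @export
annotate_results <- function(mols, cluster_threshold = 0.65) {
  if (!nrow(mols)) return(mols)
  if (is.null(mols$change_note)) mols$change_note <- NA_character_
  mols <- .ensure_properties(mols, "PFI_proxy")
  mols$cluster <- sphere_exclusion_cluster(mols, cluster_threshold)$cluster
  mols$framework <- murcko_framework(mols, "scaffold")
  mols
}
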