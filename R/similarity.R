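# Similarity scores. Two methods x three arrow-env definitions give six
# scores per pair of steps or mechanisms:
#   unordered = Jaccard index of the two sets of arrow-env canonical keys;
#   ordered   = mean of the env-set Jaccard and the chain-set Jaccard
#               (chains = edges of the step graphs, pooled across steps at
#               mechanism level).

#' Jaccard index of two finite sets
#'
#' Returns `|a n b| / |a u b|`, with the identity convention that two empty
#' sets score 1 (so self-similarity is 1 even for chain-free mechanisms).
#'
#' @param a,b vectors treated as sets.
#' @return fraction in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Pooled arrow-env key set of a mechanism
#'
#' Union over all catalytic steps of the step's arrow-env canonical keys.
#'
#' @param mech a [mechanism()].
#' @param definition an [arrow_env_definition()] or its name.
#' @return sorted character vector of distinct canonical keys.
#' @export
mechanism_envs <- function(mech, definition = "two_away") {
  envs <- arrow_envs(mech, definition)
  sort(unique(vapply(envs, canonical_key, character(1))))
}

#' Pooled chain set of a mechanism
#'
#' Union over steps of each step graph's chains (edges).
#'
#' @inheritParams mechanism_envs
#' @return sorted character vector of distinct chain identifiers.
#' @export
mechanism_chains <- function(mech, definition = "two_away") {
  sort(unique(unlist(lapply(mech$steps, function(s) {
    chains(build_step_graph(s, definition))
  }))))
}

env_key_set <- function(x, definition) {
  if (inherits(x, "mechanism")) return(mechanism_envs(x, definition))
  sort(unique(vapply(arrow_envs(x, definition), canonical_key, character(1))))
}

chain_set <- function(x, definition) {
  if (inherits(x, "mechanism")) return(mechanism_chains(x, definition))
  chains(build_step_graph(x, definition))
}

level_of <- function(x) if (inherits(x, "mechanism")) "mechanism" else "step"

check_same_level <- function(a, b) {
  la <- level_of(a); lb <- level_of(b)
  if (la != lb) stop("cannot compare a ", la, " with a ", lb)
  la
}

new_score <- function(value, definition, method, level, j_envs, j_chains = NA) {
  structure(list(value = value, definition = definition, method = method,
                 level = level, j_envs = j_envs, j_chains = j_chains),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<%s %s %s similarity: %.4f (%s)>\n", x$level, x$definition,
              x$method, x$value, format_percent(x$value)))
  invisible(x)
}

#' Unordered similarity of two steps or two mechanisms
#'
#' Jaccard index of the two sets of arrow-env canonical keys: 1 means all
#' arrow-envs are shared, 0 means none is.
#'
#' @param a,b two [catalytic_step()]s or two [mechanism()]s (same level).
#' @param definition an [arrow_env_definition()] or its name; both sides are
#'   compared under this single definition (definitions are never mixed).
#' @return a `similarity_score` with `value` in `[0, 1]`.
#' @export
similarity_unordered <- function(a, b, definition = "two_away") {
  level <- check_same_level(a, b)
  def <- as_definition(definition)$name
  j <- jaccard(env_key_set(a, def), env_key_set(b, def))
  new_score(j, def, "unordered", level, j_envs = j)
}

#' Ordered similarity of two steps or two mechanisms
#'
#' Simple average of the Jaccard index of the arrow-env key sets and the
#' Jaccard index of the chain sets (step-graph edges, pooled across steps at
#' mechanism level). Two empty chain sets contribute a Jaccard of 1.
#'
#' @inheritParams similarity_unordered
#' @return a `similarity_score`; `value = mean(j_envs, j_chains)`.
#' @export
similarity_ordered <- function(a, b, definition = "two_away") {
  level <- check_same_level(a, b)
  def <- as_definition(definition)$name
  je <- jaccard(env_key_set(a, def), env_key_set(b, def))
  jc <- jaccard(chain_set(a, def), chain_set(b, def))
  new_score((je + jc) / 2, def, "ordered", level, j_envs = je, j_chains = jc)
}

#' All six similarity scores for a pair of mechanisms
#'
#' One row per (definition, method) combination, named after the
#' arrow-env definition followed by the method, e.g. "two_away ordered".
#'
#' @param a,b [mechanism()]s.
#' @return data.frame with columns `definition`, `method`, `score`,
#'   `j_envs`, `j_chains` (NA for unordered rows) and `percent` (display
#'   rounding, half-up).
#' @export
score_suite <- function(a, b) {
  rows <- list()
  for (def in definition_names()) {
    su <- similarity_unordered(a, b, def)
    so <- similarity_ordered(a, b, def)
    rows[[length(rows) + 1L]] <- data.frame(
      definition = def, method = "unordered", score = su$value,
      j_envs = su$j_envs, j_chains = NA_real_,
      percent = format_percent(su$value), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      definition = def, method = "ordered", score = so$value,
      j_envs = so$j_envs, j_chains = so$j_chains,
      percent = format_percent(so$value), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Display rounding of a similarity fraction as an integer percentage
#'
#' Half-up rounding, so 0.41667 displays as "42%" and 0.125 as "13%".
#'
#' @param x fraction(s) in `[0, 1]`.
#' @return character vector like `"42%"`.
#' @export
format_percent <- function(x) {
  paste0(floor(x * 100 + 0.5), "%")
}
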