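# Arrow-environments: the unit of mechanism comparison. An arrow-env is the
# subgraph of the active-site state within a fixed number of bonds (shells)
# of a curly arrow's reaction centres, labelled with the arrow's electron
# count and tail/tip roles on the centre atoms.

#' Arrow-environment definitions
#'
#' Three named definitions are provided:
#' * `one_away` — reaction centres plus a single shell of atoms (bond
#'   distance <= 1);
#' * `two_away` — two shells (bond distance <= 2);
#' * `ezmechanism_like` — two shells, but carbon and hydrogen atoms in the
#'   outermost (second) shell are treated as equivalent, since at that
#'   distance a C or H should contribute little to the reaction chemistry.
#'
#' Custom definitions may be built with `name = "custom"`, any
#' `shell_depth >= 1` and an optional list of element classes merged at the
#' outermost shell only.
#'
#' @param name one of `"one_away"`, `"two_away"`, `"ezmechanism_like"`,
#'   `"custom"`.
#' @param shell_depth number of shells; ignored for the three named
#'   definitions (1, 2 and 2 respectively).
#' @param equiv_outer list of integer vectors of atomic numbers; atoms at
#'   exactly the outermost shell whose element falls in a class are labelled
#'   with the whole class instead of their element. `ezmechanism_like` uses
#'   `list(c(6, 1))`.
#' @return an object of class `arrow_env_definition`.
#' @export
arrow_env_definition <- function(name = c("one_away", "two_away",
                                          "ezmechanism_like", "custom"),
                                 shell_depth = NULL, equiv_outer = list()) {
  name <- match.arg(name)
  def <- switch(name,
    one_away = list(name = name, shell_depth = 1L, equiv_outer = list()),
    two_away = list(name = name, shell_depth = 2L, equiv_outer = list()),
    ezmechanism_like = list(name = name, shell_depth = 2L,
                            equiv_outer = list(c(6L, 1L))),
    custom = {
      if (is.null(shell_depth) || shell_depth < 1L) {
        stop("custom definitions need shell_depth >= 1")
      }
      list(name = name, shell_depth = as.integer(shell_depth),
           equiv_outer = lapply(equiv_outer, as.integer))
    })
  structure(def, class = "arrow_env_definition")
}

as_definition <- function(definition) {
  if (inherits(definition, "arrow_env_definition")) return(definition)
  arrow_env_definition(definition)
}

#' Names of the built-in arrow-environment definitions
#' @return character vector of the three built-in definition names.
#' @export
definition_names <- function() c("one_away", "two_away", "ezmechanism_like")

#' Atoms within a bond-distance shell of a set of centres
#'
#' @param state a [site_state()].
#' @param centres integer atom ids; must exist in `state`.
#' @param depth maximum shortest-path bond distance; `0` returns the centres.
#' @return sorted integer vector of atom ids at distance <= `depth` from any
#'   centre.
#' @export
shell_atoms <- function(state, centres, depth) {
  ids <- state$atoms$atom_id
  centres <- as.integer(centres)
  if (length(setdiff(centres, ids)) > 0L) {
    stop("unknown centre atom id(s): ",
         paste(setdiff(centres, ids), collapse = ","))
  }
  sort(as.integer(names(shell_distances(state, centres, depth))))
}

# BFS distances from the centre set, truncated at `depth`.
# Returns named integer vector: atom id (as name) -> distance.
shell_distances <- function(state, centres, depth) {
  adj <- state_adjacency(state)
  dist <- stats::setNames(rep(NA_integer_, nrow(state$atoms)),
                          as.character(state$atoms$atom_id))
  frontier <- unique(as.integer(centres))
  dist[as.character(frontier)] <- 0L
  d <- 0L
  while (d < depth && length(frontier) > 0L) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[is.na(dist[as.character(nxt)])]
    d <- d + 1L
    dist[as.character(nxt)] <- d
    frontier <- nxt
  }
  dist[!is.na(dist)]
}

#' Extract the arrow-environment of one curly arrow
#'
#' Collects all atoms within `shell_depth` bonds of the arrow's reaction
#' centres together with every state bond between included atoms (induced
#' subgraph). Centre atoms are annotated with the two-digit atom map of the
#' SMARTS convention: first digit = number of moving electrons (1 or 2),
#' second digit = touched by the tail (1), the tip (2) or both (3); bond
#' endpoints count as touched. Under definitions with outer-shell equivalence
#' classes (EzMechanism-like), atoms at exactly the outermost shell whose
#' element belongs to a class carry the class as their label.
#'
#' @param step a [catalytic_step()].
#' @param arrow one of `step$arrows` (or an arrow valid in `step`'s state).
#' @param definition an [arrow_env_definition()] or its name.
#' @return an object of class `arrow_env` with fields `atoms` (data.frame
#'   `atom_id`, `element`, `charge`, `equiv`, `map`), `bonds`, `definition`,
#'   `smarts` (canonical) and `key` (canonical key).
#' @export
extract_arrow_env <- function(step, arrow, definition = "two_away") {
  def <- as_definition(definition)
  state <- step$state
  centres <- reaction_centres(arrow)
  tl <- tail_atoms(arrow); tp <- tip_atoms(arrow)
  dist <- shell_distances(state, centres, def$shell_depth)
  keep <- as.integer(names(dist))

  at <- state$atoms[match(sort(keep), state$atoms$atom_id), , drop = FALSE]
  rownames(at) <- NULL
  at$equiv <- NA_character_
  at$map <- NA_character_

  d_at <- dist[as.character(at$atom_id)]
  for (cls in def$equiv_outer) {
    outer <- d_at == def$shell_depth & at$element %in% cls
    at$equiv[outer] <- paste(sort(cls, decreasing = TRUE), collapse = ",")
  }

  role <- integer(length(centres))
  role[centres %in% tl] <- 1L
  role[centres %in% tp] <- role[centres %in% tp] + 2L
  role[role == 3L] <- 3L  # 1+2 -> both
  at$map[match(centres, at$atom_id)] <- paste0(arrow$electrons, role)

  b <- state$bonds[state$bonds$a %in% keep & state$bonds$b %in% keep, ,
                   drop = FALSE]
  rownames(b) <- NULL

  env <- structure(list(atoms = at, bonds = b, definition = def$name,
                        shell_depth = def$shell_depth),
                   class = "arrow_env")
  canonicalize_env(env)
}

#' @export
print.arrow_env <- function(x, ...) {
  cat(sprintf("<arrow_env [%s]: %d atoms, %d bonds>\n  %s\n",
              x$definition, nrow(x$atoms), nrow(x$bonds), x$smarts))
  invisible(x)
}

#' Arrow-environments of every arrow in a step or mechanism
#'
#' @param x a [catalytic_step()] or [mechanism()].
#' @param definition an [arrow_env_definition()] or its name.
#' @return list of `arrow_env` objects, in arrow order (steps concatenated
#'   for a mechanism).
#' @export
arrow_envs <- function(x, definition = "two_away") {
  if (inherits(x, "mechanism")) {
    return(unlist(lapply(x$steps, arrow_envs, definition = definition),
                  recursive = FALSE))
  }
  lapply(x$arrows, function(a) extract_arrow_env(x, a, definition))
}

#' Canonical key of an arrow-environment
#'
#' Two environments of the same definition receive equal keys if and only if
#' there is a graph isomorphism between them preserving element (or
#' equivalence class), formal charge, the two-digit arrow map and bond
#' orders. Chirality is never considered. The key is the definition name
#' joined to the canonical SMARTS rendering, so it is stable across runs and
#' input atom orderings.
#'
#' @param env an `arrow_env`.
#' @return character scalar.
#' @export
canonical_key <- function(env) env$key
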