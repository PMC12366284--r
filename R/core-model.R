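# Domain model: active-site states, curly arrows, catalytic steps, mechanisms.
#
# A mechanism is an ordered list of catalytic steps. Each step holds one
# labelled molecular graph (the active-site state: every chemical species
# present, possibly disconnected) and at least one curly arrow describing a
# concerted electron movement from a source (lone pair / radical on an atom,
# or a bond) to a sink (an atom, an existing bond, or an incipient bond
# between two atoms). Hydrogens are explicit atoms wherever they take part in
# the chemistry; formal charges are integers.

#' Build an active-site state
#'
#' The state is a simple labelled graph over all species present in one
#' catalytic step. It may be disconnected (several molecules/residues).
#'
#' @param atoms data.frame with columns `atom_id` (integer, unique),
#'   `element` (atomic number) and `charge` (integer formal charge; default 0).
#' @param bonds data.frame with columns `a`, `b` (atom ids) and `order`
#'   (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`). May have zero
#'   rows.
#' @return an object of class `site_state`.
#' @export
site_state <- function(atoms, bonds = NULL) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms <- data.frame(atom_id = as.integer(atoms$atom_id),
                      element = as.integer(atoms$element),
                      charge  = as.integer(atoms$charge))
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a = integer(0), b = integer(0), order = character(0))
  } else {
    bonds <- as.data.frame(bonds)
    bonds <- data.frame(a = as.integer(bonds$a), b = as.integer(bonds$b),
                        order = as.character(bonds$order))
  }
  structure(list(atoms = atoms, bonds = bonds), class = "site_state")
}

#' Build a curly arrow
#'
#' @param electrons 1 (fishhook/radical) or 2 (electron pair).
#' @param source either `arrow_atom(id)` for a lone pair/radical source or
#'   `arrow_bond(a, b)` for a bond source.
#' @param sink one of `arrow_atom(id)`, `arrow_bond(a, b)` (existing bond) or
#'   `arrow_incipient(a, b)` (bond being formed).
#' @return an object of class `curly_arrow`.
#' @export
curly_arrow <- function(electrons, source, sink) {
  structure(list(electrons = as.integer(electrons),
                 source = source, sink = sink),
            class = "curly_arrow")
}

#' Arrow endpoint constructors
#'
#' `arrow_atom()` marks a single atom (lone pair source, or an atom sink such
#' as a proton being abstracted). `arrow_bond()` references an existing bond.
#' `arrow_incipient()` names the ordered atom pair of a bond being formed.
#'
#' @param id,a,b atom ids in the step's state.
#' @return an endpoint list with fields `type` and `atoms`.
#' @export
arrow_atom <- function(id) list(type = "atom", atoms = as.integer(id))

#' @rdname arrow_atom
#' @export
arrow_bond <- function(a, b) list(type = "bond", atoms = as.integer(c(a, b)))

#' @rdname arrow_atom
#' @export
arrow_incipient <- function(a, b) {
  list(type = "incipient", atoms = as.integer(c(a, b)))
}

#' Build a catalytic step
#'
#' @param step_index 1-based position of the step in its mechanism.
#' @param state a [site_state()].
#' @param arrows list of [curly_arrow()]; at least one.
#' @return an object of class `catalytic_step`.
#' @export
catalytic_step <- function(step_index, state, arrows) {
  structure(list(step_index = as.integer(step_index),
                 state = state, arrows = arrows),
            class = "catalytic_step")
}

#' Build a mechanism
#'
#' @param mechanism_id character identifier, unique within a corpus.
#' @param steps list of [catalytic_step()] with consecutive indices 1..n.
#' @param annotations optional named list; recognised entries are `ec`
#'   (character vector of EC numbers) and `cath` (character vector of CATH
#'   superfamily ids of the catalytic domains).
#' @return an object of class `mechanism`.
#' @export
mechanism <- function(mechanism_id, steps, annotations = NULL) {
  structure(list(mechanism_id = as.character(mechanism_id),
                 steps = steps, annotations = annotations),
            class = "mechanism")
}

#' @export
print.mechanism <- function(x, ...) {
  n_arrows <- sum(vapply(x$steps, function(s) length(s$arrows), integer(1)))
  cat(sprintf("<mechanism '%s': %d step(s), %d arrow(s)>\n",
              x$mechanism_id, length(x$steps), n_arrows))
  invisible(x)
}

#' @export
print.catalytic_step <- function(x, ...) {
  cat(sprintf("<catalytic step %d: %d atoms, %d bonds, %d arrow(s)>\n",
              x$step_index, nrow(x$state$atoms), nrow(x$state$bonds),
              length(x$arrows)))
  invisible(x)
}

# ---- endpoint helpers -------------------------------------------------------

endpoint_is_bond <- function(ep) ep$type == "bond"

# atoms touched by one endpoint; a bond endpoint touches both of its atoms
endpoint_atoms <- function(ep) ep$atoms

# atoms touched by the tail (source) of an arrow
tail_atoms <- function(arrow) endpoint_atoms(arrow$source)

# atoms touched by the tip (sink) of an arrow; an incipient pair touches both
tip_atoms <- function(arrow) endpoint_atoms(arrow$sink)

endpoints_equal <- function(a, b) {
  a$type == b$type && identical(sort(a$atoms), sort(b$atoms))
}

#' Reaction centres of a curly arrow
#'
#' The reaction centres are the atoms touched directly by the arrow's tail or
#' tip. When an endpoint is a bond (existing or incipient), both atoms of the
#' bond count. An atom touched by both tail and tip appears once.
#'
#' @param arrow a [curly_arrow()].
#' @return integer vector of atom ids, sorted, deduplicated (length 1--4).
#' @export
reaction_centres <- function(arrow) {
  sort(unique(c(tail_atoms(arrow), tip_atoms(arrow))))
}

# ---- validation -------------------------------------------------------------

validate_endpoint <- function(ep, state, where, what) {
  bad <- character(0)
  ids <- state$atoms$atom_id
  missing <- setdiff(ep$atoms, ids)
  if (length(missing) > 0L) {
    bad <- c(bad, sprintf("%s: %s references unknown atom id(s) %s",
                          where, what, paste(missing, collapse = ",")))
    return(bad)
  }
  if (ep$type == "bond") {
    key <- paste(sort(ep$atoms), collapse = "-")
    have <- paste(pmin(state$bonds$a, state$bonds$b),
                  pmax(state$bonds$a, state$bonds$b), sep = "-")
    if (!(key %in% have)) {
      bad <- c(bad, sprintf("%s: %s references bond (%s) absent from state",
                            where, what, paste(ep$atoms, collapse = ",")))
    }
  }
  if (ep$type %in% c("bond", "incipient") && length(ep$atoms) != 2L) {
    bad <- c(bad, sprintf("%s: %s endpoint must name two atoms", where, what))
  }
  if (ep$type == "incipient" && length(unique(ep$atoms)) == 1L) {
    bad <- c(bad, sprintf("%s: incipient bond (%s) is a self-pair",
                          where, paste(ep$atoms, collapse = ",")))
  }
  bad
}

validate_step <- function(step, where) {
  v <- character(0)
  st <- step$state
  if (anyDuplicated(st$atoms$atom_id)) {
    v <- c(v, sprintf("%s: duplicate atom_id(s) %s", where,
                      paste(unique(st$atoms$atom_id[
                        duplicated(st$atoms$atom_id)]), collapse = ",")))
  }
  if (any(st$atoms$element < 1L | st$atoms$element > 118L)) {
    v <- c(v, sprintf("%s: element out of range 1-118", where))
  }
  if (nrow(st$bonds) > 0L) {
    ids <- st$atoms$atom_id
    miss <- setdiff(c(st$bonds$a, st$bonds$b), ids)
    if (length(miss) > 0L) {
      v <- c(v, sprintf("%s: bond references unknown atom id(s) %s", where,
                        paste(miss, collapse = ",")))
    }
    selfb <- st$bonds$a == st$bonds$b
    if (any(selfb)) {
      v <- c(v, sprintf("%s: self-bond on atom(s) %s", where,
                        paste(st$bonds$a[selfb], collapse = ",")))
    }
    key <- paste(pmin(st$bonds$a, st$bonds$b),
                 pmax(st$bonds$a, st$bonds$b), sep = "-")
    if (anyDuplicated(key)) {
      v <- c(v, sprintf("%s: duplicate bond(s) %s", where,
                        paste(unique(key[duplicated(key)]), collapse = " ")))
    }
    badord <- !(st$bonds$order %in% BOND_ORDERS)
    if (any(badord)) {
      v <- c(v, sprintf("%s: unknown bond order '%s'", where,
                        paste(unique(st$bonds$order[badord]), collapse = ",")))
    }
  }
  if (length(step$arrows) == 0L) {
    v <- c(v, sprintf("%s: step has no arrows (at least one required)", where))
  }
  for (i in seq_along(step$arrows)) {
    ar <- step$arrows[[i]]
    aw <- sprintf("%s arrow %d", where, i)
    if (!(ar$electrons %in% c(1L, 2L))) {
      v <- c(v, sprintf("%s: electrons must be 1 or 2", aw))
    }
    if (!(ar$source$type %in% c("atom", "bond"))) {
      v <- c(v, sprintf("%s: source must be an atom or a bond", aw))
    }
    if (!(ar$sink$type %in% c("atom", "bond", "incipient"))) {
      v <- c(v, sprintf("%s: sink must be an atom, bond or incipient pair", aw))
    }
    v <- c(v, validate_endpoint(ar$source, st, aw, "source"))
    v <- c(v, validate_endpoint(ar$sink, st, aw, "sink"))
    if (endpoints_equal(ar$source, ar$sink)) {
      v <- c(v, sprintf("%s: source and sink are identical", aw))
    }
  }
  v
}

#' Validate a mechanism
#'
#' Checks every structural invariant of the data model: unique atom ids,
#' elements in range, bonds simple and resolvable, arrows referencing only
#' atoms/bonds of their own step, 1 or 2 electrons per arrow, distinct source
#' and sink, at least one arrow per step and consecutive step indices.
#' Violations are collected and returned, never raised.
#'
#' @param mech a [mechanism()].
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_mechanism <- function(mech) {
  v <- character(0)
  if (!is.character(mech$mechanism_id) || nchar(mech$mechanism_id) == 0L) {
    v <- c(v, "mechanism: mechanism_id must be a non-empty string")
  }
  if (length(mech$steps) == 0L) {
    v <- c(v, "mechanism: no steps (at least one required)")
  }
  idx <- vapply(mech$steps, function(s) s$step_index, integer(1))
  if (length(idx) > 0L && !identical(idx, seq_along(idx))) {
    v <- c(v, sprintf("mechanism: step_index values (%s) are not 1..n",
                      paste(idx, collapse = ",")))
  }
  for (s in mech$steps) {
    v <- c(v, validate_step(s, sprintf("step %d", s$step_index)))
  }
  v
}

#' @keywords internal
stop_if_invalid <- function(mech) {
  v <- validate_mechanism(mech)
  if (length(v) > 0L) {
    stop("invalid mechanism:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(mech)
}

# adjacency list of a state: named list atom_id -> integer neighbour ids
state_adjacency <- function(state) {
  ids <- state$atoms$atom_id
  adj <- vector("list", length(ids))
  names(adj) <- as.character(ids)
  for (k in seq_along(adj)) adj[[k]] <- integer(0)
  if (nrow(state$bonds) > 0L) {
    for (i in seq_len(nrow(state$bonds))) {
      a <- as.character(state$bonds$a[i]); b <- as.character(state$bonds$b[i])
      adj[[a]] <- c(adj[[a]], state$bonds$b[i])
      adj[[b]] <- c(adj[[b]], state$bonds$a[i])
    }
  }
  adj
}
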