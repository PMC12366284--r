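# Canonical mechanism JSON exchange format, version 1.0.
#
# {
#   "format_version": "1.0",
#   "mechanism": {
#     "mechanism_id": "...",
#     "annotations": {"ec": [...], "cath": [...]},      (optional)
#     "steps": [
#       {"step_index": 1,
#        "atoms": [{"atom_id": 1, "element": 8, "charge": -1}, ...],
#        "bonds": [{"atoms": [1, 2], "order": "single"}, ...],
#        "arrows": [{"electrons": 2,
#                    "source": {"type": "atom", "atoms": [1]},
#                    "sink": {"type": "incipient", "atoms": [1, 9]}}, ...]}
#     ]}}
#
# Elements are atomic numbers; hydrogens are explicit atoms wherever they
# take part in the chemistry (no implicit-H expansion is performed). Writing
# is deterministic (atoms sorted by atom_id, bonds by their atom pair, fixed
# key order), so the same mechanism always yields identical bytes.

FORMAT_VERSION <- "1.0"

endpoint_to_list <- function(ep) {
  list(type = ep$type, atoms = as.list(as.integer(ep$atoms)))
}

step_to_list <- function(step) {
  st <- step$state
  at <- st$atoms[order(st$atoms$atom_id), , drop = FALSE]
  atoms <- lapply(seq_len(nrow(at)), function(i) {
    list(atom_id = at$atom_id[i], element = at$element[i],
         charge = at$charge[i])
  })
  b <- st$bonds
  bonds <- list()
  if (nrow(b) > 0L) {
    lo <- pmin(b$a, b$b); hi <- pmax(b$a, b$b)
    o <- order(lo, hi)
    bonds <- lapply(o, function(i) {
      list(atoms = as.list(c(lo[i], hi[i])), order = b$order[i])
    })
  }
  arrows <- lapply(step$arrows, function(ar) {
    list(electrons = ar$electrons,
         source = endpoint_to_list(ar$source),
         sink = endpoint_to_list(ar$sink))
  })
  list(step_index = step$step_index, atoms = atoms, bonds = bonds,
       arrows = arrows)
}

#' Write a mechanism as canonical JSON
#'
#' Deterministic rendering: atoms sorted by id, bonds by atom pair, fixed
#' key order, two-space indentation. The same mechanism always produces
#' byte-identical output; annotations are preserved verbatim.
#'
#' @param mech a valid [mechanism()].
#' @param path optional file path; when given the document is also written
#'   there (with a trailing newline).
#' @return the JSON document as a character scalar, invisibly when `path`
#'   is given.
#' @export
write_mechanism_json <- function(mech, path = NULL) {
  stop_if_invalid(mech)
  doc <- list(format_version = FORMAT_VERSION,
              mechanism = c(
                list(mechanism_id = mech$mechanism_id),
                if (!is.null(mech$annotations)) {
                  list(annotations = mech$annotations)
                },
                list(steps = lapply(mech$steps, step_to_list))))
  json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                                        digits = NA))
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

parse_endpoint <- function(x) {
  list(type = as.character(x$type),
       atoms = as.integer(unlist(x$atoms)))
}

#' Parse a mechanism from canonical JSON
#'
#' @param text a JSON document (character scalar).
#' @return a validated [mechanism()]. Malformed JSON raises the parser's
#'   error (with position information); a structurally valid document that
#'   violates model invariants raises a validation error listing every
#'   violation.
#' @export
parse_mechanism_json <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(doc$mechanism)) stop("not a mechanism document: no 'mechanism' key")
  m <- doc$mechanism
  steps <- lapply(m$steps, function(s) {
    atoms <- data.frame(
      atom_id = vapply(s$atoms, function(a) as.integer(a$atom_id), integer(1)),
      element = vapply(s$atoms, function(a) as.integer(a$element), integer(1)),
      charge = vapply(s$atoms, function(a) {
        as.integer(if (is.null(a$charge)) 0L else a$charge)
      }, integer(1)))
    bonds <- if (length(s$bonds) > 0L) {
      data.frame(
        a = vapply(s$bonds, function(b) as.integer(b$atoms[[1]]), integer(1)),
        b = vapply(s$bonds, function(b) as.integer(b$atoms[[2]]), integer(1)),
        order = vapply(s$bonds, function(b) as.character(b$order),
                       character(1)))
    } else NULL
    arrows <- lapply(s$arrows, function(ar) {
      curly_arrow(ar$electrons, parse_endpoint(ar$source),
                  parse_endpoint(ar$sink))
    })
    catalytic_step(s$step_index, site_state(atoms, bonds), arrows)
  })
  ann <- if (!is.null(m$annotations)) {
    lapply(m$annotations, function(x) unlist(x, use.names = FALSE))
  }
  mech <- mechanism(m$mechanism_id, steps, annotations = ann)
  stop_if_invalid(mech)
  mech
}

#' Read a mechanism from a JSON file
#'
#' @param path path to a mechanism JSON document.
#' @return a validated [mechanism()].
#' @export
read_mechanism_json <- function(path) {
  parse_mechanism_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
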