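# Step graphs: within one catalytic step, arrow-envs are nodes and an arrow
# "follows" another when its tail touches an atom touched by the previous
# arrow's tip. The edges are the "chains" of length two used by the ordered
# similarity. Chains are structural, not temporal: all transformations in a
# step are concerted by convention.

#' Does one arrow follow another?
#'
#' `next_arrow` follows `prev` when the atoms touched by `next_arrow`'s tail
#' intersect the atoms touched by `prev`'s tip. Bond endpoints (existing or
#' incipient) count as touched atoms.
#'
#' @param prev,next_arrow [curly_arrow()]s of the same step.
#' @return logical scalar.
#' @export
follows <- function(prev, next_arrow) {
  length(intersect(tail_atoms(next_arrow), tip_atoms(prev))) > 0L
}

#' Build the directed arrow-env graph of a catalytic step
#'
#' Nodes are the canonical keys of the step's arrow-envs (distinct arrow
#' instances with identical keys merge into one node; the multiplicity is
#' kept as a diagnostic). There is an edge from the env of arrow A to the env
#' of arrow B whenever B follows A, over distinct arrow instances; two
#' instances sharing a key may therefore produce a loop edge, which is kept.
#'
#' @param step a [catalytic_step()].
#' @param definition an [arrow_env_definition()] or its name.
#' @return an object of class `step_graph` with fields `nodes` (character
#'   keys), `multiplicity` (named integer), `edges` (data.frame `from`, `to`),
#'   `step_index`.
#' @export
build_step_graph <- function(step, definition = "two_away") {
  envs <- arrow_envs(step, definition)
  keys <- vapply(envs, canonical_key, character(1))
  n <- length(keys)
  from <- character(0); to <- character(0)
  if (n > 1L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && follows(step$arrows[[i]], step$arrows[[j]])) {
          from <- c(from, keys[i]); to <- c(to, keys[j])
        }
      }
    }
  }
  edges <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(keys)),
                 multiplicity = table(keys),
                 edges = edges,
                 step_index = step$step_index,
                 definition = as_definition(definition)$name),
            class = "step_graph")
}

#' @export
print.step_graph <- function(x, ...) {
  cat(sprintf("<step_graph [%s] step %d: %d node(s), %d edge(s)>\n",
              x$definition, x$step_index, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Chains of a step graph
#'
#' A chain is an ordered pair of arrow-env keys joined by a "follows" edge
#' (chains of length two; the edges of the graph). Duplicates collapse to a
#' set.
#'
#' @param graph a `step_graph`.
#' @return character vector of `"from -> to"` chain identifiers (sorted).
#' @export
chains <- function(graph) {
  if (nrow(graph$edges) == 0L) return(character(0))
  sort(paste(graph$edges$from, "->", graph$edges$to))
}

#' Export a step graph to DOT or GraphML for inspection
#'
#' @param graph a `step_graph`.
#' @param path output file path; format chosen from the extension
#'   (`.dot`/`.gv` or `.graphml`).
#' @return `path`, invisibly.
#' @export
export_step_graph <- function(graph, path) {
  short <- function(k) sub("^[^|]*\\|", "", k)
  if (grepl("\\.(dot|gv)$", path)) {
    lines <- c("digraph step {",
               sprintf("  \"%s\";", short(graph$nodes)),
               if (nrow(graph$edges) > 0L) {
                 sprintf("  \"%s\" -> \"%s\";",
                         short(graph$edges$from), short(graph$edges$to))
               },
               "}")
    writeLines(lines, path)
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, length(graph$nodes),
                              name = short(graph$nodes))
    if (nrow(graph$edges) > 0L) {
      g <- igraph::add_edges(
        g, rbind(match(graph$edges$from, graph$nodes),
                 match(graph$edges$to, graph$nodes)))
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
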