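# Export of pairwise similarity tables as threshold graphs (GraphML + TSV
# edge list): one node per mechanism, an edge for every pair scoring at or
# above the cutoff, isolated nodes retained.

check_pair_table <- function(scores) {
  need <- c("mech_a", "mech_b", "score")
  if (!all(need %in% names(scores))) {
    stop("pair-score table needs columns mech_a, mech_b, score")
  }
  if (any(scores$mech_a == scores$mech_b)) {
    stop("pair-score table contains self-pairs")
  }
  if (any(scores$score < 0 | scores$score > 1)) {
    stop("scores must lie in [0, 1]")
  }
  key <- paste(pmin(scores$mech_a, scores$mech_b),
               pmax(scores$mech_a, scores$mech_b), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    rows <- scores[key %in% dup, , drop = FALSE]
    agg <- tapply(rows$score, key[key %in% dup],
                  function(s) length(unique(s)))
    if (any(agg > 1L)) {
      stop("asymmetric pair-score table: duplicated pair(s) with ",
           "conflicting scores")
    }
    scores <- scores[!duplicated(key), , drop = FALSE]
  }
  scores
}

#' Export a similarity threshold graph
#'
#' Builds the graph whose nodes are all mechanisms in the table (plus any
#' extra ids in `annotations`) and whose edges are the pairs with
#' `score >= cutoff`; isolated nodes are retained. Writes GraphML and/or a
#' TSV edge list (columns `mech_a`, `mech_b`, `score`, `definition`,
#' `method`).
#'
#' @param scores data.frame with columns `mech_a`, `mech_b`, `score` (and
#'   optionally `definition`, `method`), one row per unordered pair;
#'   duplicated pairs with conflicting scores are rejected as asymmetric.
#' @param cutoff similarity threshold in `[0, 1]`.
#' @param graphml_path,tsv_path optional output paths.
#' @param annotations optional data.frame with columns `mechanism_id`, `ec`,
#'   `cath` attached as node attributes (empty string when absent).
#' @return the igraph object, invisibly.
#' @export
export_similarity_graph <- function(scores, cutoff, graphml_path = NULL,
                                    tsv_path = NULL, annotations = NULL) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  scores <- check_pair_table(scores)
  nodes <- sort(unique(c(scores$mech_a, scores$mech_b,
                         if (!is.null(annotations)) {
                           as.character(annotations$mechanism_id)
                         })))
  keep <- scores[scores$score >= cutoff, , drop = FALSE]
  keep <- keep[order(keep$mech_a, keep$mech_b), , drop = FALSE]

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ec <- cath <- rep("", length(nodes))
  if (!is.null(annotations)) {
    i <- match(nodes, as.character(annotations$mechanism_id))
    if (!is.null(annotations$ec)) {
      ec <- ifelse(is.na(i), "", as.character(annotations$ec[i]))
      ec[is.na(ec)] <- ""
    }
    if (!is.null(annotations$cath)) {
      cath <- ifelse(is.na(i), "", as.character(annotations$cath[i]))
      cath[is.na(cath)] <- ""
    }
  }
  g <- igraph::add_vertices(g, length(nodes), name = nodes, ec = ec,
                            cath = cath)
  if (nrow(keep) > 0L) {
    g <- igraph::add_edges(g, rbind(match(keep$mech_a, nodes),
                                    match(keep$mech_b, nodes)),
                           score = keep$score)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(tsv_path)) {
    out <- data.frame(
      mech_a = keep$mech_a, mech_b = keep$mech_b, score = keep$score,
      definition = if (!is.null(keep$definition)) keep$definition else "",
      method = if (!is.null(keep$method)) keep$method else "")
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(g)
}
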