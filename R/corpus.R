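# Corpus-level driver: all-vs-all comparison, arrow-env usage statistics,
# threshold clustering and the CATH/EC agreement breakdown used to study
# convergent and divergent evolution of catalytic chemistry.

#' All-vs-all pairwise mechanism similarity
#'
#' @param mechs list of [mechanism()]s with unique ids.
#' @param definition an [arrow_env_definition()] or its name.
#' @param method `"unordered"` or `"ordered"`.
#' @return data.frame with `n(n-1)/2` rows, columns `mech_a`, `mech_b`,
#'   `definition`, `method`, `score`, `j_envs`, `j_chains`, ordered by
#'   `(mech_a, mech_b)` with `mech_a < mech_b`.
#' @export
all_vs_all <- function(mechs, definition = "two_away",
                       method = c("unordered", "ordered")) {
  method <- match.arg(method)
  def <- as_definition(definition)$name
  if (length(mechs) < 2L) stop("need at least two mechanisms")
  ids <- vapply(mechs, function(m) m$mechanism_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate mechanism id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  }
  o <- order(ids)
  mechs <- mechs[o]; ids <- ids[o]

  # precompute pooled sets once per mechanism (all-vs-all is quadratic only
  # in the set comparisons, not in env extraction)
  env_sets <- lapply(mechs, mechanism_envs, definition = def)
  chain_sets <- if (method == "ordered") {
    lapply(mechs, mechanism_chains, definition = def)
  }

  n <- length(mechs)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      je <- jaccard(env_sets[[i]], env_sets[[j]])
      jc <- if (method == "ordered") {
        jaccard(chain_sets[[i]], chain_sets[[j]])
      } else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(
        mech_a = ids[i], mech_b = ids[j], definition = def, method = method,
        score = if (method == "ordered") (je + jc) / 2 else je,
        j_envs = je, j_chains = jc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arrow-environment usage statistics of a corpus
#'
#' Counts, per definition, the distinct arrow-env canonical keys and how
#' many curly arrows, catalytic steps and mechanisms each covers; aggregates
#' into chemical-diversity summaries (singleton envs seen in exactly one
#' mechanism; "common" envs seen in more than `common_threshold` steps).
#'
#' @param mechs list of [mechanism()]s.
#' @param definition an [arrow_env_definition()] or its name.
#' @param common_threshold an env is "common" when observed in more than
#'   this many catalytic steps (default 20).
#' @return an object of class `corpus_stats`: counts plus a ranked
#'   `catalogue` data.frame (`key`, `smarts`, `n_arrows`, `n_steps`,
#'   `n_mechanisms`), most-used first.
#' @export
env_usage_stats <- function(mechs, definition = "two_away",
                            common_threshold = 20L) {
  def <- as_definition(definition)$name
  rec <- list()
  n_steps <- 0L; n_arrows <- 0L
  for (m in mechs) {
    for (s in m$steps) {
      n_steps <- n_steps + 1L
      for (env in arrow_envs(s, def)) {
        n_arrows <- n_arrows + 1L
        rec[[length(rec) + 1L]] <- data.frame(
          key = canonical_key(env), smarts = to_smarts(env),
          mech = m$mechanism_id,
          step = paste(m$mechanism_id, s$step_index),
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- do.call(rbind, rec)
  catalogue <- do.call(rbind, lapply(split(rec, rec$key), function(d) {
    data.frame(key = d$key[1], smarts = d$smarts[1], n_arrows = nrow(d),
               n_steps = length(unique(d$step)),
               n_mechanisms = length(unique(d$mech)),
               stringsAsFactors = FALSE)
  }))
  catalogue <- catalogue[order(-catalogue$n_steps, catalogue$key), ,
                         drop = FALSE]
  rownames(catalogue) <- NULL

  structure(list(
    definition = def,
    n_mechanisms = length(mechs),
    n_steps = n_steps,
    n_arrows = n_arrows,
    n_distinct_envs = nrow(catalogue),
    mean_arrows_per_env = n_arrows / nrow(catalogue),
    n_singleton_envs = sum(catalogue$n_mechanisms == 1L),
    common_threshold = as.integer(common_threshold),
    n_common_envs = sum(catalogue$n_steps > common_threshold),
    catalogue = catalogue), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<corpus_stats [%s]: %d mechanisms, %d steps, %d arrows>\n",
    "  distinct envs: %d (%.2f arrows/env); singletons: %d; ",
    "common (> %d steps): %d\n"),
    x$definition, x$n_mechanisms, x$n_steps, x$n_arrows, x$n_distinct_envs,
    x$mean_arrows_per_env, x$n_singleton_envs, x$common_threshold,
    x$n_common_envs))
  invisible(x)
}

#' Write the ranked arrow-env catalogue as TSV
#'
#' @param stats a `corpus_stats` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_env_catalogue <- function(stats, path) {
  utils::write.table(stats$catalogue, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

ec_subsubclass <- function(ec) {
  parts <- strsplit(as.character(ec), ".", fixed = TRUE)[[1]]
  if (length(parts) < 3L) return(NA_character_)
  three <- parts[1:3]
  if (any(three %in% c("-", "", "x", "X")) ||
      anyNA(suppressWarnings(as.integer(three)))) {
    return(NA_character_)
  }
  paste(three, collapse = ".")
}

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(trimws(strsplit(as.character(x), "[;,]")[[1]])))
}

#' CATH/EC agreement breakdown of similar mechanism pairs
#'
#' For each similarity cutoff, classifies every pair with `score >= cutoff`
#' by structural agreement (CATH superfamily sets equal; disjoint; partial
#' overlap, kept as its own category) and reaction agreement (EC subsubclass,
#' i.e. first three EC numbers, equal or not). Pairs with a missing or
#' incomplete annotation on either side are excluded and counted.
#'
#' @param scores pair-score table as from [all_vs_all()].
#' @param annotations data.frame with columns `mechanism_id`, `ec` (one EC
#'   number; fewer than three levels or wildcards count as missing) and
#'   `cath` (`;`- or `,`-separated CATH superfamily ids of the catalytic
#'   domains).
#' @param cutoffs numeric vector of fractions in `[0, 1]`.
#' @return data.frame with one row per cutoff: the four
#'   same/different-CATH x same/different-EC cells, `cath_partial`,
#'   `unannotated` and `n_pairs` (all pairs at or above the cutoff). The
#'   four cells plus `cath_partial` sum to `n_pairs - unannotated`.
#' @export
ec_cath_breakdown <- function(scores, annotations, cutoffs = c(0.5)) {
  scores <- check_pair_table(scores)
  ann_id <- as.character(annotations$mechanism_id)
  ecs <- vapply(as.character(annotations$ec), ec_subsubclass, character(1))
  caths <- lapply(as.character(annotations$cath), split_set)

  lookup <- function(id) {
    i <- match(id, ann_id)
    if (is.na(i)) return(NULL)
    ec <- ecs[i]; ca <- caths[[i]]
    if (is.na(ec) || length(ca) == 0L) return(NULL)
    list(ec = ec, cath = ca)
  }
  out <- lapply(cutoffs, function(ct) {
    keep <- scores[scores$score >= ct, , drop = FALSE]
    cells <- c(same_cath_same_ec = 0L, same_cath_diff_ec = 0L,
               diff_cath_same_ec = 0L, diff_cath_diff_ec = 0L,
               cath_partial = 0L, unannotated = 0L)
    if (nrow(keep) > 0L) {
      for (r in seq_len(nrow(keep))) {
        a <- lookup(keep$mech_a[r]); b <- lookup(keep$mech_b[r])
        if (is.null(a) || is.null(b)) {
          cells["unannotated"] <- cells["unannotated"] + 1L
          next
        }
        ec_same <- a$ec == b$ec
        if (setequal(a$cath, b$cath)) {
          cell <- if (ec_same) "same_cath_same_ec" else "same_cath_diff_ec"
        } else if (length(intersect(a$cath, b$cath)) == 0L) {
          cell <- if (ec_same) "diff_cath_same_ec" else "diff_cath_diff_ec"
        } else {
          cell <- "cath_partial"
        }
        cells[cell] <- cells[cell] + 1L
      }
    }
    data.frame(cutoff = ct, t(cells), n_pairs = nrow(keep))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$unannotated > 0L)) {
    warning(sum(res$unannotated), " pair classification(s) skipped for ",
            "missing/incomplete EC or CATH annotation")
  }
  res
}

#' Cluster mechanisms by similarity threshold
#'
#' Connected components of the graph whose edges are pairs with
#' `score >= cutoff`.
#'
#' @param scores pair-score table as from [all_vs_all()].
#' @param cutoff similarity threshold in `[0, 1]`.
#' @param graphml_path optional path; when given the threshold graph is also
#'   written as GraphML via [export_similarity_graph()].
#' @param annotations optional node annotations (see
#'   [export_similarity_graph()]).
#' @return list with `components` (list of character vectors, each a
#'   component with >= 2 members, largest first) and `isolated` (character
#'   vector of mechanisms without any edge).
#' @export
cluster_graph <- function(scores, cutoff, graphml_path = NULL,
                          annotations = NULL) {
  g <- export_similarity_graph(scores, cutoff, graphml_path = graphml_path,
                               annotations = annotations)
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  sizes <- vapply(groups, length, integer(1))
  components <- lapply(groups[sizes >= 2L], sort)
  components <- components[order(-vapply(components, length, integer(1)),
                                 vapply(components, `[`, character(1), 1))]
  names(components) <- NULL
  list(components = components,
       isolated = sort(unlist(groups[sizes == 1L], use.names = FALSE)))
}
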