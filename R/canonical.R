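# Canonicalization of arrow-environments and their SMARTS serialization.
#
# The equality test the similarity method needs is label-preserving graph
# isomorphism (element or equivalence class, formal charge, two-digit arrow
# map, bond order; no chirality). Environments are small (a few shells around
# at most four reaction centres), so a classic canonical-labelling scheme is
# used: iterative neighbourhood-colour refinement followed by exhaustive
# individualization over the first non-singleton colour cell, keeping the
# lexicographically minimal serialization. The canonical SMARTS string is
# rendered from the winning atom order, and the canonical key is the
# definition name joined to that string, so key equality, SMARTS equality and
# isomorphism coincide within one definition.

bond_rank <- function(order) match(order, BOND_ORDERS)

# --- atom tokens -------------------------------------------------------------

# charge suffix inside brackets; zero charge is never written
charge_token <- function(charge) {
  if (charge == 0L) return("")
  sign <- if (charge > 0L) "+" else "-"
  mag <- abs(charge)
  paste0("&", sign, if (mag > 1L) mag else "")
}

# bracket token of one env atom, e.g. "[#8&-:23]" or "[#6,#1]"
atom_token <- function(element, charge, equiv, map) {
  elems <- if (!is.na(equiv)) {
    paste0("#", strsplit(equiv, ",", fixed = TRUE)[[1]], collapse = ",")
  } else {
    paste0("#", element)
  }
  paste0("[", elems, charge_token(charge),
         if (!is.na(map)) paste0(":", map) else "", "]")
}

env_tokens <- function(env) {
  at <- env$atoms
  vapply(seq_len(nrow(at)), function(i) {
    atom_token(at$element[i], at$charge[i], at$equiv[i], at$map[i])
  }, character(1))
}

# --- initial colour order ----------------------------------------------------

# Sort precedence of atoms, which fixes both the canonical order across label
# classes and the rendering order of SMARTS neighbours: unmapped before
# mapped; heteroatoms by descending atomic number, then hydrogen, then
# carbon, then equivalence-class atoms; then charge; then map digits.
atom_sort_keys <- function(env) {
  at <- env$atoms
  elemkey <- integer(nrow(at))
  for (i in seq_len(nrow(at))) {
    elemkey[i] <- if (!is.na(at$equiv[i])) 750L
      else if (at$element[i] == 1L) 600L
      else if (at$element[i] == 6L) 700L
      else 500L - at$element[i]
  }
  sprintf("%d|%03d|%s|%03d|%s",
          as.integer(!is.na(at$map)), elemkey,
          ifelse(is.na(at$equiv), "", at$equiv),
          at$charge + 100L,
          ifelse(is.na(at$map), "", at$map))
}

# --- refinement + individualization -----------------------------------------

# bond matrix in local (row) indices; 0 = no bond, otherwise bond_rank
env_bond_matrix <- function(env) {
  n <- nrow(env$atoms)
  M <- matrix(0L, n, n)
  if (nrow(env$bonds) > 0L) {
    ia <- match(env$bonds$a, env$atoms$atom_id)
    ib <- match(env$bonds$b, env$atoms$atom_id)
    r <- bond_rank(env$bonds$order)
    M[cbind(ia, ib)] <- r
    M[cbind(ib, ia)] <- r
  }
  M
}

refine_colours <- function(cols, M) {
  n <- length(cols)
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      js <- which(M[i, ] > 0L)
      nb <- if (length(js) > 0L) {
        paste(sort(sprintf("%d:%04d", M[i, js], cols[js])), collapse = ",")
      } else ""
      sprintf("%04d|%s", cols[i], nb)
    }, character(1))
    new <- match(sig, sort(unique(sig)))
    if (max(new) == max(cols)) return(new)
    cols <- new
  }
}

# serialization of a complete atom order: label tokens + lower-triangular
# adjacency; the lexicographic minimum over admissible orders is canonical
order_serial <- function(ord, tokens, M) {
  n <- length(ord)
  parts <- character(n)
  for (i in seq_len(n)) {
    row <- if (i > 1L) paste(M[ord[i], ord[seq_len(i - 1L)]], collapse = "")
           else ""
    parts[i] <- paste0(tokens[ord[i]], "/", row)
  }
  paste(parts, collapse = ";")
}

canonical_order <- function(env) {
  n <- nrow(env$atoms)
  tokens <- env_tokens(env)
  if (n == 1L) return(1L)
  M <- env_bond_matrix(env)
  keys <- atom_sort_keys(env)
  cols <- match(keys, sort(unique(keys)))

  best <- list(serial = NULL, ord = NULL)
  search <- function(cols) {
    cols <- refine_colours(cols, M)
    tab <- table(cols)
    if (all(tab == 1L)) {
      ord <- order(cols)
      s <- order_serial(ord, tokens, M)
      if (is.null(best$serial) || s < best$serial) {
        best$serial <<- s
        best$ord <<- ord
      }
      return(invisible(NULL))
    }
    cell <- as.integer(names(tab)[tab > 1L][1])
    members <- which(cols == cell)
    for (m in members) {
      c2 <- cols * 2L
      c2[m] <- c2[m] - 1L
      search(match(c2, sort(unique(c2))))
    }
    invisible(NULL)
  }
  search(cols)
  best$ord
}

# --- SMARTS rendering --------------------------------------------------------

# Render one connected fragment as a SMILES-like SMARTS string. Traversal is
# depth-first from the lowest-ranked atom, neighbours visited in canonical
# rank order; all but the last child are parenthesized branches. Ring-closure
# bonds carry a bond symbol plus a digit (">9" uses %nn) at both endpoints.
render_fragment <- function(members, rank, tokens, M, closure_start) {
  ordered <- members[order(rank[members])]
  root <- ordered[1]
  visited <- rep(FALSE, length(rank))
  parent <- rep(NA_integer_, length(rank))
  children <- vector("list", length(rank))
  back_edges <- list()

  walk <- function(u) {
    visited[u] <<- TRUE
    nbrs <- which(M[u, ] > 0L)
    nbrs <- nbrs[order(rank[nbrs])]
    for (v in nbrs) {
      if (!is.na(parent[u]) && v == parent[u]) next
      if (visited[v]) {
        key <- paste(sort(c(u, v)), collapse = "-")
        known <- vapply(back_edges, function(e) e$key, character(1))
        if (!(key %in% known)) {
          back_edges[[length(back_edges) + 1L]] <<-
            list(key = key, u = u, v = v, digit = NA_integer_)
        }
      } else {
        parent[v] <<- u
        children[[u]] <<- c(children[[u]], v)
        walk(v)
      }
    }
  }
  walk(root)

  if (length(back_edges) > 0L) {
    for (k in seq_along(back_edges)) {
      back_edges[[k]]$digit <- closure_start + k - 1L
    }
    if (max(vapply(back_edges, function(e) e$digit, integer(1))) > 99L) {
      stop("too many ring closures for the SMARTS dialect")
    }
  }
  digit_str <- function(d) if (d <= 9L) as.character(d) else paste0("%", d)
  closures_at <- function(u) {
    out <- ""
    for (e in back_edges) {
      if (e$u == u || e$v == u) {
        out <- paste0(out, BOND_SMARTS[[BOND_ORDERS[M[e$u, e$v]]]],
                      digit_str(e$digit))
      }
    }
    out
  }
  emit <- function(u) {
    s <- paste0(tokens[u], closures_at(u))
    kids <- children[[u]]
    if (length(kids) > 0L) {
      for (i in seq_along(kids)) {
        v <- kids[i]
        bnd <- BOND_SMARTS[[BOND_ORDERS[M[u, v]]]]
        sub <- paste0(bnd, emit(v))
        s <- paste0(s, if (i < length(kids)) paste0("(", sub, ")") else sub)
      }
    }
    s
  }
  list(smarts = emit(root),
       n_closures = length(back_edges))
}

#' Serialize an arrow-environment to SMARTS
#'
#' Writes the restricted SMARTS dialect used throughout the package: one
#' dot-separated fragment per connected component; atoms as
#' `[#<atomic number>]` with an optional `&-`/`&+` charge (magnitude appended
#' when above one) and, for outer-shell equivalence classes, an alternation
#' such as `[#6,#1]`; reaction-centre atoms carry the two-digit atom map
#' `:ED` where `E` is the electron count and `D` marks tail (1), tip (2) or
#' both (3); bonds are `-`, `=`, `#`, `:`; ring closures use a bond symbol
#' plus digit at both endpoints. The rendering is canonical: environments
#' with equal canonical keys produce byte-identical strings.
#'
#' @param env an `arrow_env`.
#' @return character scalar.
#' @export
to_smarts <- function(env) env$smarts

# compute canonical order, SMARTS and key for an env under construction
canonicalize_env <- function(env) {
  ord <- canonical_order(env)
  n <- nrow(env$atoms)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  tokens <- env_tokens(env)
  M <- env_bond_matrix(env)

  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      stack <- i
      while (length(stack) > 0L) {
        u <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (comp[u] == 0L) {
          comp[u] <- cid
          stack <- c(stack, which(M[u, ] > 0L & comp == 0L))
        }
      }
    }
  }
  frags <- character(cid)
  closure_start <- 1L
  for (k in seq_len(cid)) {
    fr <- render_fragment(which(comp == k), rank, tokens, M, closure_start)
    frags[k] <- fr$smarts
    closure_start <- closure_start + fr$n_closures
  }
  env$smarts <- paste(sort(frags, method = "radix"), collapse = ".")
  env$key <- paste0(env$definition, "|", env$smarts)
  env
}

# --- SMARTS parsing (restricted dialect) ------------------------------------

parse_atom_content <- function(content, smarts) {
  m <- regmatches(content,
    regexec("^#([0-9]+)((?:,#[0-9]+)*)(&([+-])([0-9]*))?(:([0-9]{2}))?$",
            content))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("out-of-dialect SMARTS atom '[%s]' in '%s'", content, smarts))
  }
  elems <- as.integer(m[2])
  if (nzchar(m[3])) {
    extra <- as.integer(strsplit(gsub("#", "", m[3]), ",")[[1]])
    elems <- c(elems, extra[!is.na(extra)])
  }
  charge <- 0L
  if (nzchar(m[4])) {
    mag <- if (nzchar(m[6])) as.integer(m[6]) else 1L
    charge <- if (m[5] == "+") mag else -mag
  }
  map <- if (nzchar(m[7])) m[8] else NA_character_
  if (!is.na(map)) {
    e <- as.integer(substr(map, 1, 1)); d <- as.integer(substr(map, 2, 2))
    if (!(e %in% c(1L, 2L)) || !(d %in% c(1L, 2L, 3L))) {
      stop(sprintf("invalid two-digit atom map ':%s' (electrons 1-2, role 1-3)",
                   map))
    }
  }
  list(elems = sort(elems, decreasing = TRUE), charge = charge, map = map)
}

#' Parse a SMARTS string of the package dialect back into an arrow-environment
#'
#' Inverse of [to_smarts()] up to canonical form: only the emitted dialect is
#' accepted (bracket atoms with atomic-number primitives, optional charge and
#' alternation, the two-digit atom map, bond symbols `-`, `=`, `#`, `:`,
#' parenthesized branches, dot-separated fragments, digit ring closures).
#'
#' @param smarts character scalar.
#' @param definition the arrow-env definition the string belongs to
#'   (definitions are never mixed in one comparison); default `"two_away"`.
#' @return an `arrow_env` whose canonical key equals that of the environment
#'   the string was rendered from.
#' @export
parse_smarts_env <- function(smarts, definition = "two_away") {
  def <- as_definition(definition)
  stopifnot(is.character(smarts), length(smarts) == 1L)
  atoms <- list()
  bonds <- list()
  closures <- list()

  add_atom <- function(parsed) {
    id <- length(atoms) + 1L
    atoms[[id]] <<- data.frame(
      atom_id = id,
      element = parsed$elems[1],
      charge = parsed$charge,
      equiv = if (length(parsed$elems) > 1L) {
        paste(parsed$elems, collapse = ",")
      } else NA_character_,
      map = parsed$map,
      stringsAsFactors = FALSE)
    id
  }
  add_bond <- function(a, b, order) {
    bonds[[length(bonds) + 1L]] <<- data.frame(a = a, b = b, order = order,
                                               stringsAsFactors = FALSE)
  }

  bond_chars <- c("-" = "single", "=" = "double", "#" = "triple",
                  ":" = "aromatic")

  for (frag in strsplit(smarts, ".", fixed = TRUE)[[1]]) {
    chars <- strsplit(frag, "")[[1]]
    pos <- 1L
    prev <- NA_integer_
    pending <- NA_character_
    stack <- integer(0)
    bad <- function() {
      stop(sprintf("out-of-dialect SMARTS near position %d of '%s'", pos, frag))
    }
    while (pos <= length(chars)) {
      ch <- chars[pos]
      if (ch == "[") {
        close <- pos
        while (close <= length(chars) && chars[close] != "]") close <- close + 1L
        if (close > length(chars)) bad()
        parsed <- parse_atom_content(
          paste(chars[(pos + 1L):(close - 1L)], collapse = ""), smarts)
        id <- add_atom(parsed)
        if (!is.na(prev)) {
          if (is.na(pending)) bad()
          add_bond(prev, id, pending)
        }
        pending <- NA_character_
        prev <- id
        pos <- close + 1L
        # ring-closure digits directly after the bracket atom
        while (pos < length(chars) && chars[pos] %in% names(bond_chars) &&
               (grepl("^[0-9]$", chars[pos + 1L]) || chars[pos + 1L] == "%")) {
          ord <- bond_chars[[chars[pos]]]
          if (chars[pos + 1L] == "%") {
            if (pos + 3L > length(chars)) bad()
            digit <- paste(chars[(pos + 2L):(pos + 3L)], collapse = "")
            pos <- pos + 4L
          } else {
            digit <- chars[pos + 1L]
            pos <- pos + 2L
          }
          if (is.null(closures[[digit]])) {
            closures[[digit]] <- list(atom = id, order = ord)
          } else {
            if (closures[[digit]]$order != ord) {
              stop(sprintf("ring closure %s has conflicting bond orders", digit))
            }
            add_bond(closures[[digit]]$atom, id, ord)
            closures[[digit]] <- NULL
          }
        }
      } else if (ch %in% names(bond_chars)) {
        pending <- bond_chars[[ch]]
        pos <- pos + 1L
      } else if (ch == "(") {
        stack <- c(stack, prev)
        pos <- pos + 1L
      } else if (ch == ")") {
        if (length(stack) == 0L) bad()
        prev <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pos <- pos + 1L
      } else {
        bad()
      }
    }
    if (length(stack) > 0L) {
      stop(sprintf("unbalanced parentheses in SMARTS fragment '%s'", frag))
    }
  }
  if (length(closures) > 0L && any(!vapply(closures, is.null, logical(1)))) {
    stop("unmatched ring-closure digit(s) in SMARTS")
  }

  at <- do.call(rbind, atoms)
  b <- if (length(bonds) > 0L) do.call(rbind, bonds) else
    data.frame(a = integer(0), b = integer(0), order = character(0))
  env <- structure(list(atoms = at, bonds = b, definition = def$name,
                        shell_depth = def$shell_depth),
                   class = "arrow_env")
  canonicalize_env(env)
}
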