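# Shared oracles and generators for the test suite. The oracles are
# deliberately independent of the implementation paths they check:
# shell membership via dumb all-pairs BFS, env equality via igraph's VF2
# isomorphism with label colours.

# brute-force shortest-path distance between two atoms (BFS over the bond
# list, no reuse of package internals)
bf_distance <- function(state, from, to) {
  if (from == to) return(0L)
  pairs <- rbind(cbind(state$bonds$a, state$bonds$b),
                 cbind(state$bonds$b, state$bonds$a))
  seen <- from
  frontier <- from
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- unique(pairs[pairs[, 1] %in% frontier, 2])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(d)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

# oracle: all atoms within `depth` of any centre, by brute force
bf_shell <- function(state, centres, depth) {
  ids <- state$atoms$atom_id
  keep <- vapply(ids, function(a) {
    any(vapply(centres, function(ct) bf_distance(state, ct, a) <= depth,
               logical(1)))
  }, logical(1))
  sort(ids[keep])
}

# igraph with label colours for the VF2 oracle; labels combine element /
# equivalence class, charge and arrow map exactly as key equality must
env_label_strings <- function(env) {
  at <- env$atoms
  sprintf("%s|%d|%s",
          ifelse(is.na(at$equiv), as.character(at$element), at$equiv),
          at$charge,
          ifelse(is.na(at$map), "", at$map))
}

vf2_isomorphic <- function(e1, e2) {
  if (nrow(e1$atoms) != nrow(e2$atoms)) return(FALSE)
  if (nrow(e1$bonds) != nrow(e2$bonds)) return(FALSE)
  labs <- sort(unique(c(env_label_strings(e1), env_label_strings(e2))))
  ords <- c("single", "double", "triple", "aromatic")
  as_g <- function(env) {
    g <- igraph::make_empty_graph(n = nrow(env$atoms), directed = FALSE)
    if (nrow(env$bonds) > 0L) {
      g <- igraph::add_edges(g, rbind(match(env$bonds$a, env$atoms$atom_id),
                                      match(env$bonds$b, env$atoms$atom_id)))
    }
    g
  }
  igraph::isomorphic(
    as_g(e1), as_g(e2), method = "vf2",
    vertex.color1 = match(env_label_strings(e1), labs),
    vertex.color2 = match(env_label_strings(e2), labs),
    edge.color1 = if (nrow(e1$bonds) > 0L) match(e1$bonds$order, ords),
    edge.color2 = if (nrow(e2$bonds) > 0L) match(e2$bonds$order, ords))
}

# rebuild an env after randomly permuting the atom ids of its parent step;
# the result must be isomorphic to the original by construction
permute_step_atoms <- function(step, perm = NULL) {
  ids <- step$state$atoms$atom_id
  if (is.null(perm)) {
    perm <- stats::setNames(sample(1000L + seq_along(ids)), ids)
  }
  remap <- function(x) unname(perm[as.character(x)])
  atoms <- step$state$atoms
  atoms$atom_id <- remap(atoms$atom_id)
  atoms <- atoms[order(atoms$atom_id), ]
  bonds <- step$state$bonds
  if (nrow(bonds) > 0L) {
    bonds$a <- remap(bonds$a); bonds$b <- remap(bonds$b)
  }
  arrows <- lapply(step$arrows, function(ar) {
    ar$source$atoms <- remap(ar$source$atoms)
    ar$sink$atoms <- remap(ar$sink$atoms)
    ar
  })
  catalytic_step(step$step_index, site_state(atoms, bonds), arrows)
}

# pool of (step, arrow index) pairs drawn from seeded random mechanisms
random_arrow_pool <- function(n_mechs, seed_base = 100L,
                             config_args = list()) {
  pool <- list()
  for (k in seq_len(n_mechs)) {
    cfg <- do.call(generator_config,
                   c(list(seed = seed_base + k), config_args))
    mech <- random_mechanism(cfg)
    for (s in mech$steps) {
      for (i in seq_along(s$arrows)) {
        pool[[length(pool) + 1L]] <- list(step = s, arrow = s$arrows[[i]])
      }
    }
  }
  pool
}

minimal_mrv <- function() {
  paste0(
    '<cml><MDocument><MChemicalStruct><molecule molID="m1">',
    '<atomArray atomID="a1 a2 a3" elementType="O H O" formalCharge="0 0 -1"/>',
    '<bondArray><bond id="b1" atomRefs2="a1 a2" order="1"/>',
    '<bond id="b2" atomRefs2="a1 a3" order="1"/></bondArray>',
    '</molecule></MChemicalStruct>',
    '<MEFlow electrons="2"><atomSetPoint atomRefs="m1.a3"/>',
    '<atomSetPoint atomRefs="m1.a2"/></MEFlow>',
    '</MDocument></cml>')
}

fig1_smarts <- "[#6]-[#8&-:23].[#8]-[#6:22](-[#8])(-[#1])-[#6]"
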