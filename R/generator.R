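# Seeded synthetic-mechanism generator and mutation operator. Generated
# mechanisms are chemically naive (random labelled graphs with arrow
# chemistry over them) but structurally valid, which is what the similarity
# machinery and its property tests need; thermodynamic realism is a
# non-goal.

#' Configuration for the synthetic-mechanism generator
#'
#' @param seed integer seed; the same configuration always yields the same
#'   mechanism.
#' @param n_steps integer range `c(min, max)` of catalytic steps.
#' @param arrows_per_step integer range of arrows per step.
#' @param atoms_per_state integer range of atoms per state.
#' @param elements atomic numbers drawn for atoms.
#' @param element_weights sampling weights, same length as `elements`; the
#'   default palette mirrors typical active-site composition (mostly C, O,
#'   N, H with occasional S).
#' @param charge_prob probability that an atom carries a +-1 formal charge.
#' @param bond_source_frac fraction of arrows whose source is a bond (the
#'   rest start from a lone pair).
#' @param extra_bond_prob probability of each possible extra (cycle-forming)
#'   bond beyond the random spanning tree.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_steps = c(1L, 3L),
                             arrows_per_step = c(1L, 3L),
                             atoms_per_state = c(6L, 12L),
                             elements = c(6L, 8L, 7L, 1L, 16L),
                             element_weights = c(4, 3, 2, 3, 1),
                             charge_prob = 0.1,
                             bond_source_frac = 0.5,
                             extra_bond_prob = 0.05) {
  stopifnot(length(n_steps) == 2L, n_steps[1] >= 1L,
            n_steps[2] >= n_steps[1],
            length(arrows_per_step) == 2L, arrows_per_step[1] >= 1L,
            arrows_per_step[2] >= arrows_per_step[1],
            length(atoms_per_state) == 2L, atoms_per_state[1] >= 2L,
            atoms_per_state[2] >= atoms_per_state[1],
            length(elements) == length(element_weights),
            charge_prob >= 0, charge_prob <= 1,
            bond_source_frac >= 0, bond_source_frac <= 1)
  structure(list(seed = as.integer(seed), n_steps = as.integer(n_steps),
                 arrows_per_step = as.integer(arrows_per_step),
                 atoms_per_state = as.integer(atoms_per_state),
                 elements = as.integer(elements),
                 element_weights = element_weights,
                 charge_prob = charge_prob,
                 bond_source_frac = bond_source_frac,
                 extra_bond_prob = extra_bond_prob),
            class = "generator_config")
}

# run code under a private RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample1 <- function(x) x[sample.int(length(x), 1L)]
rand_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

random_state <- function(cfg) {
  n <- rand_range(cfg$atoms_per_state)
  atoms <- data.frame(
    atom_id = seq_len(n),
    element = sample(cfg$elements, n, replace = TRUE,
                     prob = cfg$element_weights),
    charge = ifelse(stats::runif(n) < cfg$charge_prob,
                    sample(c(-1L, 1L), n, replace = TRUE), 0L))
  # random spanning tree keeps each state connected enough to have shells
  a <- integer(0); b <- integer(0)
  for (i in 2:n) {
    a <- c(a, sample.int(i - 1L, 1L)); b <- c(b, i)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (!any(a == i & b == j) && stats::runif(1) < cfg$extra_bond_prob) {
        a <- c(a, i); b <- c(b, j)
      }
    }
  }
  order <- sample(c("single", "double"), length(a), replace = TRUE,
                  prob = c(0.85, 0.15))
  site_state(atoms, data.frame(a = a, b = b, order = order))
}

random_arrow <- function(state, cfg) {
  ids <- state$atoms$atom_id
  nb <- nrow(state$bonds)
  pick_bond <- function() {
    i <- sample.int(nb, 1L)
    arrow_bond(state$bonds$a[i], state$bonds$b[i])
  }
  source <- if (nb > 0L && stats::runif(1) < cfg$bond_source_frac) {
    pick_bond()
  } else {
    arrow_atom(sample1(ids))
  }
  for (attempt in 1:50) {
    sink <- switch(sample1(c("atom", "bond", "incipient")),
      atom = arrow_atom(sample1(ids)),
      bond = if (nb > 0L) pick_bond() else arrow_atom(sample1(ids)),
      incipient = {
        pair <- sample(ids, 2L)
        arrow_incipient(pair[1], pair[2])
      })
    if (!endpoints_equal(source, sink)) {
      return(curly_arrow(sample(c(1L, 2L), 1L, prob = c(0.05, 0.95)),
                         source, sink))
    }
  }
  stop("could not draw a sink distinct from the source")
}

#' Generate a random, validation-clean mechanism
#'
#' Deterministic in `config$seed`: the same configuration yields the same
#' mechanism (byte-identical JSON).
#'
#' @param config a [generator_config()].
#' @param id mechanism id (default derived from the seed).
#' @return a [mechanism()] passing [validate_mechanism()].
#' @export
random_mechanism <- function(config = generator_config(),
                             id = sprintf("synth-%d", config$seed)) {
  with_seed(config$seed, {
    n_steps <- rand_range(config$n_steps)
    steps <- lapply(seq_len(n_steps), function(si) {
      state <- random_state(config)
      n_arrows <- rand_range(config$arrows_per_step)
      arrows <- lapply(seq_len(n_arrows), function(i) {
        random_arrow(state, config)
      })
      catalytic_step(si, state, arrows)
    })
    mech <- mechanism(id, steps)
    stop_if_invalid(mech)
    mech
  })
}

#' Apply random label/topology edits to a mechanism
#'
#' Each edit is one of: an element swap on an atom outside every arrow's
#' reaction centres, a formal-charge edit, or a rewire of one arrow's sink
#' to a different atom. Edits never break validity; `n_edits = 0` returns
#' the mechanism unchanged. Used to study how similarity to the original
#' decays with increasing perturbation.
#'
#' @param mech a valid [mechanism()].
#' @param n_edits number of edits (>= 0).
#' @param seed integer seed for the edit stream.
#' @return a [mechanism()] passing [validate_mechanism()].
#' @export
mutate_mechanism <- function(mech, n_edits, seed = 1L) {
  stopifnot(n_edits >= 0L)
  if (n_edits == 0L) return(mech)
  palette <- c(6L, 8L, 7L, 1L, 16L)
  with_seed(seed, {
    for (e in seq_len(n_edits)) {
      si <- sample.int(length(mech$steps), 1L)
      step <- mech$steps[[si]]
      centres <- sort(unique(unlist(lapply(step$arrows, reaction_centres))))
      kind <- sample1(c("element", "charge", "rewire"))
      if (kind == "element") {
        cand <- setdiff(step$state$atoms$atom_id, centres)
        if (length(cand) == 0L) kind <- "charge"
        else {
          aid <- sample1(cand)
          i <- match(aid, step$state$atoms$atom_id)
          step$state$atoms$element[i] <-
            sample1(setdiff(palette, step$state$atoms$element[i]))
        }
      }
      if (kind == "charge") {
        i <- sample.int(nrow(step$state$atoms), 1L)
        step$state$atoms$charge[i] <- step$state$atoms$charge[i] +
          sample1(c(-1L, 1L))
      }
      if (kind == "rewire") {
        ai <- sample.int(length(step$arrows), 1L)
        arrow <- step$arrows[[ai]]
        for (attempt in 1:50) {
          sink <- arrow_atom(sample1(step$state$atoms$atom_id))
          if (!endpoints_equal(arrow$source, sink)) {
            arrow$sink <- sink
            break
          }
        }
        step$arrows[[ai]] <- arrow
      }
      mech$steps[[si]] <- step
    }
    stop_if_invalid(mech)
    mech
  })
}
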